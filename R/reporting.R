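#' Spectra-structure annotation of characteristic wavenumbers
#'
#' Nearest-entry lookup (within `tolerance` cm^-1) into the shipped table of
#' known NIR band assignments for the two sclerotium tissues. Annotation is
#' informational only: it never feeds back into selection or classification.
#'
#' @param wavenumbers Numeric vector, cm^-1.
#' @param tolerance Match tolerance, cm^-1 (default 2).
#' @return A tibble: `wavenumber`, `matched` (table entry or `NA`),
#'   `assignment` (`"unassigned"` when nothing is within tolerance).
#' @examples
#' annotate_bands(c(4439.33, 9000))
#' @export
annotate_bands <- function(wavenumbers, tolerance = 2) {
  tbl <- band_assignment_table()
  purrr::map_dfr(wavenumbers, function(w) {
    d <- abs(tbl$wavenumber - w)
    i <- which.min(d)
    if (d[i] <= tolerance) {
      tibble::tibble(wavenumber = w, matched = tbl$wavenumber[i],
                     assignment = tbl$assignment[i])
    } else {
      tibble::tibble(wavenumber = w, matched = NA_real_,
                     assignment = "unassigned")
    }
  })
}

#' The shipped band-assignment lookup table
#'
#' @return A tibble with `wavenumber`, `tissue`, `assignment`.
#' @export
band_assignment_table <- function() {
  readr::read_csv(system.file("extdata", "band_assignments.csv",
                              package = "nirselect"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Transcribed PLS-DA membership tables
#'
#' The printed per-sample (actual class, flag, Y_pre, Y_dev) entries of the
#' published validation tables for one tissue, across the five variable sets
#' (full band, CARS, MC-UVE, SPA, LPG). Used to replay the membership rule
#' and the column accuracies exactly.
#'
#' @param tissue `"BFL"` or `"FLP"`.
#' @return A tibble: `sample_id`, `variable_set`, `actual_class`, `flag`,
#'   `y_pre`, `y_dev`.
#' @export
galtier_reference_table <- function(tissue = c("BFL", "FLP")) {
  tissue <- match.arg(tissue)
  file <- sprintf("galtier_table_%s.csv", tolower(tissue))
  readr::read_csv(system.file("extdata", file, package = "nirselect"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Render a markdown run report
#'
#' Writes a single deterministic markdown report (no timestamps) covering the
#' pretreatment parameters, the outlier log, split sizes, per-method
#' selection summaries, the membership verdict table, the Fisher coefficient
#' table and the leave-one-out confusion table. Missing stages are flagged as
#' gaps rather than aborting.
#'
#' @param run A `nir_run` from [run_pipeline()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
render_run_report <- function(run, path) {
  lines <- c(sprintf("# NIR origin-discrimination run (%s)", run$tissue), "")
  section <- function(title, body) c(sprintf("## %s", title), "", body, "")
  fmt_tbl <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.4f", x))
    header <- paste("|", paste(names(df), collapse = " | "), "|")
    sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
    rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
    c(header, sep, rows)
  }
  gap <- function(name) sprintf("*stage `%s` missing from this run*", name)

  lines <- c(lines, section("Pretreatment",
    if (is.null(run$pretreat_params)) gap("pretreat") else
      sprintf("- %s: %s", names(run$pretreat_params),
              vapply(run$pretreat_params, function(x)
                paste(format(x), collapse = ", "), character(1)))))
  lines <- c(lines, section("Outlier screening",
    if (is.null(run$outliers)) gap("qc") else
      sprintf("Removed %d sample(s): %s",
              length(run$outliers$removed_ids),
              if (length(run$outliers$removed_ids))
                paste(run$outliers$removed_ids, collapse = ", ") else "none")))
  lines <- c(lines, section("Training/validation split",
    if (is.null(run$split_sizes)) gap("split") else
      sprintf("- %s: %d samples", names(run$split_sizes),
              unlist(run$split_sizes))))
  lines <- c(lines, section("Variable selection",
    if (is.null(run$selection_summary)) gap("select") else
      fmt_tbl(run$selection_summary)))
  lines <- c(lines, section("Membership verdicts",
    if (is.null(run$evaluation)) gap("evaluate") else fmt_tbl(run$evaluation)))
  lines <- c(lines, section("Fisher coefficients",
    if (is.null(run$fisher)) gap("fisher") else fmt_tbl(tidy(run$fisher))))
  lines <- c(lines, section("Leave-one-out validation",
    if (is.null(run$loo)) gap("loo") else c(
      sprintf("Resubstitution accuracy: %.2f%%; LOO accuracy: %.2f%%",
              run$resubstitution_accuracy, run$loo$accuracy), "",
      fmt_tbl(as.data.frame.matrix(run$loo$confusion)))))
  writeLines(lines, path)
  invisible(path)
}
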