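new_selection_result <- function(method, selected, scores, rmsecv_path,
                                 chosen_threshold, seed) {
  structure(list(method = method, selected = selected, scores = scores,
                 rmsecv_path = rmsecv_path,
                 chosen_threshold = chosen_threshold, seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d wavenumber(s) selected\n",
              x$method, length(x$selected)))
  invisible(x)
}

#' @export
tidy.selection_result <- function(x, ...) x$scores

#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(method = x$method, n_selected = length(x$selected),
                 min_rmsecv = if (any(is.finite(x$rmsecv_path)))
                   min(x$rmsecv_path, na.rm = TRUE) else NA_real_,
                 chosen_threshold = x$chosen_threshold, seed = x$seed)
}

# resolve (X, y, wavenumbers) from a spectra_set or a plain matrix
selection_input <- function(x, y) {
  if (inherits(x, "spectra_set")) {
    list(X = x$absorbance, y = if (is.null(y)) x$meta$region_class else y,
         wn = x$grid$points)
  } else {
    X <- as.matrix(x)
    wn <- suppressWarnings(as.numeric(colnames(X)))
    if (length(wn) == 0 || anyNA(wn)) wn <- seq_len(ncol(X))
    if (is.null(y)) abort("`y` is required for a matrix input.")
    list(X = X, y = as.numeric(y), wn = wn)
  }
}

#' Consensus vote over selection results
#'
#' Variables chosen by at least `min_votes` of the supplied selection results
#' become the common variables carried into discriminant modeling.
#'
#' @param results List of `selection_result` objects (at least 2).
#' @param min_votes Minimum number of methods that must agree (default 2).
#' @return Numeric vector of common wavenumbers, descending.
#' @export
consensus_vote <- function(results, min_votes = 2) {
  if (length(results) < 2) abort("Need at least 2 selection results.",
                                 class = "nirselect_parameter_error")
  all_wn <- unlist(purrr::map(results, "selected"))
  counts <- table(all_wn)
  sort(as.numeric(names(counts)[counts >= min_votes]), decreasing = TRUE)
}
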