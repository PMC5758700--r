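#' Configuration for an end-to-end discrimination run
#'
#' Bundles every tunable of the pipeline so a run is a pure function of
#' (input spectra, config). Stage seeds are derived from the master seed plus
#' the stage name, so stages can be rerun in isolation.
#'
#' @param band_high,band_low Preliminary band window, cm^-1 (defaults: the
#'   study window 7501.74 to 4088.35).
#' @param pretreat_steps,segment,gap,window,polyorder Pretreatment chain; see
#'   [pretreat()].
#' @param qc_components,qc_alpha,qc_max_iter Outlier screening; see
#'   [iterative_outlier_removal()].
#' @param validation_fraction Kennard-Stone hold-out fraction (default 1/3).
#' @param A Latent variables for all PLS models (default 5).
#' @param folds Cross-validation folds (default 10).
#' @param cars_runs,cars_iter,mcuve_draws,spa_runs,spa_q,sample_frac
#'   Per-method selection parameters.
#' @param min_votes Consensus vote threshold (default 2).
#' @param f_enter,f_remove Stepwise partial-F thresholds.
#' @param suspicious_threshold,uncredited_margin Membership rule limits.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(band_high = 7501.74, band_low = 4088.35,
                            pretreat_steps = c("norris", "mean_center",
                                               "standardize",
                                               "second_derivative"),
                            segment = 5, gap = 5, window = 11, polyorder = 2,
                            qc_components = 5, qc_alpha = 0.99,
                            qc_max_iter = 10,
                            validation_fraction = 1/3, A = 5, folds = 10,
                            cars_runs = 100, cars_iter = 50,
                            mcuve_draws = 500, spa_runs = 1000, spa_q = 10,
                            sample_frac = 0.8, min_votes = 2,
                            f_enter = 3.84, f_remove = 2.71,
                            suspicious_threshold = 0.45,
                            uncredited_margin = 0.55, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

# deterministic per-stage seed stream, kept under 2^31
stage_seed <- function(master, stage) {
  (as.integer(master) + sum(utf8ToInt(stage)) * 1009L) %% 2000000011L
}

#' Run the full discrimination pipeline on a spectra set
#'
#' Executes band cropping and pretreatment, PCA outlier screening,
#' Kennard-Stone 2:1 splitting, the four wavelength-selection algorithms,
#' consensus voting, PLS evaluation of every variable set under the
#' membership rule, stepwise Wilks-lambda screening, Fisher discriminant
#' fitting with leave-one-out validation, and (optionally) artifact writing
#' plus a markdown report.
#'
#' @param s A [spectra_set()] for one tissue.
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory; when given, every intermediate artifact
#'   and the report are written there deterministically.
#' @return A `nir_run` list with every stage output.
#' @export
run_pipeline <- function(s, cfg = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(s, "spectra_set"), inherits(cfg, "pipeline_config"))
  tissue <- unique(s$meta$tissue)
  run <- list(tissue = paste(tissue, collapse = "+"), config = cfg)

  stage <- "preprocess"
  pre <- tryCatch({
    cropped <- band_crop(s, cfg$band_high, cfg$band_low)
    pretreat(cropped, steps = cfg$pretreat_steps, segment = cfg$segment,
             gap = cfg$gap, window = cfg$window, polyorder = cfg$polyorder)
  }, error = function(e) pipeline_abort(stage, e))
  run$pretreat_params <- list(band_high = cfg$band_high,
                              band_low = cfg$band_low,
                              steps = cfg$pretreat_steps,
                              segment = cfg$segment, gap = cfg$gap,
                              window = cfg$window, polyorder = cfg$polyorder)

  stage <- "qc"
  qc <- tryCatch(
    iterative_outlier_removal(pre, k = cfg$qc_components, alpha = cfg$qc_alpha,
                              max_iter = cfg$qc_max_iter),
    error = function(e) pipeline_abort(stage, e))
  run$outliers <- qc$report
  clean <- qc$spectra

  stage <- "split"
  split <- tryCatch(kennard_stone_split(clean, cfg$validation_fraction),
                    error = function(e) pipeline_abort(stage, e))
  train <- subset_split(split, "training")
  valid <- subset_split(split, "validation")
  run$split <- split$meta
  run$split_sizes <- list(training = nrow(train$absorbance),
                          validation = nrow(valid$absorbance))

  stage <- "select"
  run$selection <- tryCatch(list(
    cars = cars_select(train, A = cfg$A, n_iter = cfg$cars_iter,
                       sample_frac = cfg$sample_frac, folds = cfg$folds,
                       n_runs = cfg$cars_runs,
                       seed = stage_seed(cfg$seed, "cars")),
    mcuve = mcuve_select(train, A = cfg$A, n_mc = cfg$mcuve_draws,
                         sample_frac = cfg$sample_frac, folds = cfg$folds,
                         seed = stage_seed(cfg$seed, "mcuve")),
    spa = spa_select(train, A = cfg$A, N = cfg$spa_runs, R = cfg$sample_frac,
                     Q = cfg$spa_q, folds = cfg$folds,
                     seed = stage_seed(cfg$seed, "spa")),
    lpg = lpg_select(train)),
    error = function(e) pipeline_abort(stage, e))
  run$consensus <- consensus_vote(run$selection, min_votes = cfg$min_votes)
  run$selection_summary <- dplyr::bind_rows(
    purrr::map(run$selection, glance),
    tibble::tibble(method = "consensus",
                   n_selected = length(run$consensus)))

  stage <- "evaluate"
  run$evaluation <- tryCatch({
    sets <- c(list(full = train$grid$points),
              purrr::map(run$selection, "selected"),
              list(consensus = run$consensus))
    purrr::imap_dfr(sets, function(wns, name) {
      if (length(wns) < 2) {
        return(tibble::tibble(variable_set = name, n_variables = length(wns),
                              rmsecv = NA_real_, r2 = NA_real_,
                              rmsep = NA_real_, accuracy = NA_real_))
      }
      cols <- match(format_wavenumber(wns), colnames(train$absorbance))
      Xtr <- train$absorbance[, cols, drop = FALSE]
      Xva <- valid$absorbance[, cols, drop = FALSE]
      ytr <- train$meta$region_class; yva <- valid$meta$region_class
      eval_seed <- stage_seed(cfg$seed, "evaluate")
      cv <- cross_validate(Xtr, ytr, A = min(cfg$A, length(wns)),
                           folds = cfg$folds, seed = eval_seed,
                           X_val = Xva, y_val = yva)
      pd <- predict_with_deviation(Xtr, ytr, Xva, A = min(cfg$A, length(wns)),
                                   folds = cfg$folds, seed = eval_seed)
      verdicts <- galtier_verdict(
        yva, pd$y_pre, pd$y_dev,
        codes = sort(unique(ytr)),
        suspicious_threshold = cfg$suspicious_threshold,
        uncredited_margin = cfg$uncredited_margin)
      tibble::tibble(variable_set = name, n_variables = length(wns),
                     rmsecv = cv$rmsecv, r2 = cv$r2, rmsep = cv$rmsep,
                     accuracy = set_accuracy(verdicts, yva))
    })
  }, error = function(e) pipeline_abort(stage, e))

  stage <- "stepwise"
  if (length(run$consensus) == 0) {
    pipeline_abort(stage, simpleError(
      "Consensus variable set is empty (min_votes exceeds the agreeing methods)."))
  }
  cols <- match(format_wavenumber(run$consensus), colnames(train$absorbance))
  Xc <- train$absorbance[, cols, drop = FALSE]
  run$stepwise <- tryCatch(
    stepwise_select(Xc, train$meta$region_class, f_enter = cfg$f_enter,
                    f_remove = cfg$f_remove),
    error = function(e) pipeline_abort(stage, e))
  retained <- run$stepwise$retained
  if (length(retained) == 0) {
    pipeline_abort(stage, simpleError("Stepwise screening retained no variable."))
  }

  stage <- "fisher"
  rcols <- match(format_wavenumber(retained), colnames(train$absorbance))
  Xr <- train$absorbance[, rcols, drop = FALSE]
  Xr_val <- valid$absorbance[, rcols, drop = FALSE]
  run$fisher <- tryCatch(fisher_fit(Xr, train$meta$region_class),
                         error = function(e) pipeline_abort(stage, e))
  resub <- fisher_classify(run$fisher, Xr)
  run$resubstitution_accuracy <-
    round(100 * mean(resub == train$meta$region_class), 2)
  run$loo <- tryCatch(loo_cross_validate(Xr, train$meta$region_class),
                      error = function(e) pipeline_abort(stage, e))
  val_pred <- fisher_classify(run$fisher, Xr_val)
  run$validation_accuracy <-
    round(100 * mean(val_pred == valid$meta$region_class), 2)
  run$annotations <- annotate_bands(retained)
  class(run) <- "nir_run"

  if (!is.null(out_dir)) write_run_artifacts(run, train, valid, out_dir)
  run
}

pipeline_abort <- function(stage, e) {
  abort(sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
        class = "nirselect_pipeline_error")
}

#' @export
print.nir_run <- function(x, ...) {
  cat(sprintf("<nir_run> %s: %d retained variable(s), LOO accuracy %.2f%%\n",
              x$tissue, length(x$stepwise$retained), x$loo$accuracy))
  invisible(x)
}

write_run_artifacts <- function(run, train, valid, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(...) file.path(out_dir, ...)
  readr::write_csv(run$outliers$iterations, f("outlier_report.csv"),
                   progress = FALSE)
  readr::write_csv(run$split, f("split.csv"), progress = FALSE)
  purrr::iwalk(run$selection, function(res, name)
    write_selection_json(res, f(sprintf("selection_%s.json", name))))
  jsonlite::write_json(run$consensus, f("consensus.json"), digits = NA)
  readr::write_csv(run$evaluation, f("evaluation.csv"), progress = FALSE)
  readr::write_csv(run$stepwise$trace, f("stepwise_trace.csv"),
                   progress = FALSE)
  write_fisher_json(run$fisher, f("fisher_model.json"))
  readr::write_csv(tibble::as_tibble(as.data.frame(run$loo$confusion)),
                   f("loo_confusion.csv"), progress = FALSE)
  readr::write_csv(run$annotations, f("annotations.csv"), progress = FALSE)
  render_run_report(run, f("report.md"))
  invisible(out_dir)
}
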