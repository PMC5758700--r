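#' Competitive adaptive reweighted sampling (CARS)
#'
#' Monte-Carlo wavelength selection driven by PLS regression coefficients.
#' Each run performs `n_iter` iterations; iteration `i` retains a fraction
#' `r_i = a exp(-k i)` of the starting variables, with `a, k` fixed so that
#' `r_1 = 1` and `r_n_iter = 2/p` (the exponentially decreasing elimination
#' schedule). Within an iteration a PLS model is fitted on a random
#' `sample_frac` subset of the samples, variables are ranked by `|b|`, the
#' forced (EDF) cut keeps the top `r_i * p`, and adaptive reweighted sampling
#' (a weighted bootstrap on `|b|`) competes the survivors. The iteration's
#' subset is scored by k-fold RMSECV on the full sample set; a run answers
#' with its minimum-RMSECV subset. Across `n_runs` runs the per-variable
#' selection frequency is recorded and the single best run (minimum RMSECV,
#' ties to fewer variables, then lowest run index) provides `selected`.
#'
#' @param x A [spectra_set()] (class codes taken from metadata) or a numeric
#'   matrix with wavenumber column names.
#' @param y Class codes; defaults to `region_class` for a spectra set.
#' @param A Latent variables (default 5).
#' @param n_iter Monte-Carlo iterations per run (default 50).
#' @param sample_frac Fraction of samples fitted per iteration (default 0.8).
#' @param folds Cross-validation folds (default 10).
#' @param n_runs Replicate runs (default 100).
#' @param seed Integer seed; every run derives its own stream.
#' @return A `selection_result` with per-variable selection `frequency`
#'   scores and the best run's `rmsecv_path`.
#' @export
cars_select <- function(x, y = NULL, A = 5, n_iter = 50, sample_frac = 0.8,
                        folds = 10, n_runs = 100, seed = 1) {
  inp <- selection_input(x, y)
  X <- inp$X; y <- inp$y; wn <- inp$wn
  n <- nrow(X); p <- ncol(X)
  if (p < 10) abort("CARS needs at least 10 variables.",
                    class = "nirselect_parameter_error")
  k_const <- log(p / 2) / (n_iter - 1)
  ratios <- exp(-k_const * (seq_len(n_iter) - 1))  # r_1 = 1, r_last = 2/p
  m <- max(2, round(sample_frac * n))

  run_best <- vector("list", n_runs)
  best_paths <- vector("list", n_runs)
  # one fold assignment for every run and iteration, so RMSECV values are
  # comparable across the whole search and the argmin is not fold luck
  fold_id <- make_folds(y, folds, seed + 7L)
  for (run in seq_len(n_runs)) {
    set.seed(seed + run * 131L)
    vars <- seq_len(p)
    path_rmsecv <- rep(NA_real_, n_iter)
    path_sets <- vector("list", n_iter)
    for (i in seq_len(n_iter)) {
      idx <- sample.int(n, m)
      A_i <- min(A, length(vars), m - 1)
      fit <- pls1_coef_cpp(X[idx, vars, drop = FALSE], y[idx], as.integer(A_i))
      w <- abs(drop(fit$b))
      n_keep <- max(2, round(ratios[i] * p))
      n_keep <- min(n_keep, length(vars))
      # forced elimination, then adaptive reweighted sampling
      keep <- vars[order(-w)[seq_len(n_keep)]]
      w_keep <- w[match(keep, vars)]
      if (sum(w_keep) <= 0) w_keep <- rep(1, length(keep))
      retained <- unique(keep[sample.int(length(keep), n_keep, replace = TRUE,
                                         prob = w_keep)])
      if (length(retained) < A) break  # stop the run at the last valid subset
      vars <- sort(retained)
      pred <- pls1_cv_pred_cpp(X[, vars, drop = FALSE], y,
                               as.integer(min(A, length(vars))),
                               as.integer(fold_id))
      path_rmsecv[i] <- rmse(y, pred)
      path_sets[[i]] <- vars
    }
    done <- which(!is.na(path_rmsecv))
    if (length(done) == 0) next
    sizes <- lengths(path_sets[done])
    ord <- done[order(path_rmsecv[done], sizes)]
    best_i <- ord[1]
    run_best[[run]] <- list(vars = path_sets[[best_i]],
                            rmsecv = path_rmsecv[best_i])
    best_paths[[run]] <- path_rmsecv
  }
  ok <- !purrr::map_lgl(run_best, is.null)
  if (!any(ok)) abort("All CARS runs terminated before a valid subset.",
                      class = "nirselect_selection_error")
  freq <- numeric(p)
  for (rb in run_best[ok]) freq[rb$vars] <- freq[rb$vars] + 1
  freq <- freq / sum(ok)
  rmsecvs <- purrr::map_dbl(run_best, ~ if (is.null(.x)) Inf else .x$rmsecv)
  sizes <- purrr::map_int(run_best, ~ if (is.null(.x)) NA_integer_ else
    length(.x$vars))
  best_run <- order(rmsecvs, sizes)[1]
  sel_idx <- run_best[[best_run]]$vars
  new_selection_result(
    method = "CARS", selected = sort(wn[sel_idx], decreasing = TRUE),
    scores = tibble::tibble(wavenumber = wn, frequency = freq,
                            selected = seq_len(p) %in% sel_idx),
    rmsecv_path = best_paths[[best_run]],
    chosen_threshold = run_best[[best_run]]$rmsecv, seed = seed)
}
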