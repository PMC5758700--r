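#' Subwindow permutation analysis (SPA)
#'
#' Variable importance from random submodels: each of `N` runs draws
#' `ceiling(R * n)` samples and `Q` variables (from a shuffled round-robin
#' queue so inclusion counts stay balanced), fits a PLS model and records the
#' prediction error on the unsampled samples. For every variable the error
#' distributions of the runs that included it versus those that excluded it
#' are compared with a one-sided rank-sum test (inclusion improves); the
#' conditional synergetic score is `COSS = -log10(P)` and variables with
#' `COSS > coss_min` are selected.
#'
#' @inheritParams cars_select
#' @param N Number of Monte-Carlo runs (default 1000, minimum 100).
#' @param R Fraction of samples drawn per run (default 0.8).
#' @param Q Variables per subwindow (default 10).
#' @param coss_min Selection cutoff on COSS (default 2, i.e. P < 0.01).
#' @return A `selection_result` with per-variable `coss` scores; the
#'   `rmsecv_path` holds the RMSECV of the selected subset.
#' @export
spa_select <- function(x, y = NULL, A = 5, N = 1000, R = 0.8, Q = 10,
                       folds = 10, coss_min = 2, seed = 1) {
  inp <- selection_input(x, y)
  X <- inp$X; y <- inp$y; wn <- inp$wn
  n <- nrow(X); p <- ncol(X)
  if (Q > p) abort("`Q` cannot exceed the variable count.",
                   class = "nirselect_parameter_error")
  if (N < 100) abort("`N` must be at least 100.",
                     class = "nirselect_parameter_error")
  m <- min(n - 2, max(3, ceiling(R * n)))
  set.seed(seed)
  # balanced variable queue: shuffled permutations concatenated, so every
  # variable is included close to N*Q/p times and never left unsampled
  need <- N * Q
  queue <- unlist(replicate(ceiling(need / p), sample.int(p),
                            simplify = FALSE))[seq_len(need)]
  var_runs <- matrix(queue, nrow = Q)  # column j: variables of run j
  err <- rep(NA_real_, N)
  for (run in seq_len(N)) {
    idx <- sample.int(n, m)
    if (length(unique(y[idx])) < 2) { idx <- sample.int(n, m) }
    vars <- var_runs[, run]
    fit <- pls1_coef_cpp(X[idx, vars, drop = FALSE], y[idx],
                         as.integer(min(A, Q, m - 1)))
    hold <- setdiff(seq_len(n), idx)
    pred <- drop(sweep(X[hold, vars, drop = FALSE], 2, drop(fit$x_mean)) %*%
                   fit$b + fit$y_mean)
    err[run] <- rmse(y[hold], pred)
  }
  included <- matrix(FALSE, N, p)
  for (run in seq_len(N)) included[run, var_runs[, run]] <- TRUE
  coss <- vapply(seq_len(p), function(j) {
    e_in <- err[included[, j]]; e_out <- err[!included[, j]]
    if (length(e_in) == 0) {
      abort(sprintf("Variable %d never sampled; increase `N`.", j),
            class = "nirselect_selection_error")
    }
    pval <- suppressWarnings(
      wilcox.test(e_in, e_out, alternative = "less", exact = FALSE)$p.value)
    -log10(max(pval, .Machine$double.xmin))
  }, numeric(1))
  sel_idx <- which(coss > coss_min)
  path <- NA_real_
  if (length(sel_idx) >= 2) {
    fold_id <- make_folds(y, folds, seed + 29L)
    path <- rmse(y, pls1_cv_pred_cpp(X[, sel_idx, drop = FALSE], y,
                                     as.integer(min(A, length(sel_idx))),
                                     as.integer(fold_id)))
  }
  new_selection_result(
    method = "SPA", selected = sort(wn[sel_idx], decreasing = TRUE),
    scores = tibble::tibble(wavenumber = wn, coss = coss,
                            selected = seq_len(p) %in% sel_idx),
    rmsecv_path = path, chosen_threshold = coss_min, seed = seed)
}
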