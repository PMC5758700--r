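#' Monte-Carlo uninformative variable elimination (MC-UVE)
#'
#' Fits a PLS model on `n_mc` random sample subsets and summarizes each
#' variable's regression coefficient by the reliability index
#' `RI = mean(b) / sd(b)` over the draws. Variables are ranked by `|RI|` and
#' added one at a time; the subset size at the global RMSECV minimum is
#' selected and the `|RI|` of the last added variable becomes the threshold.
#'
#' @inheritParams cars_select
#' @param n_mc Monte-Carlo draws (default 500).
#' @param max_add Longest forward-addition prefix evaluated (default 150);
#'   the RMSECV minimum of coefficient-ranked prefixes occurs early, so the
#'   tail of the curve is not computed.
#' @param keep_draws Keep the `n_mc` x p matrix of per-draw coefficients in
#'   the result (for resampling diagnostics such as sign-flip nulls).
#' @return A `selection_result` with per-variable `ri` scores and the
#'   forward-addition `rmsecv_path`.
#' @export
mcuve_select <- function(x, y = NULL, A = 5, n_mc = 500, sample_frac = 0.8,
                         folds = 10, max_add = 150, seed = 1,
                         keep_draws = FALSE) {
  inp <- selection_input(x, y)
  X <- inp$X; y <- inp$y; wn <- inp$wn
  n <- nrow(X); p <- ncol(X)
  m <- max(2, round(sample_frac * n))
  set.seed(seed)
  B <- matrix(0, n_mc, p)
  for (d in seq_len(n_mc)) {
    idx <- sample.int(n, m)
    fit <- pls1_coef_cpp(X[idx, , drop = FALSE], y[idx],
                         as.integer(min(A, m - 1, p)))
    B[d, ] <- drop(fit$b)
  }
  mu <- colMeans(B)
  sdev <- apply(B, 2, sd)
  ri <- mu / sdev
  degenerate <- sdev <= 0
  if (any(degenerate)) {
    warn(sprintf("%d variable(s) with zero coefficient spread; RI set to +Inf.",
                 sum(degenerate)))
    ri[degenerate] <- Inf * sign(mu[degenerate] + (mu[degenerate] == 0))
  }
  ord <- order(-abs(ri), seq_len(p))
  fold_id <- make_folds(y, folds, seed + 11L)
  m_max <- min(max_add, p)
  curve <- vapply(seq_len(m_max), function(k) {
    vars <- ord[seq_len(k)]
    rmse(y, pls1_cv_pred_cpp(X[, vars, drop = FALSE], y,
                             as.integer(min(A, k)), as.integer(fold_id)))
  }, numeric(1))
  k_best <- which.min(curve)
  sel_idx <- ord[seq_len(k_best)]
  out <- new_selection_result(
    method = "MCUVE", selected = sort(wn[sel_idx], decreasing = TRUE),
    scores = tibble::tibble(wavenumber = wn, ri = ri,
                            rank = match(seq_len(p), ord),
                            selected = seq_len(p) %in% sel_idx),
    rmsecv_path = curve, chosen_threshold = abs(ri[ord[k_best]]), seed = seed)
  if (keep_draws) out$coef_draws <- B
  out
}
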