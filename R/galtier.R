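#' Galtier membership verdict from a PLS class-code prediction
#'
#' Classifies each prediction/deviation pair against its candidate class:
#' `"suspicious"` when the deviation reaches the suspicion threshold,
#' `"uncredited"` when the predicted value falls below the smallest class
#' code by more than the uncredited margin (with a deviation below the
#' suspicion threshold), otherwise `"ok"` with the candidate class retained.
#' The rule is one-sided: membership is gained from below, so only
#' predictions under the code range can be denied credit. The 0.45/0.55
#' defaults express a 10% error band around the membership threshold; both
#' are exposed because published applications of the rule are consistent
#' with suspicion cutoffs of 0.45 and 0.50 and uncredited margins up to
#' 0.60.
#'
#' @param candidate_class Integer class being tested (vectorized).
#' @param y_pre Predicted value.
#' @param y_dev Nonnegative deviation of the prediction.
#' @param codes The ordered class codes (default `1:5`).
#' @param suspicious_threshold Deviation at or above which a sample is
#'   suspicious (default 0.45).
#' @param uncredited_margin Distance below the smallest class code at or
#'   beyond which a sample is not credited to the training set
#'   (default 0.55).
#' @return A tibble of class `galtier_verdict`: `candidate_class`, `y_pre`,
#'   `y_dev`, `flag`.
#' @examples
#' galtier_verdict(1, 1.782, 0.553)$flag # suspicious
#' galtier_verdict(1, 0.380, 0.438)$flag # uncredited
#' galtier_verdict(2, 2.084, 0.059)$flag # ok
#' @export
galtier_verdict <- function(candidate_class, y_pre, y_dev, codes = 1:5,
                            suspicious_threshold = 0.45,
                            uncredited_margin = 0.55) {
  if (any(y_dev < 0)) abort("`y_dev` must be nonnegative.",
                            class = "nirselect_parameter_error")
  n <- max(length(candidate_class), length(y_pre), length(y_dev))
  candidate_class <- rep_len(as.integer(candidate_class), n)
  y_pre <- rep_len(y_pre, n); y_dev <- rep_len(y_dev, n)
  lo <- min(codes)
  flag <- dplyr::case_when(
    y_dev >= suspicious_threshold ~ "suspicious",
    y_pre <= lo - uncredited_margin ~ "uncredited",
    TRUE ~ "ok")
  out <- tibble::tibble(candidate_class = candidate_class,
                        y_pre = y_pre, y_dev = y_dev, flag = flag)
  class(out) <- c("galtier_verdict", class(out))
  out
}

#' Membership accuracy of a verdict table
#'
#' Percentage of samples flagged `"ok"` whose candidate class equals the
#' actual class, reported to 2 decimals.
#'
#' @param verdicts A [galtier_verdict()] tibble.
#' @param actual Actual classes, same length.
#' @return A percentage (0..100) rounded to 2 decimals.
#' @export
set_accuracy <- function(verdicts, actual) {
  if (nrow(verdicts) == 0) abort("Empty verdict table.",
                                 class = "nirselect_parameter_error")
  round(100 * mean(verdicts$flag == "ok" &
                     verdicts$candidate_class == as.integer(actual)), 2)
}

#' Prediction deviation from fold-jackknife models
#'
#' The package's own estimator of the deviation Y_dev for fresh data: refit
#' the PLS model on each fold's training complement and report, per new
#' sample, half the range of the fold-model predictions. The verdict rule
#' itself accepts (y_pre, y_dev) from any source.
#'
#' @param X,y Training matrix and class codes.
#' @param X_new Samples to predict.
#' @param A Latent variables.
#' @param folds,seed Fold assignment as in [cross_validate()].
#' @return A tibble with `y_pre` (full-model prediction) and `y_dev`.
#' @export
predict_with_deviation <- function(X, y, X_new, A = 5, folds = 10, seed = 1) {
  X <- as.matrix(X); X_new <- as.matrix(X_new); y <- as.numeric(y)
  fold_id <- make_folds(y, folds, seed)
  full <- pls_fit(X, y, A = min(A, nrow(X) - 1, ncol(X)))
  y_pre <- predict(full, X_new)
  preds <- vapply(seq_len(max(fold_id)), function(k) {
    idx <- fold_id != k
    m <- pls1_coef_cpp(X[idx, , drop = FALSE], y[idx],
                       as.integer(min(A, sum(idx) - 1, ncol(X))))
    drop(sweep(X_new, 2, drop(m$x_mean)) %*% m$b + m$y_mean)
  }, numeric(nrow(X_new)))
  preds <- matrix(preds, nrow = nrow(X_new))
  y_dev <- (apply(preds, 1, max) - apply(preds, 1, min)) / 2
  tibble::tibble(y_pre = y_pre, y_dev = y_dev)
}
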