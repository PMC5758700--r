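#' Hotelling T-squared of score rows
#'
#' T2 of sample i is the sum over score columns of t_ij^2 / var(t_.j).
#'
#' @param scores Numeric matrix, samples x components.
#' @return Numeric vector of per-sample T2 values.
#' @export
hotelling_t2 <- function(scores) {
  scores <- as.matrix(scores)
  v <- apply(scores, 2, var)
  if (any(v <= 0)) abort("Zero-variance score column.",
                         class = "nirselect_degenerate_error")
  rowSums(sweep(scores^2, 2, v, "/"))
}

#' Hotelling T-squared control limit
#'
#' `k (n - 1) / (n - k)` times the F quantile at `alpha` with `(k, n - k)`
#' degrees of freedom.
#'
#' @param n Number of samples.
#' @param k Number of score components.
#' @param alpha Confidence level (e.g. 0.95 or 0.99).
#' @return The T2 limit.
#' @export
t2_limit <- function(n, k, alpha) {
  if (k < 1 || n <= k) abort("Require n > k >= 1.",
                             class = "nirselect_parameter_error")
  k * (n - 1) / (n - k) * qf(alpha, k, n - k)
}

# Jackson-Mudholkar limit for the squared reconstruction residual Q,
# from the discarded eigenvalues of the PCA.
q_limit <- function(resid_eigen, alpha) {
  resid_eigen <- resid_eigen[resid_eigen > .Machine$double.eps]
  if (length(resid_eigen) == 0) return(0)
  th1 <- sum(resid_eigen); th2 <- sum(resid_eigen^2); th3 <- sum(resid_eigen^3)
  h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
  if (!is.finite(h0) || h0 <= 0) h0 <- 1e-3
  ca <- qnorm(alpha)
  th1 * (ca * sqrt(2 * th2 * h0^2) / th1 + 1 + th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
}

#' Iterative PCA outlier removal
#'
#' Fits a PCA with `k` components, computes per-sample Hotelling T2 (score
#' space) and squared reconstruction residual Q, and removes the single worst
#' sample exceeding its `alpha` control limit (largest T2 first, then largest
#' Q; ties by lowest sample id). Refits and repeats until no sample exceeds a
#' limit or `max_iter` is reached.
#'
#' @param s A [spectra_set()] with `n > k + 2` samples.
#' @param k Number of PCA components (default 5).
#' @param alpha Control-limit confidence level (default 0.99).
#' @param max_iter Maximum removals (0 returns the input unchanged).
#' @return A list with `spectra` (the surviving [spectra_set()]) and `report`
#'   (class `outlier_report`: `removed_ids` and a per-iteration tibble of
#'   T2/Q values and limits).
#' @export
iterative_outlier_removal <- function(s, k = 5, alpha = 0.99, max_iter = 10) {
  if (nrow(s$absorbance) <= k + 2) {
    abort("Need n > k + 2 samples.", class = "nirselect_parameter_error")
  }
  n0 <- nrow(s$absorbance)
  removed <- character(0)
  log_rows <- list()
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    X <- s$absorbance
    n <- nrow(X)
    pc <- prcomp(X, center = TRUE, scale. = FALSE)
    kk <- min(k, ncol(pc$x))
    scores <- pc$x[, seq_len(kk), drop = FALSE]
    t2 <- hotelling_t2(scores)
    t2l <- t2_limit(n, kk, alpha)
    recon <- scores %*% t(pc$rotation[, seq_len(kk), drop = FALSE])
    Xc <- scale(X, center = TRUE, scale = FALSE)
    qres <- rowSums((Xc - recon)^2)
    ql <- q_limit(pc$sdev[-seq_len(kk)]^2, alpha)
    log_rows[[iter]] <- tibble::tibble(
      iteration = iter, sample_id = s$meta$sample_id,
      t2 = t2, t2_limit = t2l, q = qres, q_limit = ql)
    over_t2 <- which(t2 > t2l)
    over_q <- which(qres > ql)
    if (length(over_t2) > 0) {
      worst <- over_t2[order(-t2[over_t2], s$meta$sample_id[over_t2])][1]
    } else if (length(over_q) > 0) {
      worst <- over_q[order(-qres[over_q], s$meta$sample_id[over_q])][1]
    } else break
    removed <- c(removed, s$meta$sample_id[worst])
    if (length(removed) > 0.2 * n0) {
      abort(sprintf(
        "Outlier screening would remove more than 20%% of samples (%d of %d).",
        length(removed), n0), class = "nirselect_qc_error")
    }
    s <- subset_samples(s, -worst)
  }
  report <- structure(
    list(removed_ids = removed,
         iterations = if (length(log_rows)) dplyr::bind_rows(log_rows) else
           tibble::tibble(iteration = integer(), sample_id = character(),
                          t2 = numeric(), t2_limit = numeric(),
                          q = numeric(), q_limit = numeric())),
    class = "outlier_report")
  list(spectra = s, report = report)
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> %d sample(s) removed",
              length(x$removed_ids)))
  if (length(x$removed_ids)) cat(":", paste(x$removed_ids, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' @export
tidy.outlier_report <- function(x, ...) x$iterations
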