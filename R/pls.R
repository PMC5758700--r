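#' Fit a PLS1 model of class codes on spectra
#'
#' NIPALS partial least squares with a single numeric response: the region
#' class code (1..5). This is the PLS-DA variant whose predicted value spans
#' the class-code range, so one regression vector `b` drives both prediction
#' and the coefficient-based selection algorithms.
#'
#' @param X Numeric matrix, samples x variables (column names are treated as
#'   wavenumbers when present).
#' @param y Numeric class codes (at least 2 distinct values).
#' @param A Number of latent variables, `A <= min(n - 1, p)`.
#' @return A `pls_model`: regression vector `b`, x/y centering offsets,
#'   weights, loadings, scores and fitted values.
#' @export
pls_fit <- function(X, y, A = 5) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(unique(y)) < 2) abort("Need at least 2 distinct class codes.",
                                   class = "nirselect_fit_error")
  if (A < 1 || A > min(n - 1, p)) {
    abort("`A` must be between 1 and min(n - 1, p).",
          class = "nirselect_fit_error")
  }
  fit <- pls1_fit_cpp(X, y, as.integer(A))
  if (fit$n_components < A) {
    abort(sprintf("Rank deficiency: only %d component(s) achievable (requested %d).",
                  fit$n_components, A), class = "nirselect_fit_error")
  }
  structure(list(b = drop(fit$b), x_mean = drop(fit$x_mean),
                 y_mean = fit$y_mean, weights = fit$weights,
                 loadings = fit$loadings, scores = fit$scores,
                 y_loadings = drop(fit$y_loadings),
                 fitted = drop(fit$fitted), n_components = fit$n_components,
                 wavenumbers = suppressWarnings(as.numeric(colnames(X))),
                 class_codes = sort(unique(round(y)))),
            class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(sweep(newdata, 2, object$x_mean) %*% object$b + object$y_mean)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variable(s), %d spectral variables\n",
              x$n_components, length(x$b)))
  invisible(x)
}

#' @export
tidy.pls_model <- function(x, ...) {
  tibble::tibble(
    wavenumber = if (all(is.na(x$wavenumbers))) seq_along(x$b) else x$wavenumbers,
    coefficient = x$b)
}

#' @export
glance.pls_model <- function(x, ...) {
  tibble::tibble(n_components = x$n_components, n_variables = length(x$b),
                 y_mean = x$y_mean)
}

# stratified fold assignment for class-coded responses; guarantees every
# fold's *training* complement contains all classes (refolds with a warning
# otherwise). A response with more distinct values than folds is treated as
# continuous and assigned plain random folds.
make_folds <- function(y, folds, seed, max_tries = 20) {
  shuffle <- function(x) x[sample.int(length(x))]
  if (length(unique(y)) > folds) {
    set.seed(seed)
    return(shuffle(rep_len(seq_len(folds), length(y))))
  }
  for (try in seq_len(max_tries)) {
    set.seed(seed + try - 1)
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- shuffle(rep_len(seq_len(folds), length(idx)))
    }
    ok <- all(vapply(seq_len(folds), function(k) {
      tr <- y[fold != k]
      length(tr) > 0 && all(unique(y) %in% tr)
    }, logical(1)))
    if (ok) return(fold)
    warn("A fold's training complement missed a class; refolding.")
  }
  abort("Could not build class-covering folds.", class = "nirselect_cv_error")
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

#' Cross-validated PLS metrics
#'
#' Stratified-by-class k-fold cross validation. RMSECV is computed over the
#' held-out predictions, R2 on the training fit, and RMSEP on an explicit
#' validation set when supplied.
#'
#' @param X,y Training matrix and class codes.
#' @param A Latent variables.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @param X_val,y_val Optional validation set for RMSEP.
#' @param fold_id Optional explicit fold assignment (overrides `seed`), used
#'   to compare variable subsets on identical folds.
#' @return A one-row tibble of class `cv_metrics`: `rmsecv`, `r2`, `rmsep`,
#'   `folds`, `seed`.
#' @export
cross_validate <- function(X, y, A = 5, folds = 10, seed = 1,
                           X_val = NULL, y_val = NULL, fold_id = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (folds > nrow(X)) abort("`folds` cannot exceed n.",
                             class = "nirselect_cv_error")
  if (is.null(fold_id)) fold_id <- make_folds(y, folds, seed)
  A_use <- min(A, nrow(X) - ceiling(nrow(X) / folds) - 1, ncol(X))
  pred <- pls1_cv_pred_cpp(X, y, as.integer(A_use), as.integer(fold_id))
  fit <- pls1_fit_cpp(X, y, as.integer(min(A, nrow(X) - 1, ncol(X))))
  r2 <- 1 - sum((y - fit$fitted)^2) / sum((y - mean(y))^2)
  rmsep <- NA_real_
  if (!is.null(X_val)) {
    pv <- drop(sweep(as.matrix(X_val), 2, drop(fit$x_mean)) %*% fit$b + fit$y_mean)
    rmsep <- rmse(as.numeric(y_val), pv)
  }
  out <- tibble::tibble(rmsecv = rmse(y, pred), r2 = r2, rmsep = rmsep,
                        folds = folds, seed = seed)
  class(out) <- c("cv_metrics", class(out))
  out
}

#' PCA with the Kaiser retention rule
#'
#' Standardizes the input (the Kaiser rule reads eigenvalues on the
#' correlation scale) and retains the components with eigenvalue >= 1.
#'
#' @param X Numeric matrix with at least 3 rows.
#' @return A list: `scores`, `loadings`, `eigenvalues`, `k_retained`,
#'   `cum_variance` (fraction explained by the retained components).
#' @export
pca_kaiser <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 3) abort("Need at least 3 samples for PCA.",
                         class = "nirselect_parameter_error")
  sds <- apply(X, 2, sd)
  keep <- sds > 0
  if (!all(keep)) warn(sprintf("Dropping %d zero-variance variable(s).",
                               sum(!keep)))
  pc <- prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  k <- sum(ev >= 1)
  list(scores = pc$x, loadings = pc$rotation, eigenvalues = ev,
       k_retained = k, cum_variance = sum(ev[seq_len(max(k, 1))]) / sum(ev))
}
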