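# Wilks' lambda of a variable subset: det(W)/det(T) with W the pooled
# within-group and T the total SSCP matrix.
wilks_lambda <- function(X, labels, vars) {
  Xs <- X[, vars, drop = FALSE]
  n <- nrow(Xs)
  Tm <- crossprod(scale(Xs, center = TRUE, scale = FALSE))
  Wm <- matrix(0, length(vars), length(vars))
  for (cls in unique(labels)) {
    Xi <- Xs[labels == cls, , drop = FALSE]
    Wm <- Wm + crossprod(scale(Xi, center = TRUE, scale = FALSE))
  }
  dT <- det(Tm)
  if (!is.finite(dT) || dT <= 0) return(NA_real_)
  det(Wm) / dT
}

#' Stepwise Wilks-lambda variable screening
#'
#' Classic stepwise discriminant screening: at each step the candidate
#' variable with the largest partial F statistic enters if it reaches
#' `f_enter`; entered variables whose partial F falls below `f_remove` are
#' removed. The procedure stops when no entry or removal changes the set.
#'
#' @param X Numeric matrix (wavenumber column names) of candidate variables.
#' @param labels Class labels.
#' @param f_enter,f_remove Partial-F thresholds (defaults 3.84 / 2.71, the
#'   conventional stepwise discriminant defaults).
#' @param max_vars Optional cap on the retained set size.
#' @return A list: `retained` (wavenumbers, in entry order) and `trace`
#'   (tibble of step, action, variable, Wilks lambda, partial F).
#' @export
stepwise_select <- function(X, labels, f_enter = 3.84, f_remove = 2.71,
                            max_vars = Inf) {
  X <- as.matrix(X)
  wn <- suppressWarnings(as.numeric(colnames(X)))
  if (length(wn) == 0 || anyNA(wn)) wn <- seq_len(ncol(X))
  labels <- as.integer(labels)
  n <- nrow(X); g <- length(unique(labels))
  current <- integer(0)
  lambda_cur <- 1
  trace <- list(); step <- 0
  partial_f_enter <- function(v) {
    lam_new <- wilks_lambda(X, labels, c(current, v))
    if (!is.finite(lam_new) || lam_new <= 0) return(c(NA_real_, NA_real_))
    pf <- (n - g - length(current)) / (g - 1) * (lambda_cur / lam_new - 1)
    c(pf, lam_new)
  }
  repeat {
    changed <- FALSE
    if (length(current) < max_vars && n > g + length(current) + 1) {
      cand <- setdiff(seq_len(ncol(X)), current)
      if (length(cand) > 0) {
        stats <- vapply(cand, partial_f_enter, numeric(2))
        pf <- stats[1, ]
        if (any(is.finite(pf)) && max(pf, na.rm = TRUE) >= f_enter) {
          best <- cand[which.max(pf)]
          lambda_cur <- stats[2, which.max(pf)]
          current <- c(current, best)
          step <- step + 1
          trace[[length(trace) + 1]] <- tibble::tibble(
            step = step, action = "enter", wavenumber = wn[best],
            wilks = lambda_cur, partial_f = max(pf, na.rm = TRUE))
          changed <- TRUE
        }
      }
    }
    # removal pass
    if (length(current) > 1) {
      repeat {
        pfs <- vapply(seq_along(current), function(i) {
          lam_wo <- wilks_lambda(X, labels, current[-i])
          if (!is.finite(lam_wo) || lam_wo <= 0) return(NA_real_)
          (n - g - length(current) + 1) / (g - 1) * (lam_wo / lambda_cur - 1)
        }, numeric(1))
        if (!any(is.finite(pfs)) || min(pfs, na.rm = TRUE) >= f_remove) break
        drop_i <- which.min(pfs)
        dropped <- current[drop_i]
        current <- current[-drop_i]
        lambda_cur <- wilks_lambda(X, labels, current)
        step <- step + 1
        trace[[length(trace) + 1]] <- tibble::tibble(
          step = step, action = "remove", wavenumber = wn[dropped],
          wilks = lambda_cur, partial_f = min(pfs, na.rm = TRUE))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(current) == 0) warn("No variable reached `f_enter`; empty retention.")
  list(retained = wn[current],
       trace = if (length(trace)) dplyr::bind_rows(trace) else
         tibble::tibble(step = integer(), action = character(),
                        wavenumber = numeric(), wilks = numeric(),
                        partial_f = numeric()))
}

#' Fit Fisher linear classification functions
#'
#' Per-class linear score functions on the retained variables: coefficients
#' `W^-1 mu_c` and constant `-mu_c' W^-1 mu_c / 2 + log(prior_c)`, with `W`
#' the pooled within-class covariance. Under equal priors the score argmax is
#' the nearest class centroid in Mahalanobis distance. A singular `W` is
#' ridged by `1e-8 tr(W)/p` with a warning.
#'
#' @param X Numeric matrix of the retained variables (wavenumber column
#'   names).
#' @param labels Class labels (each class needs >= 2 samples).
#' @param priors Class priors; `"equal"` (default) or a named numeric vector.
#' @return A `fisher_model`: per-class coefficients and constants, class
#'   centroids, pooled covariance and the variable wavenumbers.
#' @export
fisher_fit <- function(X, labels, priors = "equal") {
  fisher_fit_impl(X, labels, priors = priors, min_class = 2L)
}

# min_class = 1 lets leave-one-out refits keep a class whose only other
# member was held out; a singleton class contributes nothing to the pooled
# covariance but keeps its centroid.
fisher_fit_impl <- function(X, labels, priors = "equal", min_class = 2L) {
  X <- as.matrix(X)
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  counts <- table(factor(labels, levels = classes))
  if (any(counts < min_class)) {
    abort("Every class needs at least 2 samples.",
          class = "nirselect_fit_error")
  }
  n <- nrow(X); p <- ncol(X); g <- length(classes)
  cents <- vapply(classes, function(cls)
    colMeans(X[labels == cls, , drop = FALSE]), numeric(p))
  centroids <- if (is.matrix(cents)) t(cents) else matrix(cents, ncol = 1)
  W <- matrix(0, p, p)
  for (cls in classes) {
    Xi <- X[labels == cls, , drop = FALSE]
    W <- W + crossprod(scale(Xi, center = TRUE, scale = FALSE))
  }
  W <- W / (n - g)
  if (!is.finite(rcond(W)) || rcond(W) < 1e-12) {
    # trace can be zero under exact separation; fall back to an absolute ridge
    eps <- max(1e-8 * sum(diag(W)) / p, 1e-12)
    warn(sprintf("Singular pooled covariance; ridged by %.3g.", eps))
    W <- W + diag(eps, p)
  }
  pr <- if (identical(priors, "equal")) rep(1 / g, g) else
    as.numeric(priors)[seq_len(g)]
  Winv_mu <- t(solve(W, t(centroids)))
  consts <- -0.5 * rowSums(Winv_mu * centroids) + log(pr)
  wn <- suppressWarnings(as.numeric(colnames(X)))
  if (length(wn) == 0 || anyNA(wn)) wn <- seq_len(p)
  structure(list(classes = classes, coefficients = Winv_mu,
                 constants = consts, centroids = centroids,
                 pooled_cov = W, priors = pr, wavenumbers = wn),
            class = "fisher_model")
}

#' @export
print.fisher_model <- function(x, ...) {
  cat(sprintf("<fisher_model> %d classes, %d variable(s)\n",
              length(x$classes), length(x$wavenumbers)))
  invisible(x)
}

#' @export
tidy.fisher_model <- function(x, ...) {
  coef_tbl <- tibble::as_tibble(x$coefficients, .name_repair = "minimal")
  names(coef_tbl) <- format_wavenumber(x$wavenumbers)
  dplyr::bind_cols(tibble::tibble(class = x$classes,
                                  constant = x$constants), coef_tbl) |>
    tidyr::pivot_longer(-c("class", "constant"), names_to = "wavenumber",
                        values_to = "coefficient") |>
    dplyr::mutate(wavenumber = as.numeric(.data$wavenumber))
}

#' @export
glance.fisher_model <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes),
                 n_variables = length(x$wavenumbers))
}

#' Classify samples with a Fisher model
#'
#' Scores each sample against every class function and returns the argmax
#' class; exact ties resolve to the lowest class code.
#'
#' @param m A [fisher_fit()] model.
#' @param x Numeric matrix or vector with the model's variables.
#' @return Integer vector of class assignments.
#' @export
fisher_classify <- function(m, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != length(m$wavenumbers)) {
    abort("Input is missing model variables.", class = "nirselect_input_error")
  }
  scores <- x %*% t(m$coefficients) + matrix(m$constants, nrow(x),
                                             length(m$classes), byrow = TRUE)
  m$classes[apply(scores, 1, which.max)]  # which.max takes the first (lowest) tie
}

#' @export
predict.fisher_model <- function(object, newdata, ...) {
  fisher_classify(object, newdata)
}

#' Leave-one-out cross validation of the Fisher model
#'
#' Refits the model without each sample in turn and classifies it; reports
#' the accuracy (2 decimals) and the classes-by-classes confusion table.
#'
#' @param X,labels Data and classes (`n >= 2 * n_classes`).
#' @param priors Passed to [fisher_fit()].
#' @return A list: `accuracy`, `confusion` (table), `assignments` tibble.
#' @export
loo_cross_validate <- function(X, labels, priors = "equal") {
  X <- as.matrix(X)
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  if (nrow(X) < 2 * length(classes)) {
    abort("Need at least 2 samples per class on average for LOO.",
          class = "nirselect_fit_error")
  }
  pred <- vapply(seq_len(nrow(X)), function(i) {
    m <- fisher_fit_impl(X[-i, , drop = FALSE], labels[-i], priors = priors,
                         min_class = 1L)
    fisher_classify(m, X[i, ])
  }, integer(1))
  confusion <- table(actual = factor(labels, levels = classes),
                     predicted = factor(pred, levels = classes))
  list(accuracy = round(100 * mean(pred == labels), 2),
       confusion = confusion,
       assignments = tibble::tibble(actual = labels, predicted = pred))
}
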