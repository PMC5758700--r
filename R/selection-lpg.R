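#' Latent projective graph (LPG) vertex detection
#'
#' Projects every spectral variable onto the PC1-PC2 loading plane of a PCA
#' of the spectra. Collinear (mutually redundant) variables fall on straight
#' segments of the wavenumber-ordered polyline through that plane;
#' informative variables sit at its vertices. A variable is selected when its
#' turning angle exceeds `angle_min` or it lies on the convex hull of the
#' loading cloud (both evaluated in the axis-standardized plane). The default
#' `angle_min` of 90 degrees marks points where the polyline genuinely
#' reverses direction - absorption-band vertices turn by 110-180 degrees,
#' while smooth collinear stretches and ordinary noise wiggle stay well
#' below a right angle. A turning vertex must also lie outside the central
#' cloud of near-zero loadings (`radius_min_quantile`): the farther a
#' variable sits from the origin of the loading plane, the more it
#' contributes to the latent structure, whereas variables at the origin turn
#' sharply only because their loadings are noise.
#'
#' @param x A [spectra_set()] or numeric matrix (wavenumber column names).
#' @param y Ignored; present for interface symmetry with the other selectors.
#' @param n_pcs Number of principal components for the loading plane
#'   (default 2).
#' @param angle_min Turning-angle threshold in degrees (default 90).
#' @param radius_min_quantile Quantile of the loading-plane radius a turning
#'   vertex must exceed (default 0.5; convex-hull points are exempt).
#' @return A `selection_result` with per-variable `angle`, `radius` and
#'   `hull` scores.
#' @export
lpg_select <- function(x, y = NULL, n_pcs = 2, angle_min = 90,
                       radius_min_quantile = 0.5) {
  inp <- if (inherits(x, "spectra_set")) {
    list(X = x$absorbance, wn = x$grid$points)
  } else {
    X <- as.matrix(x)
    wn <- suppressWarnings(as.numeric(colnames(X)))
    if (length(wn) == 0 || anyNA(wn)) wn <- seq_len(ncol(X))
    list(X = X, wn = wn)
  }
  X <- inp$X; wn <- inp$wn
  p <- ncol(X)
  if (p < 3) abort("LPG needs at least 3 variables.",
                   class = "nirselect_parameter_error")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  L <- pc$rotation[, seq_len(min(n_pcs, ncol(pc$rotation))), drop = FALSE]
  spread <- apply(L, 2, sd)
  if (all(pc$sdev < 1e-12) || all(spread <= .Machine$double.eps)) {
    warn("Degenerate loadings: all variables project to one point.")
    return(new_selection_result(
      method = "LPG", selected = numeric(0),
      scores = tibble::tibble(wavenumber = wn, angle = NA_real_,
                              hull = FALSE, selected = FALSE),
      rmsecv_path = NA_real_, chosen_threshold = angle_min, seed = NA_integer_))
  }
  Ls <- sweep(L, 2, pmax(spread, .Machine$double.eps), "/")
  # turning angle at each interior variable of the wavenumber-ordered polyline
  angle <- rep(NA_real_, p)
  for (i in 2:(p - 1)) {
    a <- Ls[i, ] - Ls[i - 1, ]
    b <- Ls[i + 1, ] - Ls[i, ]
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na <= .Machine$double.eps || nb <= .Machine$double.eps) {
      angle[i] <- 0
    } else {
      cosv <- min(1, max(-1, sum(a * b) / (na * nb)))
      angle[i] <- acos(cosv) * 180 / pi
    }
  }
  hull <- rep(FALSE, p)
  hull[grDevices::chull(Ls[, 1], Ls[, 2])] <- TRUE
  radius <- sqrt(rowSums(Ls^2))
  r_min <- stats::quantile(radius, radius_min_quantile, names = FALSE)
  sel <- hull | (!is.na(angle) & angle > angle_min & radius >= r_min)
  new_selection_result(
    method = "LPG", selected = sort(wn[sel], decreasing = TRUE),
    scores = tibble::tibble(wavenumber = wn, angle = angle, radius = radius,
                            hull = hull, selected = sel),
    rmsecv_path = NA_real_, chosen_threshold = angle_min, seed = NA_integer_)
}
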