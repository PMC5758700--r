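#' Write and read result objects as JSON
#'
#' Selection results and Fisher models serialize to JSON so runs can be
#' archived and replayed; the Fisher layout mirrors the published coefficient
#' tables (per-class constant plus per-variable coefficients keyed by
#' wavenumber).
#'
#' @param x A `selection_result` or `fisher_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @name result-json
NULL

#' @rdname result-json
#' @export
write_selection_json <- function(x, path) {
  stopifnot(inherits(x, "selection_result"))
  payload <- list(method = x$method, selected = x$selected,
                  scores = x$scores, rmsecv_path = x$rmsecv_path,
                  chosen_threshold = x$chosen_threshold, seed = x$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname result-json
#' @export
write_fisher_json <- function(x, path) {
  stopifnot(inherits(x, "fisher_model"))
  per_class <- purrr::map(seq_along(x$classes), function(i) {
    list(class = x$classes[i], constant = x$constants[i],
         coefficients = setNames(as.list(x$coefficients[i, ]),
                                 format_wavenumber(x$wavenumbers)),
         centroid = setNames(as.list(x$centroids[i, ]),
                             format_wavenumber(x$wavenumbers)))
  })
  payload <- list(wavenumbers = x$wavenumbers, priors = x$priors,
                  classes = per_class,
                  pooled_cov = x$pooled_cov)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname result-json
#' @param path Path of a JSON file written by [write_fisher_json()].
#' @export
read_fisher_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(j$wavenumbers)
  g <- nrow(j$classes)
  coefs <- do.call(rbind, lapply(seq_len(g), function(i)
    unlist(j$classes$coefficients[i, , drop = TRUE])))
  cents <- do.call(rbind, lapply(seq_len(g), function(i)
    unlist(j$classes$centroid[i, , drop = TRUE])))
  structure(list(classes = as.integer(j$classes$class),
                 coefficients = unname(coefs),
                 constants = as.numeric(j$classes$constant),
                 centroids = unname(cents),
                 pooled_cov = matrix(unlist(j$pooled_cov), p, p),
                 priors = as.numeric(j$priors),
                 wavenumbers = as.numeric(j$wavenumbers)),
            class = "fisher_model")
}
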