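#' @export
autoplot.spectra_set <- function(object, colour = "region_class", n_max = 60,
                                 ...) {
  df <- tidy(object)
  if (length(unique(df$sample_id)) > n_max) {
    keep <- unique(df$sample_id)[seq_len(n_max)]
    df <- dplyr::filter(df, .data$sample_id %in% keep)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavenumber, y = .data$absorbance,
                                   group = .data$sample_id,
                                   colour = factor(.data[[colour]]))) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(Wavenumber ~ (cm^-1)), y = "Absorbance",
                  colour = colour) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.selection_result <- function(object, ...) {
  score_col <- setdiff(names(object$scores),
                       c("wavenumber", "selected", "rank", "hull"))[1]
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$wavenumber, y = .data[[score_col]])) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::geom_point(data = dplyr::filter(object$scores, .data$selected),
                        colour = "red", size = 0.8, na.rm = TRUE) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(title = object$method, x = expression(Wavenumber ~ (cm^-1)),
                  y = score_col) +
    ggplot2::theme_minimal()
}

#' PCA score plot of one or two tissues
#'
#' @param s A [spectra_set()].
#' @param colour Metadata column mapped to colour (default `"tissue"`).
#' @return A ggplot object.
#' @export
plot_pca_scores <- function(s, colour = "tissue") {
  pc <- pca_kaiser(s$absorbance)
  df <- dplyr::bind_cols(s$meta,
                         tibble::tibble(PC1 = pc$scores[, 1],
                                        PC2 = pc$scores[, 2]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = factor(.data[[colour]]))) +
    ggplot2::geom_point() +
    ggplot2::labs(colour = colour) +
    ggplot2::theme_minimal()
}
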