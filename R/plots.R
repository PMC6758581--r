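# ggplot2 displays for the main result types.

#' @rdname compare_models
#' @param object A `model_comparison`.
#' @method autoplot model_comparison
#' @export
autoplot.model_comparison <- function(object, ...) {
  tab <- object$table
  tab$model <- factor(tab$model, levels = tab$model[order(tab$aicc)])
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$model, y = .data$weight)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "Akaike weight",
                  title = paste0("Model comparison (best: ", object$best, ")")) +
    ggplot2::theme_minimal()
}

#' Plot per-syndrome evolutionary optima with confidence intervals
#'
#' @param optima Tibble from [estimate_theta_uncertainty()] (optionally
#'   with a `trait` column from the pipeline report).
#' @param natural Plot the back-transformed scale when available.
#' @return A ggplot object.
#' @export
plot_optima <- function(optima, natural = TRUE) {
  use_nat <- natural && "theta_natural" %in% names(optima)
  y <- if (use_nat) "theta_natural" else "theta"
  lo <- if (use_nat) "ci_lower_natural" else "ci_lower"
  hi <- if (use_nat) "ci_upper_natural" else "ci_upper"
  optima$regime <- factor(optima$regime,
                          levels = intersect(c(syndrome_levels(), "all"),
                                             unique(optima$regime)))
  p <- ggplot2::ggplot(optima,
                       ggplot2::aes(x = .data$regime, y = .data[[y]])) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data[[lo]],
                                        ymax = .data[[hi]]), width = 0.2) +
    ggplot2::labs(x = "pollination syndrome",
                  y = if (use_nat) "optimum (natural scale)"
                      else "optimum (analysis scale)") +
    ggplot2::theme_minimal()
  if ("trait" %in% names(optima)) {
    p <- p + ggplot2::facet_wrap(~trait, scales = "free_y")
  }
  p
}

#' @rdname nectar_pca
#' @param object A `nectar_pca`.
#' @param axes Which two axes to draw.
#' @param syndromes Optional named syndrome vector to colour points.
#' @param ... Unused.
#' @method autoplot nectar_pca
#' @export
autoplot.nectar_pca <- function(object, axes = c(1, 2), syndromes = NULL,
                                ...) {
  sc <- object$scores
  ax <- paste0("PC", axes)
  ve <- round(100 * object$variance_explained[axes], 1)
  df <- sc[, c("species", ax)]
  names(df) <- c("species", "x", "y")
  if (!is.null(syndromes)) df$syndrome <- unname(syndromes[df$species])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  p <- if (is.null(syndromes)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$syndrome))
  p + ggplot2::labs(x = paste0(ax[1], " (", ve[1], "%)"),
                    y = paste0(ax[2], " (", ve[2], "%)")) +
    ggplot2::theme_minimal()
}
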