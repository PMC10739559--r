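#' Attribution summary plots
#'
#' `plot_attribution_summary()` is a beeswarm-style view of one
#' classifier's attributions: one point per sample and feature, the
#' attribution value on the x axis (near-zero values mean negligible
#' impact; positive values push toward a case call), features on the y
#' axis sorted by mean absolute attribution (most important on top), and
#' point colour encoding the feature's min-max scaled value.
#' `plot_importance_bar()` shows the mean absolute attribution per feature
#' as bars. A degenerate (all-zero) attribution matrix yields a bar plot
#' of zeros with a warning watermark.
#'
#' @param att an `igene_attribution` from [compute_attributions()].
#' @param x the matrix of explained samples (for the value colouring).
#' @param top_n number of features to display, most important first.
#'   Default 10.
#' @return a ggplot object.
#' @export
plot_attribution_summary <- function(att, x, top_n = 10) {
  stopifnot(inherits(att, "igene_attribution"))
  x <- as.matrix(x)[, colnames(att$phi), drop = FALSE]
  imp <- colMeans(abs(att$phi))
  if (all(imp == 0)) {
    return(degenerate_plot(att))
  }
  top_n <- min(top_n, ncol(att$phi))
  keep <- names(sort(imp, decreasing = TRUE))[seq_len(top_n)]
  long <- purrr::map_dfr(keep, function(f) {
    v <- x[, f]
    rng <- diff(range(v))
    tibble::tibble(
      feature = f,
      phi = att$phi[, f],
      value = if (rng == 0) 0.5 else (v - min(v)) / rng
    )
  })
  long$feature <- factor(long$feature, levels = rev(keep))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$phi, y = .data$feature,
                                     colour = .data$value)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_jitter(alpha = 0.7,
                         position = ggplot2::position_jitter(
                           height = 0.2, width = 0, seed = 1)) +
    ggplot2::scale_colour_gradient(low = "#3b4cc0", high = "#b40426",
                                   name = "feature value\n(scaled)") +
    ggplot2::labs(x = "attribution (impact on case probability)", y = NULL,
                  title = sprintf("Attribution summary: %s", att$classifier)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_attribution_summary
#' @export
plot_importance_bar <- function(att, top_n = 10) {
  stopifnot(inherits(att, "igene_attribution"))
  imp <- sort(colMeans(abs(att$phi)), decreasing = TRUE)
  if (all(imp == 0)) {
    return(degenerate_plot(att))
  }
  top_n <- min(top_n, length(imp))
  df <- tibble::tibble(feature = factor(names(imp)[seq_len(top_n)],
                                        levels = rev(names(imp)[seq_len(top_n)])),
                       importance = imp[seq_len(top_n)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_col(fill = "#3b4cc0") +
    ggplot2::labs(x = "mean |attribution|", y = NULL,
                  title = sprintf("Global importance: %s", att$classifier)) +
    ggplot2::theme_minimal()
}

degenerate_plot <- function(att) {
  rlang::warn(sprintf("attribution matrix for '%s' is all zero", att$classifier))
  df <- tibble::tibble(feature = colnames(att$phi),
                       importance = 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::annotate("text", x = 0, y = length(df$feature) / 2 + 0.5,
                      label = "DEGENERATE: all attributions zero",
                      colour = "red", size = 5, hjust = 0) +
    ggplot2::labs(x = "mean |attribution|", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an I-Gene profile
#'
#' Bar chart of I-Gene scores (0-100), coloured by directionality.
#'
#' @param object an `igene_profile` tibble.
#' @param top_n features shown, by rank. Default 20.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.igene_profile <- function(object, top_n = 20, ...) {
  df <- tibble::as_tibble(object)[seq_len(min(top_n, nrow(object))), ]
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$igene_score, y = .data$feature,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(overexpressed = "#b40426",
                                          underexpressed = "#3b4cc0",
                                          neutral = "grey65")) +
    ggplot2::labs(x = "I-Gene score (0-100)", y = NULL) +
    ggplot2::theme_minimal()
}
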