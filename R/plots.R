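#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_errorbar
#'   geom_segment facet_grid labs theme_minimal scale_y_log10 element_text
#'   theme position_dodge
NULL

#' @export
ggplot2::autoplot

#' Plot a mutational spectrum
#'
#' Bar chart of normalised class proportions; 96-class spectra are faceted
#' by substitution type in the conventional layout.
#'
#' @param object A `mut_spectrum` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mut_spectrum
#' @export
autoplot.mut_spectrum <- function(object, ...) {
  df <- as_tibble(object)
  if (attr(object, "n_classes") == 96L) {
    df$sub <- substr(df$class, 3, 5)
    df$context <- paste0(substr(df$class, 1, 1), substr(df$class, 3, 3),
                         substr(df$class, 7, 7))
    ggplot(df, aes(x = context, y = proportion, fill = sub)) +
      geom_col(show.legend = FALSE) +
      facet_grid(. ~ sub, scales = "free_x") +
      labs(x = "trinucleotide context", y = "proportion") +
      theme_minimal() +
      theme(axis.text.x = element_text(angle = 90, vjust = 0.5, size = 5))
  } else {
    ggplot(df, aes(x = class, y = proportion, fill = class)) +
      geom_col(show.legend = FALSE) +
      labs(x = "substitution", y = "proportion") +
      theme_minimal()
  }
}

#' Plot mutant-frequency estimates with confidence intervals
#'
#' @param metrics Tibble from [mutant_frequency()] carrying `tissue` and
#'   `treatment` columns.
#' @return A ggplot with points and 95% CI segments, log-scaled.
#' @export
plot_mutant_frequency <- function(metrics) {
  ggplot(metrics, aes(x = treatment, y = mf, colour = tissue)) +
    geom_point(position = position_dodge(width = 0.4)) +
    geom_errorbar(aes(ymin = ci_lo, ymax = ci_hi),
                  position = position_dodge(width = 0.4), width = 0.2) +
    scale_y_log10() +
    labs(y = "mutant frequency (per duplex bp)") +
    theme_minimal()
}

#' Plot reciprocal-substitution strand bias
#'
#' Mirrors the per-substitution layout of a strand-bias panel: one point per
#' substitution type per target with the CI of the fold difference to its
#' reciprocal; balanced types sit at fold 1.
#'
#' @param bias Tibble from [strand_bias()].
#' @return A ggplot.
#' @export
plot_strand_bias <- function(bias) {
  df <- bias[bias$applicable & !is.na(bias$fold), , drop = FALSE]
  ggplot(df, aes(x = sub, y = fold)) +
    geom_point() +
    geom_errorbar(aes(ymin = ci_lo, ymax = ci_hi), width = 0.2) +
    facet_grid(target ~ .) +
    scale_y_log10() +
    labs(x = "substitution (transcribed-strand orientation)",
         y = "fold vs reciprocal") +
    theme_minimal()
}

#' Plot a spectrum dendrogram
#'
#' Segment-based dendrogram drawing using the deterministic leaf order of
#' the object.
#'
#' @param object A `spectrum_dendrogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spectrum_dendrogram
#' @export
autoplot.spectrum_dendrogram <- function(object, ...) {
  hc <- object$hclust
  n <- length(object$labels)
  xpos <- numeric(n)
  xpos[object$leaf_order] <- seq_len(n)
  node_x <- numeric(nrow(hc$merge))
  node_y <- hc$height
  segs <- vector("list", nrow(hc$merge))
  coord <- function(v) {
    if (v < 0) c(xpos[-v], 0) else c(node_x[v], node_y[v])
  }
  for (i in seq_len(nrow(hc$merge))) {
    a <- coord(hc$merge[i, 1])
    b <- coord(hc$merge[i, 2])
    node_x[i] <- (a[1] + b[1]) / 2
    segs[[i]] <- tibble(
      x = c(a[1], b[1], a[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], b[2], node_y[i]), yend = c(node_y[i], node_y[i], node_y[i]))
  }
  segdf <- dplyr::bind_rows(segs)
  labdf <- tibble(x = xpos, y = 0, label = object$labels)
  ggplot(segdf) +
    geom_segment(aes(x = x, xend = xend, y = y, yend = yend)) +
    ggplot2::geom_text(data = labdf,
                       aes(x = x, y = y, label = label),
                       angle = 90, hjust = 1.05, size = 3) +
    ggplot2::scale_y_continuous(limits = c(-max(node_y) * 0.4, NA)) +
    labs(x = NULL, y = "cosine distance") +
    theme_minimal() +
    theme(axis.text.x = ggplot2::element_blank())
}
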