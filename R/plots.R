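#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot PVCA variance proportions
#'
#' @param object A [pvca()] result.
#' @param ... Unused.
#' @return A ggplot: weighted average proportion of variance per factor.
#' @export
autoplot.pvca_fit <- function(object, ...) {
  p <- object$proportions
  p$factor <- factor(p$factor, levels = p$factor)
  ggplot2::ggplot(p, ggplot2::aes(x = .data$factor, y = .data$proportion)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30") +
    ggplot2::geom_point(colour = "red3", size = 2) +
    ggplot2::labs(x = NULL, y = "Weighted average proportion of variance") +
    ggplot2::theme_minimal()
}

#' Plot sample PCA scores
#'
#' @param object A [pca_samples()] result.
#' @param meta Optional sample sheet; when given, points are coloured by
#'   `colour` and shaped by `shape`.
#' @param colour,shape Metadata column names (defaults `tissue`, `species`).
#' @param ... Unused.
#' @return A ggplot of the first two components.
#' @export
autoplot.sample_pca <- function(object, meta = NULL, colour = "tissue",
                                shape = "species", ...) {
  sc <- object$scores
  lab <- sprintf("PC%d (%.1f%%)", 1:2, 100 * object$prop_variance[1:2])
  if (!is.null(meta)) {
    sc <- dplyr::left_join(sc, meta, by = "sample_id")
    p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                          colour = .data[[colour]],
                                          shape = .data[[shape]]))
  } else {
    p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_minimal()
}

#' Plot correlation strata
#'
#' @param object A [pairwise_correlations()] result.
#' @param ... Unused.
#' @return A ggplot of per-pair correlations by comparison stratum.
#' @export
autoplot.cor_pairs <- function(object, ...) {
  dat <- dplyr::filter(object, .data$comparison != "other")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$comparison, y = .data$r)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "red3") +
    ggplot2::labs(x = NULL, y = "Pairwise correlation") +
    ggplot2::theme_minimal()
}

#' Plot a bootstrapped expression tree
#'
#' Draws the neighbor-joining tree with internal nodes coloured by
#' bootstrap support category (base graphics via ape).
#'
#' @param x A [bootstrap_support()] result.
#' @param ... Passed to [ape::plot.phylo()].
#' @return Invisibly, `x`.
#' @export
plot_support_tree <- function(x, ...) {
  stopifnot(inherits(x, "support_tree"))
  cols <- c("<50" = "red", "50-70" = "orange", "70-90" = "yellow",
            ">90" = "white")
  ape::plot.phylo(x$tree, type = "unrooted", ...)
  ape::nodelabels(pch = 21, bg = cols[as.character(x$support$category)],
                  cex = 1.2)
  invisible(x)
}
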