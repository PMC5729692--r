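#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PVCA fit
#'
#' @param x A [pvca()] result.
#' @param ... Unused.
#' @return Tibble: `factor`, `proportion` (weighted average proportion of
#'   variance, summing to 1 with the residual).
#' @export
tidy.pvca_fit <- function(x, ...) {
  x$proportions
}

#' @rdname tidy.pvca_fit
#' @export
glance.pvca_fit <- function(x, ...) {
  tibble(n_pcs = x$n_pcs, pc_threshold = x$pc_threshold,
         residual = x$proportions$proportion[x$proportions$factor == "residual"])
}

#' Tidy a bootstrap support tree
#'
#' @param x A [bootstrap_support()] result.
#' @param ... Unused.
#' @return Tibble: `node`, `support` (percent), `category`.
#' @export
tidy.support_tree <- function(x, ...) {
  x$support
}

#' @rdname tidy.support_tree
#' @export
glance.support_tree <- function(x, ...) {
  tibble(n_tips = length(x$tree$tip.label), n_nodes = x$tree$Nnode,
         n_replicates = x$n_valid,
         min_support = min(x$support$support),
         median_support = stats::median(x$support$support))
}

#' Tidy a sample PCA
#'
#' @param x A [pca_samples()] result.
#' @param ... Unused.
#' @return Tibble of sample scores (`sample_id` + PCs).
#' @export
tidy.sample_pca <- function(x, ...) {
  x$scores
}

#' @rdname tidy.sample_pca
#' @export
glance.sample_pca <- function(x, ...) {
  tibble(pc = seq_along(x$prop_variance),
         prop_variance = x$prop_variance,
         cum_variance = cumsum(x$prop_variance))
}
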