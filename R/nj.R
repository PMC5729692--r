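#' Neighbor-joining tree from a distance matrix
#'
#' Classic neighbor joining (Saitou-Nei agglomeration with the standard
#' Q-criterion), written out in full so its behaviour is fully specified:
#' ties are broken by the first minimal pair in row-major order, and
#' negative branch lengths (possible because correlation distances are not
#' guaranteed additive) are clamped to zero.
#'
#' @param d Symmetric numeric matrix (or `dist`) with zero diagonal;
#'   `n >= 3` taxa with rownames as labels.
#' @return An unrooted [ape::phylo] tree.
#' @examples
#' d <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' nj_tree(d)
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d))
  if (!isTRUE(all.equal(d, t(d), check.attributes = FALSE))) {
    abort("Distance matrix must be symmetric.")
  }
  n <- nrow(d)
  if (n < 3) abort("Neighbor joining needs at least 3 taxa.")
  labels <- rownames(d) %||% paste0("t", seq_len(n))

  frag <- labels  # newick fragment per active node
  D <- d
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]
    i <- min(ij); j <- max(ij)
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    new_frag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], li, frag[j], lj)
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    frag <- c(frag[keep], new_frag)
    D <- D2
  }
  la <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
  lb <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
  lc <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1], la, frag[2], lb, frag[3], lc)
  ape::read.tree(text = nwk)
}

#' Expression tree with gene-bootstrap support
#'
#' Builds the neighbor-joining tree of samples from `1 - Spearman`
#' correlation distances, then bootstraps the features: each replicate
#' resamples the rows (genes or exons) with replacement, rebuilds the tree,
#' and each internal bipartition of the original tree is supported by the
#' fraction of replicates containing it. Replicates whose resampled matrix
#' is degenerate (any constant sample, making correlations undefined) are
#' skipped and the support denominator adjusted.
#'
#' Support categories follow `<50`, `50-70`, `70-90`, `>90` (left-closed;
#' exactly 90 falls in `70-90`).
#'
#' @param data Features-by-samples wide tibble or matrix.
#' @param n_reps Bootstrap replicates (default 100).
#' @param seed Integer seed for the resampling stream.
#' @return An object of class `support_tree`: list with `tree`
#'   ([ape::phylo]), `support` (tibble: `node`, `support`, `category`),
#'   `n_valid` replicates used.
#' @export
bootstrap_support <- function(data, n_reps = 100L, seed = 1L) {
  m <- feature_matrix(data)
  if (nrow(m) < 2) abort("Need at least 2 features to bootstrap.")
  tree <- nj_tree(spearman_distance(m))

  boots <- list()
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(n_reps)) {
      idx <- sample.int(nrow(m), nrow(m), replace = TRUE)
      mb <- m[idx, , drop = FALSE]
      if (any(apply(mb, 2, stats::sd) == 0)) next  # degenerate replicate
      boots[[length(boots) + 1L]] <- nj_tree(spearman_distance(mb))
    }
  })
  n_valid <- length(boots)
  if (n_valid == 0) abort("All bootstrap replicates were degenerate.")

  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / n_valid
  nodes <- seq_len(tree$Nnode) + length(tree$tip.label)
  structure(list(
    tree = tree,
    support = tibble(node = nodes, support = support,
                     category = support_category(support)),
    n_valid = n_valid
  ), class = "support_tree")
}

support_category <- function(s) {
  cut(s, breaks = c(-Inf, 50, 70, 90, Inf), right = FALSE,
      labels = c("<50", "50-70", "70-90", ">90")) |>
    (\(x) { x[!is.na(s) & s == 90] <- "70-90"; x })()
}

#' @export
print.support_tree <- function(x, ...) {
  cat("<support_tree> ", length(x$tree$tip.label), " tips, ",
      x$tree$Nnode, " internal nodes, ", x$n_valid,
      " bootstrap replicates\n", sep = "")
  print(x$support, n = 5)
  invisible(x)
}

#' Write a support tree as Newick with node support labels
#'
#' @param x A [bootstrap_support()] result.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_support_tree <- function(x, path) {
  stopifnot(inherits(x, "support_tree"))
  tr <- x$tree
  tr$node.label <- sprintf("%.0f", x$support$support)
  ape::write.tree(tr, file = path)
  invisible(path)
}
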