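block_matrix <- function(n_feat = 60, groups = rep(c("A", "B"), each = 3),
                         sep = 6, noise_sd = 0.3, seed = 71) {
  withr::with_seed(seed, {
    base <- rnorm(n_feat, 6, 2)
    shift <- rnorm(n_feat, 0, 1)
    m <- sapply(groups, function(g) {
      base + (g == "B") * sep * shift + rnorm(n_feat, 0, noise_sd)
    })
    colnames(m) <- paste0(groups, ave(seq_along(groups), groups, FUN = seq_along))
    m
  })
}

test_that("correlation strata follow the design labels", {
  meta <- tibble::tibble(
    sample_id = c("a", "b", "c", "d"),
    species = c("sp1", "sp1", "sp2", "sp1"),
    tissue = c("heart", "heart", "heart", "liver"),
    altitude = c("low", "high", "low", "low"))
  withr::with_seed(72, m <- matrix(rnorm(40), 10, 4,
                                   dimnames = list(NULL, meta$sample_id)))
  m[, "b"] <- m[, "a"]  # duplicated sample
  pairs <- pairwise_correlations(m, meta)
  ab <- pairs[pairs$sample1 == "a" & pairs$sample2 == "b", ]
  expect_equal(ab$r, 1)
  expect_equal(ab$comparison, "altitude")
  expect_equal(pairs$comparison[pairs$sample1 == "a" & pairs$sample2 == "c"],
               "species")
  expect_equal(pairs$comparison[pairs$sample1 == "a" & pairs$sample2 == "d"],
               "tissue")
  expect_equal(spearman_distance(m)["a", "b"], 0)

  # reversed ranks give Spearman -1
  m2 <- cbind(x = c(1, 2, 3, 4), y = c(4, 3, 2, 1), z = c(1, 3, 2, 4))
  meta2 <- tibble::tibble(sample_id = c("x", "y", "z"), species = "s",
                          tissue = "t", altitude = c("low", "high", "low"))
  p2 <- pairwise_correlations(m2, meta2, method = "spearman")
  expect_equal(p2$r[p2$sample1 == "x" & p2$sample2 == "y"], -1)
})

test_that("sample correlation estimates recover a known latent correlation", {
  rho <- 0.7
  withr::with_seed(73, {
    z <- rnorm(1000)
    x <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(1000)
    y <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(1000)
  })
  meta <- tibble::tibble(sample_id = c("x", "y"), species = "s", tissue = "t",
                         altitude = c("low", "high"))
  pairs <- pairwise_correlations(cbind(x = x, y = y), meta)
  expect_lt(abs(pairs$r - rho), 0.05)
})

test_that("neighbor joining recovers additive distances exactly", {
  # classic 4-taxon additive matrix with known branch lengths
  d <- matrix(c(0, 5, 9, 9,
                5, 0, 10, 10,
                9, 10, 0, 8,
                9, 10, 8, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  # recovered tree reproduces the input distances
  cd <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(cd, d, tolerance = 1e-9)
  # oracle: exhaustive least-squares over all topologies picks the same tree
  best <- oracle_best_topology(d)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(best)), 0,
               ignore_attr = TRUE)
})

test_that("neighbor joining matches random additive trees and ape's nj", {
  skip_if_not_installed("phangorn")
  withr::with_seed(74, {
    for (n in 4:6) {
      true <- ape::rtree(n, rooted = FALSE,
                         br = function(k) runif(k, 0.5, 3))
      d <- ape::cophenetic.phylo(true)
      labs <- sort(rownames(d))
      d <- d[labs, labs]
      tr <- nj_tree(d)
      expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(true)), 0,
                   ignore_attr = TRUE)
      expect_equal(ape::cophenetic.phylo(tr)[labs, labs], d, tolerance = 1e-8)
      # independent implementation agrees
      expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ape::nj(d))), 0,
                   ignore_attr = TRUE)
      # oracle best least-squares topology agrees
      expect_equal(ape::dist.topo(ape::unroot(tr),
                                  ape::unroot(oracle_best_topology(d))), 0,
                   ignore_attr = TRUE)
    }
  })
})

test_that("neighbor joining is invariant to taxon order and rejects asymmetry", {
  d <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  perm <- c("C", "A", "D", "B")
  t1 <- nj_tree(d)
  t2 <- nj_tree(d[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
  d_bad <- d; d_bad[1, 2] <- 4
  expect_error(nj_tree(d_bad), "symmetric")
  expect_error(nj_tree(d[1:2, 1:2]), "3")
})

test_that("clean two-block data gets 100% support on the separating bipartition", {
  m <- block_matrix()
  bs <- bootstrap_support(m, n_reps = 100, seed = 7)
  expect_equal(bs$n_valid, 100)
  b_tips <- grep("^B", bs$tree$tip.label, value = TRUE)
  expect_true(ape::is.monophyletic(bs$tree, b_tips))
  node <- ape::getMRCA(bs$tree, b_tips)
  sup <- bs$support$support[bs$support$node == node]
  expect_equal(sup, 100)
  expect_equal(as.character(bs$support$category[bs$support$node == node]), ">90")
  # determinism
  bs2 <- bootstrap_support(m, n_reps = 100, seed = 7)
  expect_identical(bs$support, bs2$support)
  # feature order invariance
  bs3 <- bootstrap_support(m[nrow(m):1, ], n_reps = 100, seed = 7)
  expect_equal(bs3$support$support[bs3$support$node ==
                                     ape::getMRCA(bs3$tree, b_tips)], 100)
})

test_that("support categories split at 50/70/90 with 90 in the 70-90 band", {
  s <- c(10, 50, 69.9, 70, 90, 90.1, 100)
  expect_equal(as.character(altisplice:::support_category(s)),
               c("<50", "50-70", "50-70", "70-90", "70-90", ">90", ">90"))
})

test_that("bootstrap trees of pure noise contain a fixed bipartition ~1/3 of the time", {
  # 4 taxa admit 3 resolved splits; noise replicates should pick each ~equally
  has_split <- function(tree, pair) {
    ape::is.monophyletic(tree, pair) ||
      ape::is.monophyletic(tree, setdiff(tree$tip.label, pair))
  }
  withr::with_seed(75, {
    rate <- replicate(40, {
      m <- matrix(rnorm(4 * 25), 25, 4,
                  dimnames = list(NULL, paste0("s", 1:4)))
      hits <- replicate(25, {
        mb <- m[sample.int(nrow(m), nrow(m), replace = TRUE), ]
        has_split(nj_tree(spearman_distance(mb)), c("s1", "s2"))
      })
      mean(hits)
    })
  })
  expect_gt(mean(rate), 1 / 3 - 0.08)
  expect_lt(mean(rate), 1 / 3 + 0.08)
})

test_that("average-linkage clustering heights equal mean cross-pair distances", {
  m <- block_matrix(groups = rep(c("A", "B"), each = 3))
  h <- hierarchical_cluster(m)
  expect_true(all(diff(h$height) >= -1e-12))
  cl <- cutree(h, 2)
  expect_true(same_partition(cl, substr(names(cl), 1, 1)))
  # final merge height = mean of 1-Pearson distances across the two blocks
  d <- 1 - cor(m)
  cross <- d[names(cl)[cl == 1], names(cl)[cl == 2]]
  expect_equal(max(h$height), mean(cross), tolerance = 1e-10)
  # duplicated samples merge at height 0
  m2 <- cbind(m, A1b = m[, 1])
  h2 <- hierarchical_cluster(m2)
  expect_equal(min(h2$height), 0, tolerance = 1e-12)
})

test_that("PCA proportions behave and recover a known leading direction", {
  m <- block_matrix()
  pc <- pca_samples(m)
  expect_equal(sum(pc$prop_variance), 1)
  expect_equal(glance(pc)$cum_variance[length(pc$prop_variance)], 1)
  # rank-1 matrix: PC1 carries everything
  r1 <- outer(rnorm(20), c(1, 2, 3, 4))
  rownames(r1) <- NULL; colnames(r1) <- paste0("s", 1:4)
  pc1 <- pca_samples(r1)
  expect_equal(pc1$prop_variance[1], 1, tolerance = 1e-10)
  # 2D cloud with known covariance: PC1 within 5 degrees of the eigenvector
  withr::with_seed(76, {
    S <- matrix(c(4, 1.8, 1.8, 1), 2)
    L <- chol(S)
    x <- matrix(rnorm(2000), 1000, 2) %*% L   # samples x 2 features
  })
  fm <- t(x)  # 2 features x 1000 samples
  colnames(fm) <- paste0("s", seq_len(ncol(fm)))
  pcx <- pca_samples(fm)
  v1 <- pcx$fit$rotation[, 1]
  ev <- eigen(S)$vectors[, 1]
  ang <- acos(abs(sum(v1 * ev)) / sqrt(sum(v1^2) * sum(ev^2))) * 180 / pi
  expect_lt(ang, 5)
  # degenerate input
  zm <- matrix(1, 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_error(pca_samples(zm), "variance")
  # block structure: PC1 sign split equals the dendrogram cut
  split_pc1 <- ifelse(pc$scores$PC1 > 0, 1, 2)
  expect_true(same_partition(split_pc1, substr(pc$scores$sample_id, 1, 1)))
})
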