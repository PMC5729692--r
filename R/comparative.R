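#' Pairwise sample correlations with study-design stratification
#'
#' Computes correlations between all sample pairs of a features-by-samples
#' matrix and labels each pair with the comparison it informs:
#' `altitude` (same species and tissue, different altitude), `species`
#' (same tissue, different species), `tissue` (same species, different
#' tissue), or `other`.
#'
#' @param data Wide tibble (key column + sample columns) or numeric matrix,
#'   features x samples.
#' @param meta Sample sheet with `sample_id`, `species`, `tissue`,
#'   `altitude`.
#' @param method `"pearson"` (default) or `"spearman"` (average-rank ties).
#' @return Tibble of class `cor_pairs`: `sample1`, `sample2`, `r`,
#'   `comparison`. Constant samples produce `NA` correlations and a warning.
#' @export
pairwise_correlations <- function(data, meta, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- feature_matrix(data)
  if (nrow(m) < 3) abort("Need at least 3 features for correlations.")
  stopifnot(all(colnames(m) %in% meta$sample_id))
  if (any(apply(m, 2, stats::sd) == 0)) {
    warn("Constant sample profile(s); correlations involving them are NA.")
  }
  cm <- suppressWarnings(cor(m, method = method))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  pairs <- tibble(sample1 = colnames(cm)[idx[, 1]],
                  sample2 = colnames(cm)[idx[, 2]],
                  r = cm[idx])
  info <- meta[match(pairs$sample1, meta$sample_id), c("species", "tissue", "altitude")]
  info2 <- meta[match(pairs$sample2, meta$sample_id), c("species", "tissue", "altitude")]
  pairs$comparison <- dplyr::case_when(
    info$species == info2$species & info$tissue == info2$tissue &
      info$altitude != info2$altitude ~ "altitude",
    info$tissue == info2$tissue & info$species != info2$species ~ "species",
    info$species == info2$species & info$tissue != info2$tissue ~ "tissue",
    .default = "other")
  structure(pairs, class = c("cor_pairs", class(pairs)))
}

#' Mean correlation per comparison stratum
#'
#' @param pairs A [pairwise_correlations()] tibble.
#' @return Tibble: `comparison`, `mean_r`, `n_pairs`.
#' @export
correlation_summary <- function(pairs) {
  pairs |>
    dplyr::filter(.data$comparison != "other") |>
    dplyr::group_by(.data$comparison) |>
    dplyr::summarise(mean_r = mean(.data$r, na.rm = TRUE),
                     n_pairs = dplyr::n(), .groups = "drop")
}

#' 1 - Spearman correlation distance between samples
#'
#' @param data Features-by-samples wide tibble or matrix.
#' @return A symmetric numeric matrix with zero diagonal; values in
#'   \[0, 2\].
#' @export
spearman_distance <- function(data) {
  m <- feature_matrix(data)
  d <- 1 - cor(m, method = "spearman")
  diag(d) <- 0
  d
}

#' Average-linkage hierarchical clustering on correlation distance
#'
#' Distance between samples is `1 - Pearson correlation`; clusters are
#' merged by average (UPGMA) linkage, so the height of a merge is the mean
#' of cross-pair distances.
#'
#' @param data Features-by-samples wide tibble or matrix.
#' @return An [stats::hclust] object over the samples.
#' @export
hierarchical_cluster <- function(data) {
  m <- feature_matrix(data)
  if (ncol(m) < 2) abort("Need at least 2 samples to cluster.")
  d <- 1 - cor(m, method = "pearson")
  hclust(as.dist(d), method = "average")
}

#' Principal component analysis of samples
#'
#' Samples are projected on the principal axes of the feature-centered
#' matrix (samples as observations, features as variables, no scaling).
#'
#' @param data Features-by-samples wide tibble or matrix.
#' @return An object of class `sample_pca`: list with `scores` (tibble,
#'   `sample_id` + PCs), `prop_variance`, and the underlying
#'   [stats::prcomp] fit.
#' @export
pca_samples <- function(data) {
  m <- feature_matrix(data)
  if (ncol(m) < 2 || nrow(m) < 2) abort("Need >= 2 samples and >= 2 features.")
  x <- t(m)
  if (all(apply(x, 2, stats::sd) == 0)) abort("Matrix has zero variance.")
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  prop <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- tibble::as_tibble(fit$x)
  scores <- dplyr::mutate(scores, sample_id = rownames(fit$x), .before = 1)
  structure(list(scores = scores, prop_variance = prop, fit = fit),
            class = "sample_pca")
}

#' @export
print.sample_pca <- function(x, ...) {
  cat("<sample_pca> ", nrow(x$scores), " samples; PC1 ",
      sprintf("%.1f%%", 100 * x$prop_variance[1]), ", PC2 ",
      sprintf("%.1f%%", 100 * x$prop_variance[2] %||% NA), " of variance\n",
      sep = "")
  invisible(x)
}
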