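#' Principal variance component analysis (PVCA)
#'
#' Attributes overall data variance to experimental factors in three steps:
#' (1) PCA on the feature-centered matrix (samples as observations);
#' (2) retain the smallest set of leading components whose cumulative
#' variance reaches `pc_threshold`; (3) for each retained component, fit a
#' random-effects model of its scores with one random intercept per factor
#' (REML via lme4; negative estimates are truncated at zero by
#' construction) and convert the variance components, plus the residual,
#' to per-component proportions. The per-component proportions are then
#' averaged with each component's share of the total variance as its
#' weight; the variance share of the discarded trailing components is
#' unexplained by construction and is credited to the residual, and the
#' result is renormalized to sum to one.
#'
#' Factors with a single level contribute a zero proportion; factors whose
#' sample groupings are identical (confounded) raise an error.
#'
#' @param data Features-by-samples wide tibble or matrix.
#' @param meta Sample sheet with `sample_id` and the factor columns.
#' @param factors Factor column names (default altitude, species, tissue).
#' @param pc_threshold Cumulative variance threshold for component
#'   retention (default 0.6).
#' @param interactions Include pairwise factor interactions as additional
#'   random effects (default `FALSE`).
#' @return An object of class `pvca_fit`: list with `proportions` (tibble:
#'   `factor`, `proportion`, eigenvalue-weighted and renormalized),
#'   `per_pc` (tibble of per-component proportions), `n_pcs`,
#'   `pc_threshold`.
#' @export
pvca <- function(data, meta,
                 factors = c("altitude", "species", "tissue"),
                 pc_threshold = 0.6, interactions = FALSE) {
  m <- feature_matrix(data)
  stopifnot(all(colnames(m) %in% meta$sample_id), length(factors) >= 1)
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  if (anyNA(meta[factors])) {
    bad <- meta$sample_id[rowSums(is.na(meta[factors])) > 0]
    abort(paste0("Missing factor labels for sample(s): ",
                 paste(bad, collapse = ", ")))
  }

  grouping <- lapply(factors, function(f) as.integer(factor(meta[[f]])))
  names(grouping) <- factors
  for (i in seq_along(factors)) {
    for (j in seq_len(i - 1L)) {
      gi <- grouping[[i]]; gj <- grouping[[j]]
      if (length(unique(gi)) > 1 &&
          length(unique(paste(gi, gj))) == length(unique(gi)) &&
          length(unique(gi)) == length(unique(gj))) {
        abort(paste0("Factors `", factors[j], "` and `", factors[i],
                     "` are confounded (identical sample grouping)."))
      }
    }
  }

  live <- factors[vapply(grouping, function(g) length(unique(g)) > 1, logical(1))]
  if (length(live) == 0) abort("All factors have a single level.")

  pc <- pca_samples(m)
  prop <- pc$prop_variance
  n_pcs <- which(cumsum(prop) >= pc_threshold)[1]
  if (is.na(n_pcs)) n_pcs <- length(prop)
  eig <- pc$fit$sdev[seq_len(n_pcs)]^2

  terms <- live
  if (interactions && length(live) > 1) {
    cmb <- utils::combn(live, 2)
    terms <- c(terms, apply(cmb, 2, paste, collapse = ":"))
  }
  fml <- stats::as.formula(paste("score ~", paste(
    sprintf("(1 | %s)", terms), collapse = " + ")))

  df <- as.data.frame(meta[factors])
  per_pc <- matrix(0, n_pcs, length(factors) + 1L,
                   dimnames = list(NULL, c(factors, "residual")))
  for (i in seq_len(n_pcs)) {
    df$score <- pc$scores[[paste0("PC", i)]]
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = df, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    comp <- setNames(pmax(vc$vcov, 0), vc$grp)
    res <- comp[["Residual"]]
    main <- vapply(factors, function(f) {
      if (f %in% names(comp)) comp[[f]] else 0
    }, numeric(1))
    tot <- sum(main) + res +
      sum(comp[setdiff(names(comp), c(factors, "Residual"))])
    per_pc[i, factors] <- main / tot
    # interaction variance (when requested) is folded into the residual share
    per_pc[i, "residual"] <- 1 - sum(per_pc[i, factors])
  }

  # weight each retained component by its share of the *total* variance;
  # variance outside the retained subspace is unexplained by construction
  # and is credited to the residual
  w <- eig / sum(pc$fit$sdev^2)
  wavg <- colSums(per_pc * w)
  wavg[["residual"]] <- wavg[["residual"]] + (1 - sum(w))
  wavg <- wavg / sum(wavg)

  structure(list(
    proportions = tibble(factor = names(wavg), proportion = as.numeric(wavg)),
    per_pc = tibble::as_tibble(cbind(pc = seq_len(n_pcs), weight = w,
                                     per_pc)),
    n_pcs = n_pcs,
    pc_threshold = pc_threshold
  ), class = "pvca_fit")
}

#' @export
print.pvca_fit <- function(x, ...) {
  cat("<pvca_fit> ", x$n_pcs, " PC(s) retained (threshold ",
      x$pc_threshold, ")\n", sep = "")
  p <- x$proportions
  cat(paste(sprintf("  %-10s %.3f", p$factor, p$proportion), collapse = "\n"),
      "\n", sep = "")
  invisible(x)
}
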