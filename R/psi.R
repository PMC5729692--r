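#' Percent spliced in (PSI) from junction count triples
#'
#' `PSI = 100 * a / (c1c2 + a)` with `a = (c1a + ac2) / 2` (arithmetic mean
#' of the two inclusion junctions). Undefined (`NA`) when the denominator
#' is zero. Counts may be fractional (after mappability normalization) but
#' must be non-negative.
#'
#' @param c1a,ac2,c1c2 Numeric vectors of (normalized) junction counts for
#'   the upstream-inclusion, downstream-inclusion, and skipping junctions.
#' @return Numeric vector of PSI values in \[0, 100\] (or `NA`).
#' @examples
#' compute_psi(10, 10, 0)  # 100
#' compute_psi(6, 4, 5)    # 50
#' @export
compute_psi <- function(c1a, ac2, c1c2) {
  if (any(c(c1a, ac2, c1c2) < 0, na.rm = TRUE)) {
    abort("Junction counts must be non-negative.")
  }
  a <- (c1a + ac2) / 2
  den <- c1c2 + a
  ifelse(is.na(den) | den == 0, NA_real_, 100 * a / den)
}

#' Flag alternatively spliced exons
#'
#' An exon is alternative in a sample when `5 <= PSI <= 95` (both bounds
#' inclusive). Undefined PSI yields `FALSE`.
#'
#' @param psi Numeric PSI vector (0-100 or `NA`).
#' @return Logical vector.
#' @export
call_alternative <- function(psi) {
  !is.na(psi) & psi >= 5 & psi <= 95
}

#' Flag high-confidence PSI measurements
#'
#' Both criteria must hold:
#' 1. `max(min(c1a, ac2), c1c2) >= 5` and `min(c1a, ac2) + c1c2 >= 10`
#'    (enough informative reads);
#' 2. `|log2(c1a / ac2)| <= 1` or `max(c1a, ac2) < c1c2` (the two inclusion
#'    junctions are balanced, or skipping dominates anyway).
#'
#' When `c1a` or `ac2` is zero the log-ratio clause is treated as false and
#' confidence rests on the skipping-dominance clause.
#'
#' @inheritParams compute_psi
#' @return Logical vector.
#' @examples
#' is_high_confidence(20, 10, 0)  # TRUE
#' is_high_confidence(6, 4, 5)    # FALSE (9 informative inclusion+skip reads)
#' is_high_confidence(40, 5, 10)  # FALSE (unbalanced, skipping not dominant)
#' @export
is_high_confidence <- function(c1a, ac2, c1c2) {
  if (any(c(c1a, ac2, c1c2) < 0, na.rm = TRUE)) {
    abort("Junction counts must be non-negative.")
  }
  mn <- pmin(c1a, ac2)
  depth_ok <- pmax(mn, c1c2) >= 5 & (mn + c1c2) >= 10
  balanced <- ifelse(c1a > 0 & ac2 > 0, abs(log2(c1a / ac2)) <= 1, FALSE)
  skipping_dominant <- pmax(c1a, ac2) < c1c2
  ok <- depth_ok & (balanced | skipping_dominant)
  ok & !is.na(ok)
}

#' Per-sample PSI records from normalized counts
#'
#' @param norm_counts A [normalize_counts()] tibble.
#' @param sample_id Sample label attached to every record.
#' @param use_normalized Evaluate PSI and the confidence filters on
#'   normalized counts (default) or on raw counts.
#' @return Tibble: `triplet_id`, `sample_id`, `c1a`, `ac2`, `c1c2`
#'   (the counts used), `psi`, `is_alternative`, `is_high_confidence`.
#' @export
psi_table <- function(norm_counts, sample_id, use_normalized = TRUE) {
  cols <- if (use_normalized) c("norm_c1a", "norm_ac2", "norm_c1c2")
          else c("c1a", "ac2", "c1c2")
  stopifnot(all(c("triplet_id", cols) %in% names(norm_counts)))
  c1a <- norm_counts[[cols[1]]]
  ac2 <- norm_counts[[cols[2]]]
  c1c2 <- norm_counts[[cols[3]]]
  unq <- norm_counts$unquantifiable %||% rep(FALSE, nrow(norm_counts))
  psi <- rep(NA_real_, nrow(norm_counts))
  ok <- !unq & !is.na(c1a) & !is.na(ac2) & !is.na(c1c2)
  psi[ok] <- compute_psi(c1a[ok], ac2[ok], c1c2[ok])
  hc <- rep(FALSE, nrow(norm_counts))
  hc[ok] <- is_high_confidence(c1a[ok], ac2[ok], c1c2[ok])
  tibble(triplet_id = norm_counts$triplet_id,
         sample_id = sample_id,
         c1a = c1a, ac2 = ac2, c1c2 = c1c2,
         psi = psi,
         is_alternative = call_alternative(psi),
         is_high_confidence = hc)
}

#' Assemble the cross-species orthologous-exon PSI matrix
#'
#' Applies the inclusion rules for comparative analyses: an exon group is
#' kept iff it has a single-copy orthologue in every species (one triplet
#' per species; groups whose cassette exon overlaps multiple distinct
#' annotated exons in any species are excluded), a defined PSI in every
#' sample, and a high-confidence alternative call (`is_alternative` and
#' `is_high_confidence` together) in at least one sample.
#'
#' @param psi_records Row-bound [psi_table()] output across all samples,
#'   with a `species` and `gene_id` column joined per triplet.
#' @param exon_orthology Tibble mapping cassette exons to groups
#'   (`exon_group_id`, `species`, `gene_id`, `a_start`, `a_end`), as
#'   produced by [simulate_genomes()] or supplied externally.
#' @param samples Character vector of all expected sample ids (defaults to
#'   those present in `psi_records`).
#' @return A wide tibble of class `psi_matrix`: `exon_group_id` plus one
#'   PSI column per sample. The `excluded` attribute records per-group
#'   exclusion reasons.
#' @export
assemble_psi_matrix <- function(psi_records, exon_orthology, samples = NULL) {
  need <- c("triplet_id", "sample_id", "psi", "is_alternative",
            "is_high_confidence", "species", "gene_id", "a_start", "a_end")
  stopifnot(all(need %in% names(psi_records)))
  samples <- samples %||% unique(psi_records$sample_id)

  psi_records$exon_group_id <- NULL
  rec <- dplyr::inner_join(
    psi_records,
    dplyr::select(exon_orthology, "exon_group_id", "species", "gene_id",
                  "a_start", "a_end"),
    by = c("species", "gene_id", "a_start", "a_end"))

  n_species <- length(unique(exon_orthology$species))
  excluded <- list()

  # single-copy rule: exactly one triplet per species per group; groups with
  # multiple overlapping cassette-exon variants in any species are dropped
  copies <- rec |>
    dplyr::distinct(.data$exon_group_id, .data$species, .data$triplet_id) |>
    dplyr::count(.data$exon_group_id, .data$species)
  multi <- unique(copies$exon_group_id[copies$n > 1])
  present <- rec |>
    dplyr::distinct(.data$exon_group_id, .data$species) |>
    dplyr::count(.data$exon_group_id)
  incomplete <- present$exon_group_id[present$n < n_species]
  excluded$multi_copy <- multi
  excluded$missing_species <- setdiff(incomplete, multi)

  keep1 <- setdiff(unique(rec$exon_group_id), c(multi, incomplete))
  rec <- dplyr::filter(rec, .data$exon_group_id %in% keep1)

  miss_smp <- setdiff(samples, unique(rec$sample_id))
  if (length(miss_smp)) {
    abort(paste0("No PSI records for sample(s): ",
                 paste(miss_smp, collapse = ", ")))
  }

  by_group <- rec |>
    dplyr::filter(.data$sample_id %in% samples) |>
    dplyr::group_by(.data$exon_group_id) |>
    dplyr::summarise(
      n_defined = sum(!is.na(.data$psi)),
      n_samples = dplyr::n_distinct(.data$sample_id),
      any_confident_alt = any(.data$is_alternative & .data$is_high_confidence,
                              na.rm = TRUE))
  defined_all <- by_group$n_defined == length(samples) &
    by_group$n_samples == length(samples)
  excluded$undefined_psi <- by_group$exon_group_id[!defined_all]
  excluded$never_confident_alternative <-
    by_group$exon_group_id[defined_all & !by_group$any_confident_alt]
  keep <- by_group$exon_group_id[defined_all & by_group$any_confident_alt]

  if (length(keep) == 0) {
    wide <- tibble::as_tibble(c(list(exon_group_id = character(0)),
                                setNames(rep(list(numeric(0)), length(samples)),
                                         samples)))
  } else {
    wide <- rec |>
      dplyr::filter(.data$exon_group_id %in% keep) |>
      dplyr::select("exon_group_id", "sample_id", "psi") |>
      tidyr::pivot_wider(names_from = "sample_id", values_from = "psi") |>
      dplyr::arrange(.data$exon_group_id)
    wide <- wide[, c("exon_group_id", samples), drop = FALSE]
  }
  structure(wide, class = c("psi_matrix", class(wide)), excluded = excluded)
}
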