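#' Describe a multi-species, multi-tissue RNA-seq simulation design
#'
#' A design captures everything the simulator needs: the sampling layout
#' (species pairs, tissues, altitudes, individuals), the genomic scale
#' (genes, cassette exons, exon/intron sizes), sequencing parameters
#' (read length, depth, error rate), and the variance structure of the
#' true expression and splicing signals. The defaults mirror a
#' five-species-pair, six-tissue, two-altitude, three-individual study
#' (180 samples) at a desk-scale gene count, with expression variation
#' dominated by tissue and splicing variation dominated by species.
#'
#' @param n_species_pairs Number of species groups. Each group is one
#'   reference genome shared by a low- and a high-altitude population.
#' @param tissues Character vector of tissue labels.
#' @param n_individuals Replicate individuals per species x tissue x
#'   altitude cell.
#' @param n_genes Genes per genome; all are single-copy orthologues across
#'   species by construction.
#' @param n_cassette_exons Number of genes (<= `n_genes`) carrying one
#'   designated alternatively spliced internal (cassette) exon.
#' @param read_length Read length k in nt; must be >= 17 so that the
#'   junction retrieval rule (k-8) and the mappability bound (k-15) are
#'   both positive.
#' @param depth Mean reads per gene per sample (Poisson mean for a gene of
#'   average expression).
#' @param error_rate Per-base substitution sequencing error probability,
#'   in [0, 1).
#' @param divergence Per-branch per-site substitution probability applied
#'   independently to each species' copy of the ancestral sequence.
#' @param expr_variance Named numeric vector of variance components for
#'   log2 expression: `tissue`, `species`, `altitude`, `residual`.
#' @param psi_variance Named numeric vector of variance components for
#'   logit(PSI/100): `species`, `tissue`, `altitude`, `residual`.
#' @param n_exons_per_gene Exons per gene (>= 3; the cassette exon is the
#'   middle one).
#' @param exon_length,intron_length Length-2 integer vectors giving the
#'   sampling range (min, max) of exon and intron lengths in nt.
#' @param seed Master integer seed; all per-stage and per-sample random
#'   streams are derived from it deterministically.
#'
#' @return An object of class `simulation_design` (a validated list).
#' @examples
#' design <- simulation_design(n_species_pairs = 2, tissues = c("heart", "liver"),
#'                             n_individuals = 2, n_genes = 20,
#'                             n_cassette_exons = 10, seed = 1)
#' design
#' @export
simulation_design <- function(n_species_pairs = 5,
                              tissues = c("heart", "kidney", "liver",
                                          "lung", "muscle", "spleen"),
                              n_individuals = 3,
                              n_genes = 200,
                              n_cassette_exons = 100,
                              read_length = 76,
                              depth = 30,
                              error_rate = 0.001,
                              divergence = 0.02,
                              expr_variance = c(tissue = 1.5, species = 0.5,
                                                altitude = 0.05, residual = 0.2),
                              psi_variance = c(species = 1.5, tissue = 0.4,
                                               altitude = 0.05, residual = 0.2),
                              n_exons_per_gene = 5,
                              exon_length = c(90L, 240L),
                              intron_length = c(60L, 200L),
                              seed = 1L) {
  stopifnot(is.numeric(n_species_pairs), n_species_pairs >= 1,
            is.character(tissues), length(tissues) >= 1, !anyDuplicated(tissues),
            is.numeric(n_individuals), n_individuals >= 1,
            is.numeric(n_genes), n_genes >= 1,
            is.numeric(n_cassette_exons), n_cassette_exons >= 0,
            is.numeric(read_length), length(read_length) == 1,
            is.numeric(depth), depth > 0,
            is.numeric(error_rate), length(error_rate) == 1,
            is.numeric(divergence), divergence >= 0, divergence < 1,
            is.numeric(n_exons_per_gene), n_exons_per_gene >= 3,
            length(exon_length) == 2, length(intron_length) == 2,
            is.numeric(seed), length(seed) == 1)
  if (n_cassette_exons > n_genes) {
    abort("`n_cassette_exons` cannot exceed `n_genes`.")
  }
  if (read_length < 17) {
    abort("`read_length` must be >= 17 so that k-8 > 8 and k-15 >= 2.")
  }
  if (error_rate < 0 || error_rate >= 1) {
    abort("`error_rate` must lie in [0, 1).")
  }
  for (nm in list(c("expr_variance", "tissue", "species", "altitude", "residual"),
                  c("psi_variance", "species", "tissue", "altitude", "residual"))) {
    v <- get(nm[[1]])
    if (!all(nm[-1] %in% names(v))) {
      abort(paste0("`", nm[[1]], "` must be named with components: ",
                   paste(nm[-1], collapse = ", ")))
    }
    if (any(v < 0)) abort(paste0("`", nm[[1]], "` components must be >= 0."))
  }
  if (any(exon_length < 1) || any(intron_length < 1)) {
    abort("Exon and intron lengths must be >= 1 nt.")
  }
  if (exon_length[1] > exon_length[2] || intron_length[1] > intron_length[2]) {
    abort("Length ranges must be (min, max) with min <= max.")
  }

  design <- list(
    n_species_pairs = as.integer(n_species_pairs),
    species = paste0("sp", seq_len(n_species_pairs)),
    tissues = tissues,
    altitudes = c("low", "high"),
    n_individuals = as.integer(n_individuals),
    n_genes = as.integer(n_genes),
    n_cassette_exons = as.integer(n_cassette_exons),
    read_length = as.integer(read_length),
    depth = depth,
    error_rate = error_rate,
    divergence = divergence,
    expr_variance = expr_variance[c("tissue", "species", "altitude", "residual")],
    psi_variance = psi_variance[c("species", "tissue", "altitude", "residual")],
    n_exons_per_gene = as.integer(n_exons_per_gene),
    exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length),
    seed = as.integer(seed)
  )
  structure(design, class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  n_samples <- x$n_species_pairs * length(x$tissues) * 2 * x$n_individuals
  cat("<simulation_design>\n")
  cat(sprintf("  %d species pair(s) x %d tissue(s) x 2 altitudes x %d individual(s) = %d samples\n",
              x$n_species_pairs, length(x$tissues), x$n_individuals, n_samples))
  cat(sprintf("  %d genes (%d with a cassette exon), %d exons/gene\n",
              x$n_genes, x$n_cassette_exons, x$n_exons_per_gene))
  cat(sprintf("  reads: k = %d nt, depth %s reads/gene, error rate %g\n",
              x$read_length, format(x$depth), x$error_rate))
  cat(sprintf("  divergence %g subst/site/branch, seed %d\n", x$divergence, x$seed))
  cat("  expr variance: ", paste(sprintf("%s=%g", names(x$expr_variance), x$expr_variance),
                                 collapse = ", "), "\n", sep = "")
  cat("  psi variance:  ", paste(sprintf("%s=%g", names(x$psi_variance), x$psi_variance),
                                 collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Sample sheet for a design
#'
#' Enumerates every sample in the design in a fixed, deterministic order.
#'
#' @param design A [simulation_design()].
#' @return A tibble with columns `sample_id`, `species`, `tissue`,
#'   `altitude`, `individual`.
#' @export
sample_sheet <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  grid <- expand.grid(individual = seq_len(design$n_individuals),
                      altitude = design$altitudes,
                      tissue = design$tissues,
                      species = design$species,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("species", "tissue", "altitude", "individual")]
  tibble::as_tibble(grid) |>
    dplyr::mutate(sample_id = paste(.data$species, .data$tissue,
                                    .data$altitude, .data$individual, sep = "_"),
                  .before = 1)
}

## Deterministic 31-bit substream seed derived from the master seed and an
## integer tag (stage or sample index). Linear-congruential style mixing keeps
## everything inside the 32-bit signed range R requires.
substream_seed <- function(master, tag) {
  m <- 2147483647
  x <- (as.numeric(master) %% m) + 1
  for (t in c(as.numeric(tag), 104729)) {
    x <- (x * 48271 + t) %% m
  }
  as.integer(x)
}
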