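#' Validate a sample metadata table
#'
#' @param meta Tibble with `sample_id`, `species`, `tissue`, `altitude`,
#'   and optionally `individual`.
#' @return `meta`, invisibly, if valid; otherwise an error naming the
#'   offending samples/columns.
#' @export
validate_samples <- function(meta) {
  need <- c("sample_id", "species", "tissue", "altitude")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols)) {
    abort(paste0("Metadata lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  for (cn in need) {
    bad <- which(is.na(meta[[cn]]) | meta[[cn]] == "")
    if (length(bad)) {
      ids <- ifelse(cn == "sample_id", paste0("row ", bad),
                    meta$sample_id[bad])
      abort(paste0("Metadata column `", cn, "` missing for: ",
                   paste(ids, collapse = ", ")))
    }
  }
  if (anyDuplicated(meta$sample_id)) abort("Duplicate sample_id in metadata.")
  invisible(meta)
}

#' Run the full simulate-QC-catalog-quantify-PSI-compare pipeline
#'
#' End-to-end driver: simulates genomes, truth tables and reads for the
#' design, QC-filters the reads, builds per-species junction catalogs with
#' mappability, aligns and counts per sample, assembles the expression and
#' cross-species PSI matrices, and runs the comparative layer (correlation
#' summaries, bootstrapped NJ expression tree, hierarchical clustering,
#' PCA, PVCA). All stage outputs are written under `out_dir` along with a
#' provenance record (design hash, seed, package version); the same design
#' and seed reproduce outputs byte-identically.
#'
#' @param design A [simulation_design()].
#' @param out_dir Output directory.
#' @param adapter Adapter sequence for the QC stage (default a standard
#'   sequencing adapter; simulated reads contain none, so QC is a pass-through
#'   guard here).
#' @param n_boot Bootstrap replicates for the expression tree (default 100).
#' @param force Recompute even if `out_dir` already holds a completed run
#'   with the same provenance hash (default `FALSE` skips the run).
#' @return An object of class `altisplice_run` (list of stage results and
#'   file paths), invisibly.
#' @export
run_pipeline <- function(design, out_dir, adapter = "AGATCGGAAGAGC",
                         n_boot = 100L, force = FALSE) {
  stopifnot(inherits(design, "simulation_design"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  provenance <- list(
    design = unclass(design),
    design_hash = rlang::hash(unclass(design)),
    seed = design$seed,
    adapter = adapter,
    n_boot = as.integer(n_boot),
    package_version = as.character(utils::packageVersion("altisplice")))
  prov_path <- file.path(out_dir, "provenance.json")
  done_path <- file.path(out_dir, ".done")
  if (!force && file.exists(prov_path) && file.exists(done_path)) {
    old <- jsonlite::read_json(prov_path)
    if (identical(old$design_hash, provenance$design_hash)) {
      message("Outputs up to date for this design; skipping (use force = TRUE).")
      return(invisible(structure(list(out_dir = out_dir, skipped = TRUE),
                                 class = "altisplice_run")))
    }
  }
  unlink(done_path)

  sim <- simulate_genomes(design)
  truth <- simulate_truth(design)
  validate_samples(truth$samples)
  sim_dir <- file.path(out_dir, "simulation")
  write_simulation(sim, sim_dir, truth)
  reads <- simulate_reads(sim, truth)

  # QC
  qc_reports <- list()
  kept <- list()
  for (sid in names(reads$reads)) {
    f <- filter_reads(reads$reads[[sid]], adapter = adapter)
    kept[[sid]] <- f
    qc_reports[[sid]] <- qc_report(f)
  }
  qc_tbl <- dplyr::bind_rows(qc_reports, .id = "sample_id")
  readr::write_tsv(qc_tbl, file.path(out_dir, "qc_report.tsv"))

  # per-species catalogs with mappability
  k <- design$read_length
  catalogs <- list(); triplets <- list()
  for (sp in names(sim$genomes)) {
    ann <- dplyr::filter(sim$annotation, .data$species == sp)
    tr <- extract_cassette_triplets(ann)
    cat_sp <- build_junction_catalog(sim$genomes[[sp]], tr, k)
    cat_sp <- compute_effective_mappability(cat_sp, sim$genomes[[sp]])
    catalogs[[sp]] <- cat_sp
    triplets[[sp]] <- tr
    readr::write_tsv(cat_sp$junctions,
                     file.path(out_dir, paste0("catalog_", sp, ".tsv")))
  }

  # per-sample quantification
  fpkm_tables <- list()
  psi_records <- list()
  for (i in seq_len(nrow(truth$samples))) {
    smp <- truth$samples[i, ]
    sid <- smp$sample_id
    sp <- smp$species
    aln <- align_reads(kept[[sid]], sim$genomes[[sp]], k = k)
    jc <- count_junction_reads(aln$unaligned, catalogs[[sp]])
    norm <- normalize_counts(jc, catalogs[[sp]])
    fpkm_tables[[sid]] <- quantify_fpkm(
      aln, jc, dplyr::filter(sim$annotation, .data$species == sp),
      catalog = catalogs[[sp]], triplets = triplets[[sp]])
    psi_records[[sid]] <- psi_table(norm, sid) |>
      dplyr::left_join(dplyr::select(triplets[[sp]], "triplet_id", "gene_id",
                                     "a_start", "a_end"),
                       by = "triplet_id") |>
      dplyr::mutate(species = sp)
  }
  psi_all <- dplyr::bind_rows(psi_records)
  readr::write_tsv(psi_all, file.path(out_dir, "psi_records.tsv"))

  expr_fpkm <- assemble_expression_matrix(fpkm_tables, sim$gene_orthology)
  expr_mat <- filter_expressed(expr_fpkm)
  readr::write_tsv(expr_mat, file.path(out_dir, "expression_log2fpkm.tsv"))
  psi_mat <- assemble_psi_matrix(psi_all, sim$exon_orthology,
                                 samples = truth$samples$sample_id)
  readr::write_tsv(psi_mat, file.path(out_dir, "psi_matrix.tsv"))

  # comparative layer
  meta <- truth$samples
  comparative <- list()
  for (layer in c("expression", "psi")) {
    mat <- if (layer == "expression") expr_mat else psi_mat
    if (nrow(mat) < 3) {
      warn(paste0("Too few features in the ", layer, " matrix; comparative ",
                  "layer skipped for it."))
      next
    }
    pairs <- pairwise_correlations(mat, meta)
    res <- list(
      correlations = correlation_summary(pairs),
      tree = bootstrap_support(mat, n_reps = n_boot,
                               seed = substream_seed(design$seed, 77L)),
      hclust = hierarchical_cluster(mat),
      pca = pca_samples(mat),
      pvca = pvca(mat, meta))
    readr::write_tsv(res$correlations,
                     file.path(out_dir, paste0(layer, "_correlations.tsv")))
    write_support_tree(res$tree,
                       file.path(out_dir, paste0(layer, "_nj_tree.nwk")))
    readr::write_tsv(tidy(res$pvca),
                     file.path(out_dir, paste0(layer, "_pvca.tsv")))
    readr::write_tsv(tidy(res$pca),
                     file.path(out_dir, paste0(layer, "_pca_scores.tsv")))
    comparative[[layer]] <- res
  }

  jsonlite::write_json(provenance, prov_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(provenance$design_hash, done_path)

  invisible(structure(list(
    out_dir = out_dir, design = design, truth = truth,
    qc = qc_tbl, catalogs = catalogs,
    expression = expr_mat, psi = psi_mat,
    comparative = comparative, provenance = provenance,
    skipped = FALSE), class = "altisplice_run"))
}

#' @export
print.altisplice_run <- function(x, ...) {
  cat("<altisplice_run> outputs under ", x$out_dir, "\n", sep = "")
  if (isTRUE(x$skipped)) {
    cat("  (skipped: outputs were up to date)\n")
    return(invisible(x))
  }
  cat("  expression matrix: ", nrow(x$expression), " gene group(s)\n", sep = "")
  cat("  PSI matrix: ", nrow(x$psi), " exon group(s)\n", sep = "")
  invisible(x)
}
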