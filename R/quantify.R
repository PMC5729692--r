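#' Align reads to the genome with a mismatch budget
#'
#' A read is genome-aligned when at least one locus (either strand) matches
#' with at most `max_mismatch` substitutions; it is *unique* when exactly
#' one locus matches within the budget. Non-unique reads are aligned but
#' never counted. Reads with no locus within budget form the unaligned set
#' handed to junction counting. Reads whose length differs from `k` are
#' excluded and summarised in the `rejected` attribute.
#'
#' @param reads Tibble with `read_id`, `sequence` (and optionally
#'   `quality`).
#' @param genome A [Biostrings::DNAStringSet].
#' @param k Expected read length.
#' @param max_mismatch Mismatch budget (default 2).
#' @return A list of class `alignment_result`: `alignments` (tibble
#'   `read_id`, `chrom`, `strand`, `pos`, `mismatches`, `n_hits`, `unique`;
#'   one row per aligned read, at its first best locus), and `unaligned`
#'   (the reads with no alignment). Attribute `rejected` holds the count of
#'   wrong-length reads.
#' @export
align_reads <- function(reads, genome, k, max_mismatch = 2L) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  k <- as.integer(k)
  good_len <- nchar(reads$sequence) == k
  n_rejected <- sum(!good_len)
  if (n_rejected > 0) {
    warn(sprintf("%d read(s) of length != %d rejected.", n_rejected, k))
    reads <- reads[good_len, , drop = FALSE]
  }
  empty_aln <- tibble(read_id = character(), chrom = character(),
                      strand = character(), pos = integer(),
                      mismatches = integer(), n_hits = integer(),
                      unique = logical())
  if (nrow(reads) == 0) {
    return(structure(list(alignments = empty_aln, unaligned = reads),
                     class = "alignment_result", rejected = n_rejected,
                     read_length = k))
  }

  useq <- unique(reads$sequence)
  hits <- find_genome_hits(useq, genome, max_mismatch = max_mismatch)
  n_hits <- tabulate(hits$query, nbins = length(useq))

  best <- hits |>
    dplyr::arrange(.data$query, .data$mismatches, .data$chrom, .data$pos) |>
    dplyr::distinct(.data$query, .keep_all = TRUE)

  seq_idx <- match(reads$sequence, useq)
  aligned_mask <- n_hits[seq_idx] > 0
  aln_reads <- reads[aligned_mask, , drop = FALSE]
  aln_idx <- seq_idx[aligned_mask]
  row <- match(aln_idx, best$query)
  nh <- n_hits[aln_idx]
  alignments <- tibble(
    read_id = aln_reads$read_id,
    chrom = best$chrom[row], strand = best$strand[row],
    pos = best$pos[row], mismatches = best$mismatches[row],
    n_hits = nh,
    unique = nh == 1L)

  structure(list(alignments = alignments,
                 unaligned = reads[!aligned_mask, , drop = FALSE]),
            class = "alignment_result", rejected = n_rejected, read_length = k)
}

#' Count junction-spanning reads against the catalog
#'
#' A read counts for a junction when the read or its reverse complement
#' matches (exactly, by default over the whole catalog's k-mer positions)
#' exactly one junction position across the nonredundant junction set;
#' reads matching two or more positions are counted for neither. Counts of
#' a collapsed junction record are distributed to every (triplet, type)
#' member.
#'
#' @param unaligned Reads not aligned to the genome (tibble with `read_id`,
#'   `sequence`).
#' @param catalog A [build_junction_catalog()] result.
#' @return A list of class `junction_counts`: `counts` (tibble
#'   `triplet_id`, `c1a`, `ac2`, `c1c2` raw counts, zero-filled for every
#'   member triplet), and `assignments` (tibble `read_id`, `junction_id`).
#' @export
count_junction_reads <- function(unaligned, catalog) {
  stopifnot(inherits(catalog, "junction_catalog"))
  k <- catalog$k
  km <- junction_kmers(catalog$junctions, k)

  all_triplets <- unique(catalog$members$triplet_id)
  zero <- tibble(triplet_id = all_triplets, c1a = 0, ac2 = 0, c1c2 = 0)

  empty <- list(counts = zero,
                assignments = tibble(read_id = character(),
                                     junction_id = character()))
  class(empty) <- "junction_counts"
  if (nrow(unaligned) == 0 || nrow(km) == 0) return(empty)

  reads <- unaligned[nchar(unaligned$sequence) == k, , drop = FALSE]
  if (nrow(reads) == 0) return(empty)

  useq <- unique(reads$sequence)
  urc <- vapply(useq, revcomp, "", USE.NAMES = FALSE)
  # matches of each unique read sequence over all junction k-mer positions
  n_fwd <- match_counts(useq, km$kmer)
  n_rev <- match_counts(urc, km$kmer)
  total <- n_fwd + n_rev
  unique_hit <- total == 1L

  jid <- rep(NA_character_, length(useq))
  take <- function(x) km$junction_id[match(x, km$kmer)]
  jid[unique_hit & n_fwd == 1L] <- take(useq[unique_hit & n_fwd == 1L])
  jid[unique_hit & n_rev == 1L] <- take(urc[unique_hit & n_rev == 1L])

  rj <- jid[match(reads$sequence, useq)]
  counted <- !is.na(rj)
  assignments <- tibble(read_id = reads$read_id[counted],
                        junction_id = rj[counted])

  per_junction <- assignments |> dplyr::count(.data$junction_id, name = "n")
  mem <- dplyr::inner_join(catalog$members, per_junction, by = "junction_id")
  wide <- mem |>
    dplyr::mutate(col = dplyr::recode(.data$type, C1A = "c1a", AC2 = "ac2",
                                      C1C2 = "c1c2")) |>
    dplyr::group_by(.data$triplet_id, .data$col) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "col", values_from = "n", values_fill = 0)
  for (cn in c("c1a", "ac2", "c1c2")) if (!cn %in% names(wide)) wide[[cn]] <- 0
  counts <- zero |>
    dplyr::rows_update(dplyr::select(wide, "triplet_id", "c1a", "ac2", "c1c2"),
                       by = "triplet_id")
  structure(list(counts = counts, assignments = assignments),
            class = "junction_counts")
}

## occurrences of each query string among the catalog k-mer multiset
match_counts <- function(queries, kmers) {
  tab <- table(kmers)
  n <- as.integer(tab[queries])
  n[is.na(n)] <- 0L
  n
}

#' Normalize junction counts by effective mappability
#'
#' Each junction's count is multiplied by `(k - 15) / effective_positions`,
#' the ratio of the maximum number of mappable positions to the junction's
#' effective uniquely mappable positions, so junctions whose placements are
#' partly shadowed by the genome or by other junctions are scaled up to a
#' common footing. Triplets with any constituent junction at zero effective
#' positions are flagged unquantifiable (normalized counts set to `NA`).
#'
#' @param counts A [count_junction_reads()] result (or its `$counts` tibble).
#' @param catalog Catalog with mappability computed
#'   ([compute_effective_mappability()]).
#' @return Tibble: `triplet_id`, raw `c1a`/`ac2`/`c1c2`, normalized
#'   `norm_c1a`/`norm_ac2`/`norm_c1c2`, `unquantifiable`.
#' @export
normalize_counts <- function(counts, catalog) {
  stopifnot(inherits(catalog, "junction_catalog"))
  if (inherits(counts, "junction_counts")) counts <- counts$counts
  jt <- catalog$junctions
  if (!"effective_positions" %in% names(jt)) {
    abort("Catalog has no mappability; run compute_effective_mappability() first.")
  }
  k <- catalog$k
  eff <- setNames(jt$effective_positions, jt$junction_id)

  tri_j <- catalog$members |>
    dplyr::mutate(col = dplyr::recode(.data$type, C1A = "c1a", AC2 = "ac2",
                                      C1C2 = "c1c2")) |>
    dplyr::distinct(.data$triplet_id, .data$col, .keep_all = TRUE) |>
    dplyr::mutate(eff = eff[.data$junction_id]) |>
    dplyr::select("triplet_id", "col", "eff") |>
    tidyr::pivot_wider(names_from = "col", values_from = "eff",
                       names_prefix = "eff_")

  out <- dplyr::left_join(counts, tri_j, by = "triplet_id")
  scale1 <- function(raw, e) {
    unname(ifelse(!is.na(e) & e > 0, raw * (k - 15) / e, NA_real_))
  }
  out <- out |>
    dplyr::mutate(
      norm_c1a = scale1(.data$c1a, .data$eff_c1a),
      norm_ac2 = scale1(.data$ac2, .data$eff_ac2),
      norm_c1c2 = scale1(.data$c1c2, .data$eff_c1c2),
      unquantifiable = .data$eff_c1a == 0 | .data$eff_ac2 == 0 |
        .data$eff_c1c2 == 0) |>
    dplyr::select("triplet_id", "c1a", "ac2", "c1c2",
                  "norm_c1a", "norm_ac2", "norm_c1c2", "unquantifiable")
  out
}

#' Simplified FPKM gene expression from unique alignments
#'
#' A deliberately simple union-exon quantifier: a gene's count is the
#' number of uniquely genome-aligned reads lying fully inside the gene's
#' exonic union, plus the uniquely junction-mapped reads whose junction
#' belongs to that gene alone. `FPKM = count * 1e9 / (library_size *
#' union_length)`, where `library_size` is the total of counted reads in
#' the sample. Relative comparisons across samples are the intended use;
#' no isoform deconvolution is attempted.
#'
#' @param aln An [align_reads()] result.
#' @param junction_counts A [count_junction_reads()] result (or `NULL` to
#'   use genome alignments only).
#' @param annotation Exon annotation tibble for the same genome.
#' @param catalog The junction catalog (required when `junction_counts`
#'   is given, to map junctions to genes).
#' @param triplets The triplet table the catalog was built from (maps
#'   triplet ids to gene ids).
#' @return Tibble: `gene_id`, `count`, `union_length`, `fpkm`.
#' @export
quantify_fpkm <- function(aln, junction_counts = NULL, annotation,
                          catalog = NULL, triplets = NULL) {
  stopifnot(inherits(aln, "alignment_result"))
  genes <- unique(annotation$gene_id)

  ex <- GenomicRanges::GRanges(annotation$seqnames,
                               IRanges::IRanges(annotation$start, annotation$end),
                               gene_id = annotation$gene_id)
  by_gene <- GenomicRanges::split(ex, ex$gene_id)
  union_gr <- GenomicRanges::reduce(by_gene)
  union_len <- sum(IRanges::width(union_gr))
  if (any(union_len == 0)) {
    abort(paste0("Gene(s) with zero-length exonic union: ",
                 paste(names(union_len)[union_len == 0], collapse = ", ")))
  }

  a <- dplyr::filter(aln$alignments, .data$unique)
  gene_counts <- setNames(numeric(length(genes)), genes)
  if (nrow(a) > 0) {
    read_len <- attr(aln, "read_length") %||%
      (if (!is.null(catalog)) catalog$k else
         abort("Cannot infer read length; supply `catalog`."))
    rgr <- GenomicRanges::GRanges(a$chrom,
                                  IRanges::IRanges(a$pos, a$pos + read_len - 1L))
    flat <- unlist(union_gr)
    ov <- GenomicRanges::findOverlaps(rgr, flat, type = "within")
    gid <- names(flat)[S4Vectors::subjectHits(ov)]
    # a read within one union piece maps to exactly one gene here
    first_hit <- !duplicated(S4Vectors::queryHits(ov))
    tab <- table(gid[first_hit])
    gene_counts[names(tab)] <- gene_counts[names(tab)] + as.numeric(tab)
  }

  if (!is.null(junction_counts) && nrow(junction_counts$assignments) > 0) {
    if (is.null(catalog) || is.null(triplets)) {
      abort("`catalog` and `triplets` are required to credit junction reads to genes.")
    }
    j_gene <- catalog$members |>
      dplyr::left_join(dplyr::select(triplets, "triplet_id", "gene_id"),
                       by = "triplet_id") |>
      dplyr::distinct(.data$junction_id, .data$gene_id) |>
      dplyr::group_by(.data$junction_id) |>
      dplyr::filter(dplyr::n() == 1L) |>   # ambiguous junctions credit no gene
      dplyr::ungroup()
    jr <- dplyr::inner_join(junction_counts$assignments, j_gene,
                            by = "junction_id")
    tab <- table(jr$gene_id)
    keep <- names(tab) %in% genes
    gene_counts[names(tab)[keep]] <- gene_counts[names(tab)[keep]] +
      as.numeric(tab[keep])
  }

  library_size <- sum(gene_counts)
  fpkm <- if (library_size > 0) {
    gene_counts * 1e9 / (library_size * union_len[genes])
  } else {
    gene_counts * 0
  }
  tibble(gene_id = genes, count = as.numeric(gene_counts[genes]),
         union_length = as.integer(union_len[genes]),
         fpkm = as.numeric(fpkm))
}

#' Assemble a genes-by-samples FPKM matrix
#'
#' @param fpkm_tables Named list (by sample id) of [quantify_fpkm()] tibbles.
#' @param orthology Optional gene orthology tibble (`group_id`, `species`,
#'   `gene_id`); when given, rows are keyed by `group_id` so samples from
#'   different species can share rows.
#' @return A wide tibble: key column (`gene_id` or `group_id`) plus one
#'   FPKM column per sample.
#' @export
assemble_expression_matrix <- function(fpkm_tables, orthology = NULL) {
  stopifnot(length(fpkm_tables) > 0, !is.null(names(fpkm_tables)))
  long <- dplyr::bind_rows(fpkm_tables, .id = "sample_id")
  if (!is.null(orthology)) {
    long <- long |>
      dplyr::inner_join(dplyr::select(orthology, "group_id", "gene_id"),
                        by = "gene_id") |>
      dplyr::select("group_id", "sample_id", "fpkm")
    key <- "group_id"
  } else {
    long <- dplyr::select(long, gene_id = "gene_id", "sample_id", "fpkm")
    key <- "gene_id"
  }
  tidyr::pivot_wider(long, names_from = "sample_id", values_from = "fpkm")
}

#' Filter to expressed genes and log-transform
#'
#' Retains a gene iff its FPKM exceeds `threshold` in strictly more than
#' `fraction` of the samples, then returns `log2(FPKM + 1)` values.
#'
#' @param expr_matrix Wide FPKM tibble from [assemble_expression_matrix()].
#' @param threshold FPKM threshold (default 0.5, exceeded strictly).
#' @param fraction Fraction of samples (default 0.8, exceeded strictly).
#' @param log2_transform Return `log2(FPKM + 1)` (default `TRUE`).
#' @return The filtered (and transformed) wide tibble.
#' @export
filter_expressed <- function(expr_matrix, threshold = 0.5, fraction = 0.8,
                             log2_transform = TRUE) {
  m <- feature_matrix(expr_matrix)
  keep <- rowMeans(m > threshold) > fraction
  out <- expr_matrix[keep, , drop = FALSE]
  if (log2_transform) {
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(x) log2(x + 1))
  }
  out
}
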