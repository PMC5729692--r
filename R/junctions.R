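#' Extract cassette-exon triplets from an annotation
#'
#' Every internal exon of every transcript is treated as a candidate
#' cassette exon A, flanked by its upstream (C1) and downstream (C2)
#' neighbours in transcript order. Triplets with identical genomic
#' coordinates arising from different transcripts are collapsed to one.
#'
#' @param annotation Exon tibble as returned by [read_gtf_exons()] or found
#'   in a [simulate_genomes()] result (columns `seqnames`, `start`, `end`,
#'   `strand`, `gene_id`, `transcript_id`, `exon_number`; 1-based inclusive).
#' @return A tibble of triplets: `triplet_id`, `transcript_id`, `gene_id`,
#'   `seqnames`, `strand`, and `c1_start`/`c1_end`/`a_start`/`a_end`/
#'   `c2_start`/`c2_end`. Transcripts with fewer than 3 exons contribute
#'   none.
#' @export
extract_cassette_triplets <- function(annotation) {
  need <- c("seqnames", "start", "end", "strand", "gene_id",
            "transcript_id", "exon_number")
  stopifnot(all(need %in% names(annotation)))
  ann <- dplyr::arrange(annotation, .data$transcript_id, .data$exon_number)
  rows <- ann |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::filter(dplyr::n() >= 3) |>
    dplyr::mutate(
      c1_start = dplyr::lag(.data$start), c1_end = dplyr::lag(.data$end),
      c2_start = dplyr::lead(.data$start), c2_end = dplyr::lead(.data$end)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$c1_start), !is.na(.data$c2_start)) |>
    dplyr::transmute(
      transcript_id = .data$transcript_id, gene_id = .data$gene_id,
      seqnames = .data$seqnames, strand = .data$strand,
      c1_start = .data$c1_start, c1_end = .data$c1_end,
      a_start = .data$start, a_end = .data$end,
      c2_start = .data$c2_start, c2_end = .data$c2_end)
  dedup <- dplyr::distinct(rows, .data$seqnames, .data$strand,
                           .data$c1_start, .data$c1_end,
                           .data$a_start, .data$a_end,
                           .data$c2_start, .data$c2_end, .keep_all = TRUE)
  dplyr::mutate(dedup, triplet_id = sprintf("tri%05d", dplyr::row_number()),
                .before = 1)
}

#' Build the nonredundant junction catalog for a set of triplets
#'
#' For each triplet, three junction sequences are built in transcript
#' orientation (minus-strand exon sequence reverse-complemented): C1A and
#' AC2 (inclusion junctions) and C1C2 (the skipping junction). Each side
#' contributes its terminal `k - 8` nt, or the whole exon when the exon is
#' shorter than `k - 8`, which guarantees a mapped read overlaps each
#' flanking exon by at least 8 nt. Identical junction sequences are
#' collapsed into one record listing every (triplet, junction type) member.
#'
#' @param genome A [Biostrings::DNAStringSet] (the triplets' chromosomes).
#' @param triplets Output of [extract_cassette_triplets()].
#' @param k Read length (>= 17).
#' @return An object of class `junction_catalog`: list with `junctions`
#'   (tibble: `junction_id`, `type`, `seq`, `left_len`, `right_len`, `L`)
#'   and `members` (tibble: `junction_id`, `triplet_id`, `type`), plus `k`.
#' @export
build_junction_catalog <- function(genome, triplets, k) {
  stopifnot(k >= 17)
  k <- as.integer(k)
  part <- k - 8L

  exon_seq <- function(chrom, s, e, strand, trip) {
    chr <- genome[[chrom]]
    if (is.null(chr)) abort(paste0("Chromosome ", chrom, " absent from genome (",
                                   trip, ")."))
    if (s < 1 || e > length(chr)) {
      abort(paste0("Exon outside chromosome bounds for triplet ", trip, "."))
    }
    x <- as.character(Biostrings::subseq(chr, s, e))
    if (strand == "-") revcomp(x) else x
  }

  recs <- vector("list", nrow(triplets))
  for (i in seq_len(nrow(triplets))) {
    tr <- triplets[i, ]
    c1 <- exon_seq(tr$seqnames, tr$c1_start, tr$c1_end, tr$strand, tr$triplet_id)
    a  <- exon_seq(tr$seqnames, tr$a_start, tr$a_end, tr$strand, tr$triplet_id)
    c2 <- exon_seq(tr$seqnames, tr$c2_start, tr$c2_end, tr$strand, tr$triplet_id)
    jn <- function(left, right) {
      ll <- min(nchar(left), part); rl <- min(nchar(right), part)
      lpart <- substr(left, nchar(left) - ll + 1L, nchar(left))
      rpart <- substr(right, 1L, rl)
      tibble(seq = paste0(lpart, rpart), left_len = ll, right_len = rl,
             L = ll + rl)
    }
    recs[[i]] <- dplyr::bind_rows(
      dplyr::mutate(jn(c1, a), type = "C1A"),
      dplyr::mutate(jn(a, c2), type = "AC2"),
      dplyr::mutate(jn(c1, c2), type = "C1C2")) |>
      dplyr::mutate(triplet_id = tr$triplet_id)
  }
  all_j <- dplyr::bind_rows(recs)

  nonred <- all_j |>
    dplyr::group_by(.data$seq) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  # stable ids in first-appearance order
  first_order <- match(unique(all_j$seq), nonred$seq)
  nonred <- nonred[first_order, ]
  nonred$junction_id <- sprintf("J%05d", seq_len(nrow(nonred)))

  members <- all_j |>
    dplyr::left_join(dplyr::select(nonred, "seq", "junction_id"), by = "seq") |>
    dplyr::select("junction_id", "triplet_id", "type")

  junctions <- dplyr::select(nonred, "junction_id", "type", "seq",
                             "left_len", "right_len", "L")
  structure(list(junctions = junctions, members = members, k = k),
            class = "junction_catalog")
}

#' @export
print.junction_catalog <- function(x, ...) {
  cat("<junction_catalog> ", nrow(x$junctions), " nonredundant junction(s), k = ",
      x$k, sep = "")
  if ("effective_positions" %in% names(x$junctions)) {
    cat("; mappability computed")
  }
  cat("\n")
  invisible(x)
}

#' Compute effective uniquely mappable positions per junction
#'
#' Each junction of length L yields `L - k + 1` k-mers (its possible read
#' placements). A k-mer is *effective* when (a) it has no alignment to the
#' genome within 2 mismatches on either strand, and (b) it occurs at exactly
#' one position across the whole nonredundant junction set. The count of
#' effective k-mers per junction is bounded above by `L - k + 1`, itself at
#' most `k - 15` when both exon parts are full length; `k - 15` is the
#' normalization ceiling used by [normalize_counts()].
#'
#' @param catalog A [build_junction_catalog()] result.
#' @param genome The same genome the catalog was built from.
#' @param max_mismatch Mismatch allowance for the genome pre-screen
#'   (default 2).
#' @param junction_mismatch If `TRUE`, junction uniqueness also allows up to
#'   `max_mismatch` mismatches; the default (`FALSE`) requires exact,
#'   single-position matches on the forward junction sequences.
#' @return The catalog with `effective_positions` and `max_positions`
#'   (`k - 15`) columns added to `$junctions`.
#' @export
compute_effective_mappability <- function(catalog, genome, max_mismatch = 2L,
                                          junction_mismatch = FALSE) {
  stopifnot(inherits(catalog, "junction_catalog"))
  k <- catalog$k
  jt <- catalog$junctions
  km <- junction_kmers(jt, k)

  if (nrow(km) == 0) {
    jt$effective_positions <- 0L
    jt$max_positions <- k - 15L
    catalog$junctions <- jt
    return(catalog)
  }

  uniq <- unique(km$kmer)
  gh <- find_genome_hits(uniq, genome, max_mismatch = max_mismatch)
  genome_free <- !(uniq %in% uniq[gh$query])

  if (!junction_mismatch) {
    occ <- table(km$kmer)
    unique_in_catalog <- occ[uniq] == 1L
  } else {
    jh <- find_subject_hits(uniq, setNames(jt$seq, jt$junction_id),
                            max_mismatch = max_mismatch, both_strands = FALSE)
    cnt <- tabulate(jh$query, nbins = length(uniq))
    unique_in_catalog <- cnt == 1L
  }

  eff_kmer <- setNames(genome_free & as.logical(unique_in_catalog), uniq)
  km$effective <- eff_kmer[km$kmer]
  eff <- km |>
    dplyr::group_by(.data$junction_id) |>
    dplyr::summarise(effective_positions = sum(.data$effective))

  jt <- dplyr::left_join(jt, eff, by = "junction_id") |>
    dplyr::mutate(effective_positions =
                    as.integer(dplyr::coalesce(.data$effective_positions, 0L)),
                  max_positions = k - 15L)
  catalog$junctions <- jt
  catalog
}

## all k-mers (read placements) of every junction, with positions
junction_kmers <- function(junctions, k) {
  res <- lapply(seq_len(nrow(junctions)), function(i) {
    L <- junctions$L[i]
    if (L < k) return(NULL)
    pos <- seq_len(L - k + 1L)
    tibble(junction_id = junctions$junction_id[i], pos = pos,
           kmer = substring(junctions$seq[i], pos, pos + k - 1L))
  })
  dplyr::bind_rows(res)
}
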