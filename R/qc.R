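#' Filter reads by N content, adapter contamination, and base quality
#'
#' Applies three removal rules, in order, attributing each removed read to
#' the first rule it violates:
#'
#' 1. **N rule** — the fraction of unidentified nucleotides (N) is >= 10%
#'    (inclusive bound).
#' 2. **Adapter rule** — some ungapped alignment of the adapter against the
#'    read (any offset, overhangs allowed) covers m > 10 read bases with at
#'    most `floor(0.10 * m)` mismatches.
#' 3. **Quality rule** — strictly more than 50% of bases have phred
#'    quality < 5.
#'
#' Reads are removed, never trimmed. Thresholds are exposed as arguments
#' but default to the rules above.
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality` (phred+33).
#' @param adapter Adapter sequence (required when the adapter rule is
#'   active; pass `NULL` to disable rule 2).
#' @param n_fraction Inclusive minimum N fraction for removal (default 0.10).
#' @param adapter_min_overlap Strict minimum aligned length m (default 10).
#' @param adapter_mismatch_rate Mismatch budget as a fraction of m,
#'   floored to an integer (default 0.10).
#' @param quality_threshold Phred value below which a base counts as
#'   low-quality (default 5).
#' @param quality_fraction Strict minimum fraction of low-quality bases for
#'   removal (default 0.5).
#' @return The kept reads as a tibble of class `qc_reads`, with the QC
#'   report attached (see [qc_report()]).
#' @examples
#' reads <- tibble::tibble(read_id = "r1",
#'                         sequence = strrep("ACGT", 25),
#'                         quality = strrep("I", 100))
#' filter_reads(reads, adapter = "AGATCGGAAGAGC")
#' @export
filter_reads <- function(reads, adapter = NULL,
                         n_fraction = 0.10,
                         adapter_min_overlap = 10L,
                         adapter_mismatch_rate = 0.10,
                         quality_threshold = 5L,
                         quality_fraction = 0.5) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  n <- nrow(reads)
  if (n == 0) {
    rep0 <- tibble(input_count = 0L, removed_by_n = 0L, removed_by_adapter = 0L,
                   removed_by_quality = 0L, kept_count = 0L)
    return(structure(reads, class = c("qc_reads", class(reads)), report = rep0))
  }
  if (any(nchar(reads$sequence) != nchar(reads$quality)) ||
      any(nchar(reads$sequence) == 0)) {
    abort("Each read must have matching, non-empty sequence and quality strings.")
  }

  len <- nchar(reads$sequence)
  n_count <- stringr::str_count(reads$sequence, stringr::fixed("N"))
  fail_n <- n_count / len >= n_fraction

  fail_adapter <- rep(FALSE, n)
  if (!is.null(adapter)) {
    if (!nzchar(adapter)) abort("`adapter` must be a non-empty sequence.")
    fail_adapter <- adapter_contaminated(reads$sequence, adapter,
                                         adapter_min_overlap,
                                         adapter_mismatch_rate)
  }

  phred_low <- vapply(reads$quality, function(q) {
    sum(utf8ToInt(q) - 33L < quality_threshold)
  }, integer(1), USE.NAMES = FALSE)
  fail_quality <- phred_low / len > quality_fraction

  by_n <- fail_n
  by_adapter <- !by_n & fail_adapter
  by_quality <- !by_n & !by_adapter & fail_quality
  keep <- !(by_n | by_adapter | by_quality)

  report <- tibble(input_count = n,
                   removed_by_n = sum(by_n),
                   removed_by_adapter = sum(by_adapter),
                   removed_by_quality = sum(by_quality),
                   kept_count = sum(keep))
  kept <- reads[keep, , drop = FALSE]
  structure(kept, class = c("qc_reads", class(tibble::as_tibble(kept))),
            report = report)
}

#' Retrieve the QC report attached to filtered reads
#'
#' @param x A `qc_reads` object from [filter_reads()].
#' @return A one-row tibble: `input_count`, `removed_by_n`,
#'   `removed_by_adapter`, `removed_by_quality`, `kept_count`.
#' @export
qc_report <- function(x) {
  rep <- attr(x, "report")
  if (is.null(rep)) abort("`x` carries no QC report; was it made by filter_reads()?")
  rep
}

## Ungapped scan of the adapter across every offset of every read (overhangs
## allowed at both ends). A read is contaminated if any offset aligns
## m > min_overlap read bases with mismatches <= floor(mismatch_rate * m).
## Vectorized across reads per length group and offset; N never matches.
adapter_contaminated <- function(seqs, adapter, min_overlap, mismatch_rate) {
  out <- logical(length(seqs))
  ad <- strsplit(toupper(adapter), "", fixed = TRUE)[[1]]
  la <- length(ad)
  for (k in unique(nchar(seqs))) {
    idx <- which(nchar(seqs) == k)
    mat <- matrix(unlist(strsplit(toupper(seqs[idx]), "", fixed = TRUE)),
                  nrow = length(idx), ncol = k, byrow = TRUE)
    hit <- logical(length(idx))
    for (off in (-(la - 1L)):(k - 1L)) {
      cols <- max(1L, off + 1L):min(k, off + la)
      m <- length(cols)
      if (m <= min_overlap) next
      acols <- cols - off
      ref <- matrix(ad[acols], nrow = length(idx), ncol = m, byrow = TRUE)
      mm <- rowSums(mat[, cols, drop = FALSE] != ref)
      hit <- hit | (mm <= floor(mismatch_rate * m))
      if (all(hit)) break
    }
    out[idx] <- hit
  }
  out
}
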