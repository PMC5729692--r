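## Internal seed-and-verify matcher for fixed-length queries against a
## genome, tolerating up to `max_mismatch` substitutions. Pigeonhole
## seeding: a query is split into max_mismatch + 1 parts; any placement
## within the mismatch budget must match at least one part exactly, so
## exact part hits (via Biostrings::matchPDict) enumerate every candidate
## placement, which is then verified with a direct mismatch count.
## Queries containing non-ACGT letters are treated as unalignable.

#' Find all genomic alignments of fixed-length sequences
#'
#' Reports every placement of each query (or its reverse complement) on the
#' genome with at most `max_mismatch` substitutions. Positions are 1-based
#' forward-strand coordinates of the placement's first base.
#'
#' @param seqs Character vector of equal-length query sequences.
#' @param genome A [Biostrings::DNAStringSet].
#' @param max_mismatch Maximum substitutions (default 2).
#' @return A tibble: `query` (index into `seqs`), `chrom`, `strand`, `pos`,
#'   `mismatches`.
#' @export
find_genome_hits <- function(seqs, genome, max_mismatch = 2L) {
  stopifnot(length(seqs) > 0)
  seqs <- toupper(seqs)
  k <- unique(nchar(seqs))
  if (length(k) != 1) abort("All query sequences must have equal length.")
  max_mismatch <- as.integer(max_mismatch)

  ok <- which(!grepl("[^ACGT]", seqs))
  empty <- tibble(query = integer(), chrom = character(), strand = character(),
                  pos = integer(), mismatches = integer())
  if (length(ok) == 0) return(empty)
  qs <- Biostrings::DNAStringSet(seqs[ok])

  npart <- max_mismatch + 1L
  bounds <- unique(as.integer(floor(seq(0, k, length.out = npart + 1L))))

  out <- list()
  for (str in c("+", "-")) {
    pats <- if (str == "+") qs else Biostrings::reverseComplement(qs)
    for (chrom in names(genome)) {
      subj <- genome[[chrom]]
      cand_q <- integer(0); cand_s <- integer(0)
      for (p in seq_len(length(bounds) - 1L)) {
        s <- bounds[p] + 1L; e <- bounds[p + 1L]
        pd <- Biostrings::PDict(Biostrings::subseq(pats, s, e))
        st <- Biostrings::startIndex(Biostrings::matchPDict(pd, subj))
        ns <- lengths(st)
        if (sum(ns) == 0) next
        cand_q <- c(cand_q, rep.int(seq_along(st), ns))
        cand_s <- c(cand_s, unlist(st, use.names = FALSE) - (s - 1L))
      }
      if (length(cand_q) == 0) next
      valid <- cand_s >= 1L & cand_s + k - 1L <= length(subj)
      cand_q <- cand_q[valid]; cand_s <- cand_s[valid]
      if (length(cand_q) == 0) next
      dup <- duplicated(cbind(cand_q, cand_s))
      cand_q <- cand_q[!dup]; cand_s <- cand_s[!dup]
      sp <- split(cand_s, cand_q)
      for (qi_chr in names(sp)) {
        qi <- as.integer(qi_chr)
        starts <- sp[[qi_chr]]
        mm <- Biostrings::neditStartingAt(pats[[qi]], subj, starting.at = starts,
                                          with.indels = FALSE)
        hit <- mm <= max_mismatch
        if (any(hit)) {
          out[[length(out) + 1L]] <- tibble(
            query = ok[qi], chrom = chrom, strand = str,
            pos = starts[hit], mismatches = as.integer(mm[hit]))
        }
      }
    }
  }
  if (length(out) == 0) empty else dplyr::bind_rows(out)
}

## Mismatch-tolerant hits of queries against a set of short subject
## sequences (used only for the optional mismatch-tolerant junction
## uniqueness mode). Subjects are few and short, so a direct scan at every
## placement is fine.
find_subject_hits <- function(seqs, subjects, max_mismatch = 2L,
                              both_strands = FALSE) {
  k <- unique(nchar(seqs))
  stopifnot(length(k) == 1)
  out <- list()
  variants <- list(`+` = seqs)
  if (both_strands) {
    variants[["-"]] <- vapply(seqs, revcomp, "", USE.NAMES = FALSE)
  }
  for (sid in names(subjects)) {
    subj <- Biostrings::DNAString(subjects[[sid]])
    L <- length(subj)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    for (str in names(variants)) {
      vs <- variants[[str]]
      for (q in seq_along(vs)) {
        if (grepl("[^ACGT]", vs[q])) next
        mm <- Biostrings::neditStartingAt(Biostrings::DNAString(vs[q]), subj,
                                          starting.at = starts,
                                          with.indels = FALSE)
        hit <- which(mm <= max_mismatch)
        if (length(hit)) {
          out[[length(out) + 1L]] <- tibble(query = q, subject = sid,
                                            strand = str, pos = hit,
                                            mismatches = as.integer(mm[hit]))
        }
      }
    }
  }
  if (length(out) == 0) {
    tibble(query = integer(), subject = character(), strand = character(),
           pos = integer(), mismatches = integer())
  } else {
    dplyr::bind_rows(out)
  }
}
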