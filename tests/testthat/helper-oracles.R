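## Independent brute-force oracles. These deliberately avoid the package's
## seed-and-verify matcher and k-mer dictionaries: every placement is scanned
## directly, so agreement is a genuine cross-check.

# all placements of each query on the genome with <= max_mismatch
# substitutions, scanning every position on both strands
oracle_genome_hits <- function(seqs, genome, max_mismatch = 2L) {
  out <- list()
  for (q in seq_along(seqs)) {
    k <- nchar(seqs[q])
    pats <- list(`+` = Biostrings::DNAString(seqs[q]),
                 `-` = Biostrings::reverseComplement(Biostrings::DNAString(seqs[q])))
    for (chrom in names(genome)) {
      subj <- genome[[chrom]]
      if (length(subj) < k) next
      starts <- seq_len(length(subj) - k + 1L)
      for (str in names(pats)) {
        mm <- Biostrings::neditStartingAt(pats[[str]], subj, starting.at = starts,
                                          with.indels = FALSE)
        hit <- which(mm <= max_mismatch)
        if (length(hit)) {
          out[[length(out) + 1L]] <- tibble::tibble(
            query = q, chrom = chrom, strand = str, pos = hit,
            mismatches = as.integer(mm[hit]))
        }
      }
    }
  }
  if (!length(out)) {
    tibble::tibble(query = integer(), chrom = character(), strand = character(),
                   pos = integer(), mismatches = integer())
  } else {
    dplyr::bind_rows(out)
  }
}

# exact-match positions of a read (and its reverse complement) across all
# junction sequences, comparing the read against every placement explicitly
oracle_junction_matches <- function(seq, junctions) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  k <- nchar(seq)
  total <- 0L
  jid <- NA_character_
  for (i in seq_len(nrow(junctions))) {
    js <- junctions$seq[i]
    L <- nchar(js)
    if (L < k) next
    for (p in seq_len(L - k + 1L)) {
      w <- substr(js, p, p + k - 1L)
      for (s in c(seq, rc)) {
        if (w == s) { total <- total + 1L; jid <- junctions$junction_id[i] }
      }
    }
  }
  list(n = total, junction_id = if (total == 1L) jid else NA_character_)
}

# per-read brute-force junction count table (triplet x junction type)
oracle_junction_counts <- function(reads, catalog) {
  k <- catalog$k
  counts <- list()
  for (s in unique(reads$sequence)) {
    if (nchar(s) != k) next
    hit <- oracle_junction_matches(s, catalog$junctions)
    if (!is.na(hit$junction_id)) {
      counts[[s]] <- c(hit$junction_id, sum(reads$sequence == s))
    }
  }
  tb <- tibble::tibble(
    junction_id = vapply(counts, `[`, "", 1),
    n = as.integer(vapply(counts, `[`, "", 2)))
  tb |>
    dplyr::group_by(junction_id) |>
    dplyr::summarise(n = sum(n), .groups = "drop")
}

# exhaustive effective-positions computation per junction
oracle_effective_positions <- function(catalog, genome, max_mismatch = 2L) {
  k <- catalog$k
  jt <- catalog$junctions
  all_kmers <- character(0)
  per_j <- vector("list", nrow(jt))
  for (i in seq_len(nrow(jt))) {
    L <- jt$L[i]
    if (L < k) { per_j[[i]] <- character(0); next }
    pos <- seq_len(L - k + 1L)
    per_j[[i]] <- substring(jt$seq[i], pos, pos + k - 1L)
    all_kmers <- c(all_kmers, per_j[[i]])
  }
  occ <- table(all_kmers)
  eff <- integer(nrow(jt))
  for (i in seq_len(nrow(jt))) {
    kms <- per_j[[i]]
    if (!length(kms)) { eff[i] <- 0L; next }
    n_eff <- 0L
    for (km in kms) {
      gh <- oracle_genome_hits(km, genome, max_mismatch)
      if (nrow(gh) == 0 && occ[[km]] == 1L) n_eff <- n_eff + 1L
    }
    eff[i] <- n_eff
  }
  tibble::tibble(junction_id = jt$junction_id, effective_positions = eff)
}

# brute-force adapter contamination check for a single read
oracle_adapter_hit <- function(read, adapter, min_overlap = 10L, rate = 0.10) {
  r <- strsplit(read, "")[[1]]; a <- strsplit(adapter, "")[[1]]
  k <- length(r); la <- length(a)
  for (off in (-(la - 1L)):(k - 1L)) {
    cols <- max(1L, off + 1L):min(k, off + la)
    m <- length(cols)
    if (m <= min_overlap) next
    mm <- sum(r[cols] != a[cols - off])
    if (mm <= floor(rate * m)) return(TRUE)
  }
  FALSE
}

# least-squares branch-length fit of a fixed topology to a distance matrix
ls_fit_rss <- function(tree, d) {
  labs <- rownames(d)
  n <- length(labs)
  pairs <- utils::combn(n, 2)
  n_edge <- nrow(tree$edge)
  A <- matrix(0, ncol(pairs), n_edge)
  y <- numeric(ncol(pairs))
  tip_idx <- match(labs, tree$tip.label)
  for (p in seq_len(ncol(pairs))) {
    i <- tip_idx[pairs[1, p]]; j <- tip_idx[pairs[2, p]]
    path <- ape::nodepath(tree, i, j)
    for (e in seq_len(n_edge)) {
      a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
      hits <- which(path[-length(path)] == a & path[-1] == b |
                      path[-length(path)] == b & path[-1] == a)
      if (length(hits)) A[p, e] <- 1
    }
    y[p] <- d[pairs[1, p], pairs[2, p]]
  }
  fit <- stats::lm.fit(A, y)
  sum(fit$residuals^2)
}

# best topology for a distance matrix by exhaustive least squares
oracle_best_topology <- function(d) {
  labs <- rownames(d)
  tops <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  rss <- vapply(tops, ls_fit_rss, numeric(1), d = d)
  tops[[which.min(rss)]]
}

# do two label vectors induce the same partition of the samples?
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}
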