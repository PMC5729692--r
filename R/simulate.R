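#' Simulate orthologous genomes and annotations for a design
#'
#' Builds one genome (a single chromosome) per species group from a common
#' ancestral sequence. Gene structures (exon/intron lengths, strand, the
#' designated cassette exon) are drawn once for the ancestor and preserved
#' in every species, so exon orthology holds by construction; each species'
#' sequence is derived by independent per-site substitutions at the design's
#' `divergence` rate (a star phylogeny). The first `n_cassette_exons` genes
#' carry one designated cassette exon (the middle exon); all other splicing
#' is constitutive.
#'
#' @param design A [simulation_design()].
#' @return An object of class `sim_genomes`: a list with `genomes` (named
#'   list of [Biostrings::DNAStringSet], one chromosome per species),
#'   `annotation` (tibble of exons with 1-based inclusive coordinates),
#'   `gene_orthology` and `exon_orthology` tibbles, and the `design`.
#' @export
simulate_genomes <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  d <- design
  withr::with_seed(substream_seed(d$seed, 1L), {
    n_ex <- d$n_exons_per_gene
    cassette_idx <- as.integer(ceiling(n_ex / 2))  # always internal for n_ex >= 3

    structures <- lapply(seq_len(d$n_genes), function(g) {
      list(
        exon_len = sample(d$exon_length[1]:d$exon_length[2], n_ex, replace = TRUE),
        intron_len = sample(d$intron_length[1]:d$intron_length[2], n_ex - 1L,
                            replace = TRUE),
        strand = sample(c("+", "-"), 1L),
        is_cassette = g <= d$n_cassette_exons
      )
    })
    if (any(vapply(structures, function(s) any(c(s$exon_len, s$intron_len) < 1),
                   logical(1)))) {
      abort("Simulated exon/intron lengths must be >= 1 nt.")
    }

    bases <- c("A", "C", "G", "T")
    anc_locus <- lapply(structures, function(s) {
      total <- sum(s$exon_len) + sum(s$intron_len)
      sample(bases, total, replace = TRUE)
    })
    spacer_len <- sample(150:300, d$n_genes + 1L, replace = TRUE)
    anc_spacer <- lapply(spacer_len, function(n) sample(bases, n, replace = TRUE))

    mutate_seq <- function(x, rate) {
      if (rate <= 0) return(x)
      hit <- which(runif(length(x)) < rate)
      if (length(hit)) {
        x[hit] <- vapply(x[hit], function(b) sample(setdiff(bases, b), 1L), "")
      }
      x
    }

    genomes <- list()
    ann <- list()
    for (sp in d$species) {
      cursor <- 0L
      chrom_parts <- character(0)
      rows <- list()
      for (g in seq_len(d$n_genes)) {
        chrom_parts <- c(chrom_parts, paste(mutate_seq(anc_spacer[[g]], d$divergence),
                                            collapse = ""))
        cursor <- cursor + spacer_len[g]
        s <- structures[[g]]
        locus <- mutate_seq(anc_locus[[g]], d$divergence)
        locus_len <- length(locus)
        # exon offsets within the transcript-oriented locus
        offs <- integer(0); pos <- 0L
        starts_tx <- integer(n_ex); ends_tx <- integer(n_ex)
        for (e in seq_len(n_ex)) {
          starts_tx[e] <- pos + 1L
          ends_tx[e] <- pos + s$exon_len[e]
          pos <- ends_tx[e] + if (e < n_ex) s$intron_len[e] else 0L
        }
        if (s$strand == "+") {
          locus_str <- paste(locus, collapse = "")
          g_start <- cursor + starts_tx
          g_end <- cursor + ends_tx
        } else {
          locus_str <- revcomp(paste(locus, collapse = ""))
          g_start <- cursor + locus_len - ends_tx + 1L
          g_end <- cursor + locus_len - starts_tx + 1L
        }
        chrom_parts <- c(chrom_parts, locus_str)
        cursor <- cursor + locus_len
        gene_id <- sprintf("%s_g%03d", sp, g)
        rows[[g]] <- tibble(
          species = sp, seqnames = "chr1",
          gene_id = gene_id,
          transcript_id = paste0(gene_id, "_t1"),
          gene_group = sprintf("grp%03d", g),
          exon_number = seq_len(n_ex),
          start = g_start, end = g_end, strand = s$strand,
          is_cassette = s$is_cassette & seq_len(n_ex) == cassette_idx
        )
      }
      chrom_parts <- c(chrom_parts, paste(mutate_seq(anc_spacer[[d$n_genes + 1L]],
                                                     d$divergence), collapse = ""))
      chrom <- paste(chrom_parts, collapse = "")
      genomes[[sp]] <- Biostrings::DNAStringSet(setNames(chrom, "chr1"))
      ann[[sp]] <- dplyr::bind_rows(rows)
    }
    annotation <- dplyr::bind_rows(ann)

    gene_orthology <- annotation |>
      dplyr::distinct(.data$gene_group, .data$species, .data$gene_id) |>
      dplyr::rename(group_id = "gene_group")
    exon_orthology <- annotation |>
      dplyr::filter(.data$is_cassette) |>
      dplyr::transmute(
        exon_group_id = sub("^grp", "ex", .data$gene_group),
        gene_group = .data$gene_group, species = .data$species,
        gene_id = .data$gene_id, transcript_id = .data$transcript_id,
        seqnames = .data$seqnames, strand = .data$strand,
        a_start = .data$start, a_end = .data$end)

    structure(list(genomes = genomes, annotation = annotation,
                   gene_orthology = gene_orthology,
                   exon_orthology = exon_orthology, design = d),
              class = "sim_genomes")
  })
}

#' @export
print.sim_genomes <- function(x, ...) {
  cat("<sim_genomes> ", length(x$genomes), " genome(s), ",
      x$design$n_genes, " genes each, ",
      nrow(x$exon_orthology) / max(1, length(x$genomes)),
      " cassette exon group(s)\n", sep = "")
  invisible(x)
}

#' Simulate true expression and PSI tables for a design
#'
#' True log2 expression for gene group g in sample j is
#' `mu_g + tissue_g + species_g + altitude_g + noise`, with each effect drawn
#' per gene and factor level from a centered normal with the design's
#' variance component. True PSI is generated the same way on the logit scale
#' and back-transformed to `100 * plogis(x)`, so PSI always lies in (0, 100).
#'
#' @param design A [simulation_design()].
#' @return An object of class `sim_truth`: a list with `samples` (the
#'   [sample_sheet()]), `expression` (tibble, `gene_group` x sample columns,
#'   log2 scale), and `psi` (tibble, `exon_group_id` x sample columns,
#'   0-100 scale).
#' @export
simulate_truth <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  d <- design
  samples <- sample_sheet(d)
  withr::with_seed(substream_seed(d$seed, 2L), {
    expr <- effect_matrix(
      n_features = d$n_genes,
      base = runif(d$n_genes, 3, 8),
      samples = samples,
      variances = d$expr_variance)
    rownames(expr) <- sprintf("grp%03d", seq_len(d$n_genes))

    psi_logit <- effect_matrix(
      n_features = d$n_cassette_exons,
      base = rnorm(max(d$n_cassette_exons, 1L), 0, 1.2)[seq_len(d$n_cassette_exons)],
      samples = samples,
      variances = d$psi_variance)
    psi <- psi_logit
    psi[] <- 100 * plogis(psi_logit)  # keep matrix shape even when empty
    if (d$n_cassette_exons > 0) {
      rownames(psi) <- sprintf("ex%03d", seq_len(d$n_cassette_exons))
    }

    structure(list(
      samples = samples,
      expression = mat_to_wide(expr, "gene_group"),
      psi = mat_to_wide(psi, "exon_group_id")
    ), class = "sim_truth")
  })
}

## additive per-(feature, factor level) effects + iid residual
effect_matrix <- function(n_features, base, samples, variances) {
  n_s <- nrow(samples)
  out <- matrix(0, n_features, n_s,
                dimnames = list(NULL, samples$sample_id))
  if (n_features == 0) return(out)
  factor_cols <- setdiff(names(variances), "residual")
  effects <- lapply(factor_cols, function(f) {
    lev <- unique(samples[[f]])
    m <- matrix(rnorm(n_features * length(lev), 0, sqrt(variances[[f]])),
                n_features, length(lev), dimnames = list(NULL, lev))
    m
  })
  names(effects) <- factor_cols
  for (j in seq_len(n_s)) {
    x <- base
    for (f in factor_cols) x <- x + effects[[f]][, samples[[f]][j]]
    out[, j] <- x + rnorm(n_features, 0, sqrt(variances[["residual"]]))
  }
  out
}

mat_to_wide <- function(m, key) {
  tb <- tibble::as_tibble(m)
  tb[[key]] <- rownames(m) %||% character(nrow(m))
  dplyr::relocate(tb, dplyr::all_of(key))
}

#' Extract the numeric feature matrix from a wide table
#'
#' Wide result tables in this package keep one key column (e.g. `gene_group`)
#' followed by one numeric column per sample. This strips the key into
#' rownames and returns the numeric matrix (features x samples).
#'
#' @param data A wide tibble or a numeric matrix (returned unchanged).
#' @param key Key column name; defaults to the first non-numeric column.
#' @return A numeric matrix with feature rownames and sample colnames.
#' @export
feature_matrix <- function(data, key = NULL) {
  if (is.matrix(data)) return(data)
  stopifnot(is.data.frame(data))
  if (is.null(key)) {
    nonnum <- names(data)[!vapply(data, is.numeric, logical(1))]
    key <- if (length(nonnum)) nonnum[[1]] else NULL
  }
  keep <- setdiff(names(data), key)
  m <- as.matrix(data[keep])
  if (!is.null(key)) rownames(m) <- data[[key]]
  m
}

#' Simulate single-end FASTQ reads for every sample
#'
#' For each sample, each gene contributes `Poisson(depth * 2^expr / mean(2^expr))`
#' reads; for cassette genes, each read's source isoform (inclusion vs
#' skipping) is Bernoulli with the gene's true PSI/100. Read start positions
#' are uniform over the transcript; substitution errors are applied per base
#' at `error_rate`; qualities are a constant high phred (Sanger phred+33)
#' except at `low_quality_positions`. Transcripts shorter than the read
#' length contribute no reads and are logged.
#'
#' @param sim A [simulate_genomes()] result.
#' @param truth A [simulate_truth()] result for the same design.
#' @param out_dir Optional directory; when given, one `<sample_id>.fastq`
#'   is written per sample.
#' @param quality_phred Constant phred score for base qualities (default 35).
#' @param low_quality_positions Optional integer vector of read positions
#'   forced to phred 2 in every read (handy for exercising QC filters).
#' @return An object of class `sim_reads`: a list with `reads` (named list
#'   of per-sample tibbles `read_id`/`sequence`/`quality`), and `log`
#'   (tibble with per-sample read totals and skipped-transcript counts).
#' @export
simulate_reads <- function(sim, truth, out_dir = NULL,
                           quality_phred = 35L, low_quality_positions = NULL) {
  stopifnot(inherits(sim, "sim_genomes"), inherits(truth, "sim_truth"))
  d <- sim$design
  k <- d$read_length
  samples <- truth$samples
  expr_m <- feature_matrix(truth$expression, "gene_group")
  psi_m <- feature_matrix(truth$psi, "exon_group_id")
  if (!setequal(colnames(expr_m), samples$sample_id)) {
    abort("Truth tables do not match the design's sample sheet.")
  }

  # per-species spliced transcript sequences (inclusion and skipping isoforms)
  tx <- transcript_isoforms(sim)

  qual_chr <- function() {
    q <- rep(as.integer(quality_phred), k)
    if (!is.null(low_quality_positions)) {
      lp <- as.integer(low_quality_positions)
      stopifnot(all(lp >= 1 & lp <= k))
      q[lp] <- 2L
    }
    rawToChar(as.raw(q + 33L))
  }
  qstr <- qual_chr()

  reads <- vector("list", nrow(samples))
  names(reads) <- samples$sample_id
  log_rows <- vector("list", nrow(samples))

  for (i in seq_len(nrow(samples))) {
    smp <- samples[i, ]
    sid <- smp$sample_id
    sp_tx <- tx[[smp$species]]
    expr <- expr_m[sp_tx$gene_group, sid]
    lambda <- d$depth * 2^expr / mean(2^expr)
    withr::with_seed(substream_seed(d$seed, 1000L + i), {
      n_reads <- rpois(length(lambda), lambda)
      skipped <- 0L
      seqs <- character(0); ids <- character(0)
      for (g in seq_along(lambda)) {
        n_g <- n_reads[g]
        if (n_g == 0) next
        inc_seq <- sp_tx$inclusion[g]
        if (is.na(sp_tx$exon_group_id[g])) {
          n_inc <- n_g
        } else {
          # PSI is a molar fraction of transcripts; reads sample fragments
          # uniformly, so an isoform's read share is molar fraction times
          # its number of read start positions
          p <- psi_m[sp_tx$exon_group_id[g], sid] / 100
          w_inc <- max(nchar(inc_seq) - k + 1L, 0L)
          w_skp <- max(nchar(sp_tx$skipping[g]) - k + 1L, 0L)
          denom <- p * w_inc + (1 - p) * w_skp
          p_read <- if (denom > 0) p * w_inc / denom else 0
          n_inc <- rbinom(1L, n_g, p_read)
        }
        for (iso in c("inc", "skp")) {
          n_iso <- if (iso == "inc") n_inc else n_g - n_inc
          if (n_iso == 0) next
          src <- if (iso == "inc") inc_seq else sp_tx$skipping[g]
          len <- nchar(src)
          if (len < k) { skipped <- skipped + n_iso; next }
          st <- sample.int(len - k + 1L, n_iso, replace = TRUE)
          rs <- substring(src, st, st + k - 1L)
          if (d$error_rate > 0) rs <- add_read_errors(rs, d$error_rate)
          seqs <- c(seqs, rs)
          ids <- c(ids, sprintf("%s|%s|%s|%d", sid, sp_tx$gene_id[g], iso,
                                seq_along(rs)))
        }
      }
      reads[[sid]] <- tibble(read_id = ids, sequence = seqs,
                             quality = rep(qstr, length(seqs)))
      log_rows[[i]] <- tibble(sample_id = sid, n_reads = length(seqs),
                              n_skipped = skipped)
    })
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      write_fastq(reads[[sid]], file.path(out_dir, paste0(sid, ".fastq")))
    }
  }

  structure(list(reads = reads, log = dplyr::bind_rows(log_rows)),
            class = "sim_reads")
}

#' @export
print.sim_reads <- function(x, ...) {
  cat("<sim_reads> ", nrow(x$log), " sample(s), ",
      sum(x$log$n_reads), " reads total\n", sep = "")
  invisible(x)
}

## Spliced transcript sequences per species: inclusion isoform (all exons)
## and, for cassette genes, the skipping isoform (cassette exon dropped).
transcript_isoforms <- function(sim) {
  out <- list()
  for (sp in names(sim$genomes)) {
    genome <- sim$genomes[[sp]]
    ann <- dplyr::filter(sim$annotation, .data$species == sp)
    genes <- dplyr::distinct(ann, .data$gene_id, .data$gene_group)
    ex_orth <- dplyr::filter(sim$exon_orthology, .data$species == sp)
    inc <- character(nrow(genes)); skp <- rep(NA_character_, nrow(genes))
    egid <- rep(NA_character_, nrow(genes))
    for (g in seq_len(nrow(genes))) {
      exons <- ann[ann$gene_id == genes$gene_id[g], ]
      exons <- exons[order(exons$exon_number), ]
      inc[g] <- spliced_sequence(genome, exons)
      if (any(exons$is_cassette)) {
        skp[g] <- spliced_sequence(genome, exons[!exons$is_cassette, ])
        m <- match(genes$gene_id[g], ex_orth$gene_id)
        egid[g] <- ex_orth$exon_group_id[m]
      }
    }
    out[[sp]] <- list(gene_id = genes$gene_id, gene_group = genes$gene_group,
                      inclusion = inc, skipping = skp, exon_group_id = egid)
  }
  out
}

## Exons in transcript (5'->3') order; minus-strand exons reverse-complemented.
spliced_sequence <- function(genome, exons) {
  chrom <- genome[[exons$seqnames[1]]]
  parts <- vapply(seq_len(nrow(exons)), function(i) {
    s <- as.character(Biostrings::subseq(chrom, exons$start[i], exons$end[i]))
    if (exons$strand[i] == "-") revcomp(s) else s
  }, "")
  paste(parts, collapse = "")
}

add_read_errors <- function(reads, error_rate) {
  k <- nchar(reads[1])
  n_err <- rbinom(length(reads), k, error_rate)
  hit <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(k, n_err[i])
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(bases, b), 1L), "")
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Write a simulation to disk in standard formats
#'
#' Writes, per species, a genome FASTA and an exon GTF (1-based inclusive
#' coordinates with `gene_id`/`transcript_id` attributes), plus TSV
#' orthology tables, truth tables, and the sample sheet.
#'
#' @param sim A [simulate_genomes()] result.
#' @param truth Optional [simulate_truth()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of written paths.
#' @export
write_simulation <- function(sim, dir, truth = NULL) {
  stopifnot(inherits(sim, "sim_genomes"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list()
  for (sp in names(sim$genomes)) {
    fa <- file.path(dir, paste0(sp, ".fa"))
    Biostrings::writeXStringSet(sim$genomes[[sp]], fa)
    gtf <- file.path(dir, paste0(sp, ".gtf"))
    write_gtf_exons(dplyr::filter(sim$annotation, .data$species == sp), gtf)
    paths[[sp]] <- c(fasta = fa, gtf = gtf)
  }
  readr::write_tsv(sim$gene_orthology, file.path(dir, "gene_orthology.tsv"))
  readr::write_tsv(sim$exon_orthology, file.path(dir, "exon_orthology.tsv"))
  if (!is.null(truth)) {
    readr::write_tsv(truth$samples, file.path(dir, "samples.tsv"))
    readr::write_tsv(truth$expression, file.path(dir, "true_expression.tsv"))
    readr::write_tsv(truth$psi, file.path(dir, "true_psi.tsv"))
  }
  invisible(paths)
}
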