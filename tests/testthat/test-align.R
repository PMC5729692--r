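test_that("seed-and-verify matcher agrees with the exhaustive scan", {
  withr::with_seed(31, {
    chrom <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
                   collapse = "")
    genome <- Biostrings::DNAStringSet(setNames(chrom, "chr1"))
    k <- 36
    queries <- character(60)
    for (i in seq_along(queries)) {
      s <- sample(6000 - k + 1, 1)
      q <- substr(chrom, s, s + k - 1)
      n_mut <- sample(0:3, 1)  # some queries exceed the budget
      if (n_mut > 0) {
        pos <- sample(k, n_mut)
        ch <- strsplit(q, "")[[1]]
        ch[pos] <- vapply(ch[pos],
                          function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                          "")
        q <- paste(ch, collapse = "")
      }
      if (i %% 3 == 0) {  # reverse-complement some queries
        q <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
      }
      queries[i] <- q
    }
  })
  got <- find_genome_hits(queries, genome, max_mismatch = 2) |>
    dplyr::arrange(query, chrom, strand, pos)
  want <- oracle_genome_hits(queries, genome, max_mismatch = 2) |>
    dplyr::arrange(query, chrom, strand, pos)
  expect_equal(as.data.frame(got), as.data.frame(want))
})

test_that("alignment uniqueness separates unique, multi-hit, and unaligned reads", {
  withr::with_seed(32, {
    unit <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
    rest <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
  })
  # 'unit' occurs twice: reads from it are aligned but not unique
  genome <- Biostrings::DNAStringSet(setNames(paste0(unit, rest, unit), "chr1"))
  k <- 40
  reads <- tibble::tibble(
    read_id = c("uniq", "dup", "none"),
    sequence = c(substr(rest, 101, 140), substr(unit, 11, 50), strrep("ACGT", 10)))
  res <- align_reads(reads, genome, k = k)
  aln <- res$alignments
  expect_true(aln$unique[aln$read_id == "uniq"])
  expect_equal(aln$mismatches[aln$read_id == "uniq"], 0L)
  expect_false(aln$unique[aln$read_id == "dup"])
  expect_equal(aln$n_hits[aln$read_id == "dup"], 2L)
  expect_true("none" %in% res$unaligned$read_id ||
                !"none" %in% aln$read_id)  # periodic read may align by chance
})

test_that("junction-spanning reads land in the unaligned set", {
  d <- tiny_design(n_genes = 4, n_cassette_exons = 4, read_length = 50,
                   intron_length = c(80, 150), seed = 41)
  sim <- simulate_genomes(d)
  sp <- "sp1"
  genome <- sim$genomes[[sp]]
  ann <- dplyr::filter(sim$annotation, species == sp)
  exons <- ann[ann$gene_id == ann$gene_id[1], ]
  exons <- exons[order(exons$exon_number), ]
  tx <- altisplice:::spliced_sequence(genome, exons)
  # read straddling the first splice boundary, 25 nt on each side
  e1_len <- exons$end[exons$exon_number == 1] - exons$start[exons$exon_number == 1] + 1
  read <- substr(tx, e1_len - 24, e1_len + 25)
  res <- align_reads(tibble::tibble(read_id = "span", sequence = read),
                     genome, k = 50)
  expect_equal(res$unaligned$read_id, "span")
  expect_equal(nrow(oracle_genome_hits(read, genome, 2)), 0)
})

test_that("reads of the wrong length are rejected with a summary", {
  genome <- Biostrings::DNAStringSet(setNames(strrep("ACGT", 100), "chr1"))
  reads <- tibble::tibble(read_id = c("a", "b"),
                          sequence = c(strrep("A", 30), strrep("A", 31)))
  expect_warning(res <- align_reads(reads, genome, k = 30), "rejected")
  expect_equal(attr(res, "rejected"), 1L)
})

test_that("junction counting matches per-read brute-force assignment", {
  d <- tiny_design(n_genes = 8, n_cassette_exons = 6, depth = 80,
                   read_length = 44, seed = 42)
  sim <- simulate_genomes(d)
  truth <- simulate_truth(d)
  reads <- simulate_reads(sim, truth)
  sp <- "sp1"
  ann <- dplyr::filter(sim$annotation, species == sp)
  tr <- extract_cassette_triplets(ann)
  cat_ <- build_junction_catalog(sim$genomes[[sp]], tr, d$read_length)
  sid <- truth$samples$sample_id[1]
  aln <- align_reads(reads$reads[[sid]], sim$genomes[[sp]], k = d$read_length)
  jc <- count_junction_reads(aln$unaligned, cat_)

  oracle <- oracle_junction_counts(aln$unaligned, cat_)
  got <- jc$assignments |> dplyr::count(junction_id, name = "n")
  expect_equal(as.data.frame(dplyr::arrange(got, junction_id)),
               as.data.frame(dplyr::arrange(oracle, junction_id)))
  # counts propagate to every member triplet
  expect_setequal(jc$counts$triplet_id, tr$triplet_id)
})

test_that("a read matching two junction records counts for neither", {
  jA <- paste0(strrep("A", 20), strrep("C", 20))
  jB <- paste0(strrep("A", 20), strrep("C", 20), strrep("G", 10))
  catalog <- structure(list(
    junctions = tibble::tibble(junction_id = c("J1", "J2"), type = "C1A",
                               seq = c(jA, jB), left_len = 20, right_len = c(20, 30),
                               L = nchar(c(jA, jB))),
    members = tibble::tibble(junction_id = c("J1", "J2"),
                             triplet_id = c("t1", "t2"), type = "C1A"),
    k = 40L), class = "junction_catalog")
  reads <- tibble::tibble(read_id = "amb", sequence = jA)
  jc <- count_junction_reads(reads, catalog)
  expect_equal(nrow(jc$assignments), 0)
  expect_true(all(jc$counts$c1a == 0))
})

test_that("inclusion-only samples yield zero skipping-junction counts", {
  d <- tiny_design(n_genes = 4, n_cassette_exons = 4, depth = 120,
                   read_length = 44, seed = 43)
  sim <- simulate_genomes(d)
  truth <- simulate_truth(d)
  pm <- truth$psi
  num <- vapply(pm, is.numeric, logical(1))
  pm[num] <- lapply(pm[num], function(x) rep(100, length(x)))
  truth$psi <- pm
  reads <- simulate_reads(sim, truth)
  sp <- "sp1"; sid <- truth$samples$sample_id[1]
  ann <- dplyr::filter(sim$annotation, species == sp)
  tr <- extract_cassette_triplets(ann)
  cat_ <- build_junction_catalog(sim$genomes[[sp]], tr, d$read_length)
  aln <- align_reads(reads$reads[[sid]], sim$genomes[[sp]], k = d$read_length)
  jc <- count_junction_reads(aln$unaligned, cat_)
  cass <- tr$triplet_id[tr$a_start %in%
                          sim$exon_orthology$a_start[sim$exon_orthology$species == sp]]
  expect_true(all(jc$counts$c1c2[jc$counts$triplet_id %in% cass] == 0))
  expect_gt(sum(jc$counts$c1a), 0)
})
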