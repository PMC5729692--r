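## hand-built annotation helper: one transcript on one chromosome; rows are
## given in transcript (5'->3') order
tx_annotation <- function(exon_starts, exon_ends, strand = "+",
                          gene = "gA", chrom = "chr1") {
  tibble::tibble(seqnames = chrom, start = exon_starts, end = exon_ends,
                 strand = strand, gene_id = gene,
                 transcript_id = paste0(gene, "_t1"),
                 exon_number = seq_along(exon_starts))
}

random_genome <- function(len, seed = 1, name = "chr1") {
  withr::with_seed(seed, {
    Biostrings::DNAStringSet(setNames(
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      name))
  })
}

test_that("internal exons yield n-2 triplets; short transcripts yield none", {
  ann3 <- tx_annotation(c(1, 201, 401), c(100, 300, 500))
  ann2 <- tx_annotation(c(1, 201), c(100, 300), gene = "gB")
  ann5 <- tx_annotation(c(1, 201, 401, 601, 801),
                        c(100, 300, 500, 700, 900), gene = "gC")
  expect_equal(nrow(extract_cassette_triplets(ann3)), 1)
  expect_equal(nrow(extract_cassette_triplets(ann2)), 0)
  expect_equal(nrow(extract_cassette_triplets(ann5)), 3)
  # identical coordinate triples across transcripts collapse to one
  ann_dup <- dplyr::bind_rows(ann3, dplyr::mutate(ann3, transcript_id = "gA_t2"))
  expect_equal(nrow(extract_cassette_triplets(ann_dup)), 1)
})

test_that("junction lengths follow the k-8 retrieval rule", {
  k <- 100
  genome <- random_genome(2000)
  ann <- tx_annotation(c(1, 301, 601), c(200, 500, 800))
  tr <- extract_cassette_triplets(ann)
  cat100 <- build_junction_catalog(genome, tr, k)
  expect_equal(sort(unique(cat100$junctions$L)), 2 * (k - 8))

  # short cassette exon: whole exon retrieved
  ann_short <- tx_annotation(c(1, 301, 601), c(200, 320, 800))
  cat_s <- build_junction_catalog(genome, extract_cassette_triplets(ann_short), k)
  j <- cat_s$junctions
  mem <- cat_s$members
  c1a <- j$L[j$junction_id == mem$junction_id[mem$type == "C1A"][1]]
  expect_equal(c1a, (k - 8) + 20)
  ac2 <- j$L[j$junction_id == mem$junction_id[mem$type == "AC2"][1]]
  expect_equal(ac2, 20 + (k - 8))
  c1c2 <- j$L[j$junction_id == mem$junction_id[mem$type == "C1C2"][1]]
  expect_equal(c1c2, 2 * (k - 8))
})

test_that("junctions are built in transcript orientation on both strands", {
  k <- 40
  genome <- random_genome(3000, seed = 4)
  chrom <- as.character(genome[[1]])
  ann_plus <- tx_annotation(c(101, 501, 901), c(300, 700, 1100), strand = "+")
  cat_p <- build_junction_catalog(genome, extract_cassette_triplets(ann_plus), k)

  # a minus-strand transcript over the reverse complement of the same exons
  rc_genome <- Biostrings::DNAStringSet(setNames(
    as.character(Biostrings::reverseComplement(genome[[1]])), "chr1"))
  L <- nchar(chrom)
  flip <- function(s, e) c(L - e + 1, L - s + 1)
  coords <- rbind(flip(101, 300), flip(501, 700), flip(901, 1100))
  ann_minus <- tx_annotation(coords[, 1], coords[, 2], strand = "-")
  cat_m <- build_junction_catalog(rc_genome, extract_cassette_triplets(ann_minus), k)
  expect_setequal(cat_p$junctions$seq, cat_m$junctions$seq)
})

test_that("identical junction sequences collapse into one member-listing record", {
  k <- 30
  # two genes with identical exon sequences at different loci
  withr::with_seed(5, {
    unit <- paste(sample(c("A", "C", "G", "T"), 700, replace = TRUE),
                  collapse = "")
  })
  genome <- Biostrings::DNAStringSet(setNames(paste0(unit, unit), "chr1"))
  ann <- dplyr::bind_rows(
    tx_annotation(c(1, 201, 401), c(100, 300, 500), gene = "gA"),
    tx_annotation(700 + c(1, 201, 401), 700 + c(100, 300, 500), gene = "gB"))
  tr <- extract_cassette_triplets(ann)
  expect_equal(nrow(tr), 2)
  cat_ <- build_junction_catalog(genome, tr, k)
  expect_equal(nrow(cat_$junctions), 3)   # all three shared
  expect_equal(nrow(cat_$members), 6)
  expect_true(all(table(cat_$members$junction_id) == 2))
})

test_that("exon beyond chromosome bounds is a hard error naming the triplet", {
  genome <- random_genome(400)
  ann <- tx_annotation(c(1, 101, 301), c(90, 200, 500))
  tr <- extract_cassette_triplets(ann)
  expect_error(build_junction_catalog(genome, tr, 30), "tri00001")
})

test_that("mappability attains the upper bound on clean junctions", {
  k <- 40
  genome <- random_genome(4000, seed = 6)
  ann <- tx_annotation(c(101, 501, 901), c(300, 700, 1100))
  cat_ <- build_junction_catalog(genome, extract_cassette_triplets(ann), k)
  cat_ <- compute_effective_mappability(cat_, genome)
  j <- cat_$junctions
  expect_true(all(j$effective_positions == j$L - k + 1))
  expect_true(all(j$L - k + 1 <= k - 15))
  expect_true(all(j$max_positions == k - 15))
})

test_that("a spliced pseudogene copy of the C1A junction kills its k-mers", {
  k <- 40
  genome <- random_genome(3000, seed = 7)
  ann <- tx_annotation(c(101, 501, 901), c(300, 700, 1100))
  # insert a processed copy of the spliced C1-A boundary elsewhere
  chrom <- as.character(genome[[1]])
  dup <- paste0(substr(chrom, 241, 300), substr(chrom, 501, 560))
  genome2 <- Biostrings::DNAStringSet(setNames(paste0(chrom, dup), "chr1"))
  cat_ <- build_junction_catalog(genome2, extract_cassette_triplets(ann), k)
  cat_ <- compute_effective_mappability(cat_, genome2)
  j <- cat_$junctions
  mem <- cat_$members
  c1a <- j[j$junction_id == mem$junction_id[mem$type == "C1A"], ]
  expect_equal(c1a$effective_positions, 0L)
  other <- j[j$junction_id != c1a$junction_id, ]
  expect_true(all(other$effective_positions == other$L - k + 1))
  expect_equal(cat_$junctions$effective_positions,
               oracle_effective_positions(cat_, genome2)$effective_positions)
})

test_that("a k-mer shared by two junction records counts for neither", {
  k <- 30  # part length 22
  withr::with_seed(9, {
    rseq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
    c1 <- rseq(60); a1 <- rseq(40); c2 <- rseq(60)
    a_b <- substr(c2, 1, 8)          # gB cassette exon = first 8 nt of gA's C2
    c2b <- rseq(60)
    intr <- rseq(50)
    spacers <- replicate(8, rseq(50))
  })
  chrom <- paste0(spacers[1], c1, intr, a1, intr, c2, spacers[2],
                  c1, intr, a_b, intr, c2b, spacers[3])
  genome <- Biostrings::DNAStringSet(setNames(chrom, "chr1"))
  off <- nchar(spacers[1])
  gA_starts <- off + cumsum(c(1, 60 + 50, 40 + 50))
  gA_ends <- gA_starts + c(59, 39, 59)
  off_b <- off + 60 + 50 + 40 + 50 + 60 + nchar(spacers[2])
  gB_starts <- off_b + cumsum(c(1, 60 + 50, 8 + 50))
  gB_ends <- gB_starts + c(59, 7, 59)
  ann <- dplyr::bind_rows(
    tx_annotation(gA_starts, gA_ends, gene = "gA"),
    tx_annotation(gB_starts, gB_ends, gene = "gB"))
  cat_ <- build_junction_catalog(genome, extract_cassette_triplets(ann), k)
  cat_ <- compute_effective_mappability(cat_, genome)
  # gB's C1A junction (22 + 8 = 30 nt) has exactly one k-mer, which also
  # occurs as the first k-mer of gA's C1C2 junction -> unique for neither
  j <- cat_$junctions; mem <- cat_$members
  trB <- extract_cassette_triplets(ann)$triplet_id[2]
  c1a_b <- mem$junction_id[mem$triplet_id == trB & mem$type == "C1A"]
  expect_equal(j$L[j$junction_id == c1a_b], 30)
  expect_equal(j$effective_positions[j$junction_id == c1a_b], 0L)
  oracle <- oracle_effective_positions(cat_, genome)
  expect_equal(j$effective_positions, oracle$effective_positions)
})
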