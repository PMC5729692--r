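#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ file (Sanger phred+33 qualities).
#' @return A tibble with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(read_id = names(x) %||% as.character(seq_along(x)),
         sequence = unname(as.character(x)),
         quality = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' Write a reads tibble to FASTQ
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality` columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  q <- Biostrings::BStringSet(reads$quality)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read exon records from a GTF file
#'
#' Imports a GTF (1-based inclusive coordinates) and returns its exon rows
#' in the annotation layout used throughout this package.
#'
#' @param path GTF file with `gene_id` and `transcript_id` attributes.
#' @return A tibble with `seqnames`, `start`, `end`, `strand`, `gene_id`,
#'   `transcript_id`, `exon_number`.
#' @export
read_gtf_exons <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  tb <- tibble(
    seqnames = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    exon_number = if (!is.null(gr$exon_number)) as.integer(gr$exon_number)
                  else NA_integer_
  )
  if (anyNA(tb$exon_number)) {
    # fall back to 5'->3' genomic order within transcript
    tb <- tb |>
      dplyr::group_by(.data$transcript_id) |>
      dplyr::mutate(exon_number = if (.data$strand[1] == "-") {
        rank(-.data$start)
      } else {
        rank(.data$start)
      }) |>
      dplyr::ungroup()
  }
  tb
}

write_gtf_exons <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$seqnames,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand)
  gr$type <- "exon"
  gr$source <- "altisplice"
  gr$gene_id <- annotation$gene_id
  gr$transcript_id <- annotation$transcript_id
  gr$exon_number <- annotation$exon_number
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}
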