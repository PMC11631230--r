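#' Write genomes as FASTA
#'
#' @param genomes Named list of genome objects or sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genomes_fasta <- function(genomes, path) {
  seqs <- vapply(genomes, genome_seq, character(1))
  ids <- names(genomes) %||% vapply(genomes, genome_id_of, character(1))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(seqs, ids)), path)
  invisible(path)
}

#' Read genomes from FASTA
#'
#' @param path FASTA file.
#' @return Named list of genome objects (no ORF annotation).
#' @export
read_genomes_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  out <- lapply(seq_along(x), function(i)
    new_genome(ids[i], as.character(x[[i]]),
               orfs = data.frame(start = integer(0), end = integer(0),
                                 strand = character(0))))
  setNames(out, ids)
}

#' Write reads as FASTQ with constant quality
#'
#' @param reads Named character vector of read sequences.
#' @param path Output file.
#' @param quality_char Constant per-base quality character (default "I").
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path, quality_char = "I") {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep(quality_char, n), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read reads from FASTQ (or FASTA)
#'
#' @param path Input file.
#' @param format `"fastq"` (default) or `"fasta"`.
#' @return Named character vector of read sequences.
#' @export
read_reads_fastq <- function(path, format = "fastq") {
  x <- Biostrings::readDNAStringSet(path, format = format)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

# 0-based half-open intervals -> GRanges (1-based closed) for BED export.
intervals_to_granges <- function(df, seqname) {
  GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*")
}

#' Write ORF (or island) intervals as BED
#'
#' Intervals are 0-based half-open in memory and on disk (BED convention).
#'
#' @param df Data frame with `start`, `end` and optional `strand`.
#' @param genome_id Sequence name for the BED records.
#' @param path Output file.
#' @param names Optional feature names.
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(df, genome_id, path, names = NULL) {
  gr <- intervals_to_granges(df, genome_id)
  if (!is.null(names)) names(gr) <- names
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Read BED intervals
#'
#' @param path BED file.
#' @return Data frame with `seqname`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @export
read_intervals_bed <- function(path) {
  gr <- rtracklayer::import.bed(path)
  data.frame(seqname = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write recruitment hits as TSV
#'
#' Columns: read_id, genome_id, g_start, g_end, strand, identity,
#' read_cov, aligned_nt.
#'
#' @param hits Hits from [recruit_best_hits()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  cols <- c("read_id", "genome_id", "g_start", "g_end", "strand",
            "identity", "read_cov", "aligned_nt")
  write.table(hits[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read recruitment hits from TSV
#'
#' @param path TSV written by [write_hits_tsv()].
#' @return Hits data frame.
#' @export
read_hits_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a depth profile as TSV
#'
#' @param profile A [depth_profile()].
#' @param path Output file (columns: position, depth).
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(profile, path) {
  write.table(data.frame(position = seq_along(profile$depth) - 1L,
                         depth = profile$depth),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a matrix as square TSV
#'
#' @param m Matrix with row/column names.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the truth record (or any report) as JSON
#'
#' @param x List to serialize.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
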