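genome_seq <- function(genome) {
  if (inherits(genome, c("ss_genome", "ss_genome_index"))) genome$seq
  else as.character(genome)
}

genome_id_of <- function(genome, default = "genome") {
  if (inherits(genome, c("ss_genome", "ss_genome_index"))) genome$id
  else default
}

#' Precompute a k-mer index for repeated alignment against one genome
#'
#' Index objects can stand in for genomes in [recruit_best_hits()],
#' [intergenomic_similarity()] and friends, avoiding repeated index
#' construction.
#'
#' @param genome Genome object or character sequence.
#' @param k Seed k-mer size (default 15).
#' @return Object of class `ss_genome_index`.
#' @export
genome_index <- function(genome, k = 15) {
  sq <- genome_seq(genome)
  structure(list(ptr = .cpp_build_index(sq, as.integer(k)),
                 id = genome_id_of(genome), seq = sq, k = as.integer(k),
                 orfs = if (inherits(genome, "ss_genome")) genome$orfs),
            class = "ss_genome_index")
}

map_reads_to <- function(reads, genome, k = 15) {
  if (inherits(genome, "ss_genome_index"))
    .cpp_map_reads_idx(reads, genome$ptr)
  else
    .cpp_map_reads(reads, genome_seq(genome), as.integer(k))
}

#' Align one read to a genome (ungapped seed-and-extend)
#'
#' Seeds with exact k-mer matches on both strands and extends each seeded
#' diagonal without gaps, scoring +1 per match and -1 per mismatch; the
#' maximal-scoring placement is returned. Among equal-scoring placements the
#' canonical choice is '+' strand first, then smaller genome start, then the
#' shorter span; within a diagonal the shortest maximal segment (both ends
#' matching) is taken.
#'
#' @param read_seq Read sequence (character scalar).
#' @param genome Genome object or character sequence.
#' @param k Seed k-mer size (default 15).
#' @return One-row data frame with `g_start`, `g_end` (0-based half-open),
#'   `strand`, `identity` (matches / alignment columns), `read_cov`
#'   (aligned read bases / read length), `aligned_nt`, `score`; or `NULL`
#'   when no seeded placement exists.
#' @export
align_read_local <- function(read_seq, genome, k = 15) {
  if (nchar(read_seq) < k)
    stop("read shorter than the seed size k = ", k)
  hit <- map_reads_to(read_seq, genome, k)
  if (is.na(hit$g_start[1])) return(NULL)
  data.frame(g_start = hit$g_start[1], g_end = hit$g_end[1],
             strand = hit$strand[1],
             identity = hit$matches[1] / hit$alen[1],
             read_cov = hit$alen[1] / nchar(read_seq),
             aligned_nt = hit$alen[1], score = hit$score[1],
             stringsAsFactors = FALSE)
}

#' Recruit reads against a set of reference genomes
#'
#' Places every read on every genome with the seed-and-extend aligner and
#' keeps, per read, the single best placement passing the read-coverage and
#' identity filters (both inclusive). Ties across genomes are broken by
#' higher aligned length, then higher identity, then lexicographically
#' smallest genome id. Reads with no passing placement are absent from the
#' output.
#'
#' @param reads Named character vector of read sequences.
#' @param genomes Named list of genome objects (or character sequences).
#' @param min_read_cov Minimum aligned fraction of the read (default 0.70).
#' @param min_identity Minimum identity over the aligned span (default 0).
#' @param k Seed k-mer size.
#' @return Data frame of recruitment hits: `read_id`, `genome_id`,
#'   `g_start`, `g_end`, `strand`, `identity`, `read_cov`, `aligned_nt`.
#' @export
recruit_best_hits <- function(reads, genomes, min_read_cov = 0.70,
                              min_identity = 0, k = 15) {
  if (length(genomes) == 0) stop("empty genome set")
  stopifnot(min_read_cov >= 0, min_read_cov <= 1,
            min_identity >= 0, min_identity <= 1)
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%06d", seq_along(reads))
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, genome_id_of, character(1))
  per_genome <- lapply(names(genomes), function(gid) {
    h <- map_reads_to(unname(reads), genomes[[gid]], k)
    keep <- which(!is.na(h$g_start))
    if (!length(keep)) return(NULL)
    data.frame(read_idx = keep, genome_id = gid,
               g_start = h$g_start[keep], g_end = h$g_end[keep],
               r_start = h$r_start[keep], r_end = h$r_end[keep],
               strand = h$strand[keep], matches = h$matches[keep],
               aligned_nt = h$alen[keep], score = h$score[keep],
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, per_genome)
  empty <- data.frame(read_id = character(0), genome_id = character(0),
                      g_start = integer(0), g_end = integer(0),
                      strand = character(0), identity = numeric(0),
                      read_cov = numeric(0), aligned_nt = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0) return(empty)
  hits$identity <- hits$matches / hits$aligned_nt
  hits$read_cov <- hits$aligned_nt / nchar(reads)[hits$read_idx]
  hits <- hits[hits$read_cov >= min_read_cov &
                 hits$identity >= min_identity, , drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  ord <- order(hits$read_idx, -hits$score, -hits$aligned_nt,
               -hits$identity, hits$genome_id)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$read_idx), , drop = FALSE]
  out <- data.frame(read_id = names(reads)[hits$read_idx],
                    genome_id = hits$genome_id,
                    g_start = hits$g_start, g_end = hits$g_end,
                    strand = hits$strand, identity = hits$identity,
                    read_cov = hits$read_cov,
                    aligned_nt = hits$aligned_nt,
                    r_start = hits$r_start, r_end = hits$r_end,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-position sequencing depth of a genome in one sample
#'
#' Accumulates coverage over `[g_start, g_end)` for hits at or above the
#' identity floor, and keeps the (position, identity) pairs used by
#' recruitment plots.
#'
#' @param hits Recruitment hits for this genome (see [recruit_best_hits()]).
#' @param genome Genome object or character sequence.
#' @param sample_id Sample label.
#' @param identity_floor Minimum identity for a hit to contribute.
#' @return Object of class `ss_depth_profile`: `genome_id`, `sample_id`,
#'   `identity_floor`, integer `depth` vector (genome length), and a
#'   `points` data frame (position, identity).
#' @export
depth_profile <- function(hits, genome, sample_id = "sample",
                          identity_floor = 0) {
  len <- nchar(genome_seq(genome))
  gid <- genome_id_of(genome)
  if (nrow(hits) > 0 && "genome_id" %in% names(hits)) {
    own <- hits$genome_id == gid
    if (any(own)) hits <- hits[own, , drop = FALSE]
  }
  if (nrow(hits) > 0 &&
      (any(hits$g_start < 0) || any(hits$g_end > len) ||
       any(hits$g_start >= hits$g_end)))
    stop("hit coordinates outside genome bounds: corrupt input")
  hits <- hits[hits$identity >= identity_floor, , drop = FALSE]
  delta <- integer(len + 1L)
  if (nrow(hits) > 0) {
    add <- tabulate(hits$g_start + 1L, nbins = len + 1L)
    sub <- tabulate(hits$g_end + 1L, nbins = len + 1L)
    delta <- add - sub
  }
  depth <- cumsum(delta)[seq_len(len)]
  structure(list(genome_id = gid, sample_id = sample_id,
                 identity_floor = identity_floor,
                 depth = as.integer(depth),
                 points = data.frame(position = hits$g_start,
                                     identity = hits$identity)),
            class = "ss_depth_profile")
}
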