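#' Normalized genotype abundance from recruitment hits
#'
#' Applies the genotype filter (read coverage at least `min_read_cov` and,
#' by default, perfect identity over the aligned span), then computes the
#' recruited-nucleotide percentage of the metagenome normalized by genome
#' size in Kbp, and the mean sequencing depth. For display, figures
#' conventionally multiply the normalized abundance by 1000.
#'
#' @param hits Recruitment hits for this genome.
#' @param genome Genome object or character sequence.
#' @param metagenome_nt Total nucleotides in the metagenome (must be > 0).
#' @param sample_id Sample label.
#' @param min_read_cov Read-coverage filter (default 0.70).
#' @param exact_identity If `TRUE` (default) only hits with identity 1.0
#'   over the aligned span are counted, the genotype-level filter.
#' @return One-row data frame: `genome_id`, `sample_id`, `n_reads`,
#'   `recruited_nt`, `metagenome_nt`, `normalized_abundance`
#'   (percent of metagenome nucleotides per Kbp of genome), `seq_depth`.
#' @export
genotype_abundance <- function(hits, genome, metagenome_nt,
                               sample_id = "sample", min_read_cov = 0.70,
                               exact_identity = TRUE) {
  if (metagenome_nt <= 0) stop("metagenome_nt must be positive")
  len <- nchar(genome_seq(genome))
  keep <- hits$read_cov >= min_read_cov
  if (exact_identity) keep <- keep & hits$identity >= 1
  hits <- hits[keep, , drop = FALSE]
  recruited <- sum(hits$aligned_nt)
  data.frame(genome_id = genome_id_of(genome), sample_id = sample_id,
             n_reads = nrow(hits), recruited_nt = recruited,
             metagenome_nt = metagenome_nt,
             normalized_abundance =
               (recruited / metagenome_nt * 100) / (len / 1000),
             seq_depth = recruited / len,
             stringsAsFactors = FALSE)
}

#' Fold change between consecutive abundances
#'
#' @param abundance_t_n Abundance at the later time point.
#' @param abundance_t_prev Abundance at the previous time point.
#' @return `abundance_t_n / abundance_t_prev`, or `NA` when the previous
#'   abundance is zero (genotype below detection; no ratio is defined).
#' @export
fold_change <- function(abundance_t_n, abundance_t_prev) {
  if (is.na(abundance_t_prev) || abundance_t_prev == 0) return(NA_real_)
  abundance_t_n / abundance_t_prev
}

#' Fold-change series over a trajectory
#'
#' @param abundances Numeric vector of abundances in time order.
#' @param timepoints Optional time labels (defaults to indices).
#' @return Data frame with `from`, `to`, `ratio` and `below_detection`
#'   (`TRUE` where the previous abundance was zero and the ratio undefined).
#' @export
fold_change_series <- function(abundances, timepoints = seq_along(abundances)) {
  n <- length(abundances)
  if (n < 2) return(data.frame(from = numeric(0), to = numeric(0),
                               ratio = numeric(0),
                               below_detection = logical(0)))
  prev <- abundances[-n]
  data.frame(from = timepoints[-n], to = timepoints[-1],
             ratio = ifelse(prev == 0, NA_real_, abundances[-1] / prev),
             below_detection = prev == 0)
}

#' Culture-captured fraction of a species-like population
#'
#' Retrieves the species-like population as the reads mapping at or above
#' the species identity threshold (default 0.95) after the read-coverage
#' filter, and quantifies the fraction matching the isolate genome at 100%
#' identity over the aligned span.
#'
#' @param hits Recruitment hits carrying exact identity values.
#' @param genome_id Genome label for the output.
#' @param sample_id Sample label.
#' @param min_read_cov Read-coverage filter (default 0.70).
#' @param species_identity Species threshold for the denominator
#'   (default 0.95, inclusive).
#' @return One-row data frame: `genome_id`, `sample_id`, `n_reads_species`,
#'   `n_reads_isolate`, `capture_pct` (`NA` when no reads reach the species
#'   threshold, i.e. the population is undetected).
#' @export
population_capture <- function(hits, genome_id = "genome",
                               sample_id = "sample", min_read_cov = 0.70,
                               species_identity = 0.95) {
  hits <- hits[hits$read_cov >= min_read_cov, , drop = FALSE]
  n_species <- sum(hits$identity >= species_identity)
  n_isolate <- sum(hits$identity >= 1)
  data.frame(genome_id = genome_id, sample_id = sample_id,
             n_reads_species = n_species, n_reads_isolate = n_isolate,
             capture_pct = if (n_species == 0) NA_real_ else
               100 * n_isolate / n_species,
             stringsAsFactors = FALSE)
}

#' Detect metagenomic islands in a depth profile
#'
#' Scans non-overlapping windows and calls runs of windows whose mean depth
#' falls at or below `ratio_max` times the genome-wide median depth;
#' adjacent qualifying windows are merged and merged runs of at least
#' `min_island_len` are reported. When the median depth does not exceed
#' `min_detect_depth` the genome is considered absent and no islands are
#' called.
#'
#' @param profile A [depth_profile()] object.
#' @param window_bp Window size (default 500).
#' @param ratio_max Maximum window/median depth ratio for island windows
#'   (default 0.2, inclusive).
#' @param min_island_len Minimum merged island length (default 1000).
#' @param min_detect_depth Minimum genome median depth (default 5, strict).
#' @return Data frame of islands: `genome_id`, `start`, `end`, `mean_depth`,
#'   `genome_median_depth`, `ratio`; attribute `genome_status` is either
#'   `"present"` or `"absent_genome"`.
#' @export
detect_islands <- function(profile, window_bp = 500, ratio_max = 0.2,
                           min_island_len = 1000, min_detect_depth = 5) {
  depth <- profile$depth
  len <- length(depth)
  if (window_bp > len) stop("window_bp exceeds genome length")
  med <- median(depth)
  empty <- data.frame(genome_id = character(0), start = integer(0),
                      end = integer(0), mean_depth = numeric(0),
                      genome_median_depth = numeric(0), ratio = numeric(0),
                      stringsAsFactors = FALSE)
  if (med <= min_detect_depth) {
    attr(empty, "genome_status") <- "absent_genome"
    return(empty)
  }
  starts <- seq(0L, len - 1L, by = as.integer(window_bp))
  ends <- pmin(starts + as.integer(window_bp), len)
  wmean <- vapply(seq_along(starts), function(i)
    mean(depth[(starts[i] + 1L):ends[i]]), numeric(1))
  low <- wmean / med <= ratio_max
  runs <- rle(low)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  out <- empty
  for (r in which(runs$values)) {
    s <- starts[run_start[r]]
    e <- ends[run_end[r]]
    if (e - s >= min_island_len) {
      md <- mean(depth[(s + 1L):e])
      out <- rbind(out, data.frame(genome_id = profile$genome_id,
                                   start = s, end = e, mean_depth = md,
                                   genome_median_depth = med,
                                   ratio = md / med,
                                   stringsAsFactors = FALSE))
    }
  }
  attr(out, "genome_status") <- "present"
  out
}

#' Re-evaluate t0 islands across a sample series
#'
#' Each island called at the first time point is re-scored in every sample:
#' status is `"filled"` when its mean-depth/median-depth ratio reaches
#' `fill_ratio` (inclusive boundary), `"island"` otherwise, and
#' `"absent_genome"` when the genome's median depth does not exceed
#' `min_detect_depth` in that sample.
#'
#' @param profiles Named list of [depth_profile()] objects (one per sample,
#'   same genome).
#' @param islands Islands called at t0 (see [detect_islands()]).
#' @param fill_ratio Ratio at which an island counts as filled (default 0.8).
#' @param min_detect_depth Genome-presence threshold (default 5, strict).
#' @return Data frame: `island_id`, `genome_id`, `start`, `end`,
#'   `sample_id`, `ratio`, `status`.
#' @export
island_timecourse <- function(profiles, islands, fill_ratio = 0.8,
                              min_detect_depth = 5) {
  gids <- unique(vapply(profiles, `[[`, character(1), "genome_id"))
  if (length(gids) > 1)
    stop("profiles span multiple genomes: ", paste(gids, collapse = ", "))
  if (nrow(islands) > 0 && any(islands$genome_id != gids))
    stop("island/profile genome ids differ")
  out <- list()
  for (si in seq_along(profiles)) {
    p <- profiles[[si]]
    med <- median(p$depth)
    for (ii in seq_len(nrow(islands))) {
      iv <- islands[ii, ]
      md <- mean(p$depth[(iv$start + 1L):iv$end])
      status <- if (med <= min_detect_depth) "absent_genome"
      else if (md / med >= fill_ratio) "filled" else "island"
      out[[length(out) + 1L]] <- data.frame(
        island_id = sprintf("%s_island%d", iv$genome_id, ii),
        genome_id = iv$genome_id, start = iv$start, end = iv$end,
        sample_id = p$sample_id,
        ratio = if (med > 0) md / med else NA_real_,
        status = status, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(island_id = character(0), genome_id = character(0),
                      start = integer(0), end = integer(0),
                      sample_id = character(0), ratio = numeric(0),
                      status = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
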