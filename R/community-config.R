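#' Configuration for the synthetic viral community
#'
#' Defines the planted structure of a two-species viral genus emulating a
#' hypersaline mesocosm: genome size and GC content, species/group divergence
#' levels, a hypervariable island, and a rare genotype sweeping over a
#' 0-672 h time course.
#'
#' Divergence parameters are per-lineage i.i.d. site-resampling
#' probabilities relative to the shared ancestor: a site is resampled with
#' the given probability from the genome-wide base composition, so
#' back-substitutions occur and GC content is stationary. The realized
#' pairwise divergence between two lineages resampled at rates `p1`, `p2`
#' is `(p1 + p2 - p1*p2) * (1 - sum(q^2))` with `q` the base frequencies
#' (see [planted_divergence()]).
#'
#' @param genome_length_bp Genome length; `NULL` (default) draws one length
#'   uniformly in 44000-46000 bp at simulation time, applied to all genomes.
#' @param gc_fraction Target GC content of the backbone (default 0.63).
#' @param n_species Number of species in the genus (default 2). Species 1
#'   carries the intra-species group structure; the remaining species are
#'   represented by a single genome each.
#' @param interspecies_divergence Per-site resampling probability used to
#'   derive each species ancestor from the genus backbone, outside islands
#'   (default 0.12).
#' @param n_groups Intra-species variant groups within species 1 (default 9).
#'   The last group is the sweep genotype and is a singleton.
#' @param genomes_per_group Genomes per non-sweep group (default 2).
#' @param intragroup_divergence Per-site probability deriving each genome
#'   from its group ancestor (default 0.002).
#' @param intergroup_divergence Per-site probability deriving each group
#'   ancestor from the species ancestor, outside islands (default 0.02).
#'   Constrained so planted within-species identity exceeds 0.95.
#' @param island_intervals List of 0-based half-open `c(start, end)`
#'   intervals; default one 3000 bp interval at 30000-33000.
#' @param island_divergence Per-site probability inside islands when deriving
#'   species ancestors (default 0.30).
#' @param island_group_divergence Per-site probability inside islands when
#'   deriving group ancestors (default 0.10), making the island hypervariable
#'   among co-existing intra-species variants while keeping within-species
#'   identity above the 0.95 species threshold.
#' @param sweep_genotype_f0 Initial relative abundance of the sweep genotype
#'   (default 1e-4, below the detection limit of a 5000-read sample).
#' @param sweep_f_end Final relative abundance (default 0.5).
#' @param timepoints_h Sampling times in hours (default 0, 72, 168, 336, 672).
#' @param reads_per_sample Metagenomic reads per time point (default 5000).
#' @param read_length_bp Read length (default 250).
#' @param error_rate Per-base substitution error probability (default 0.005).
#' @param background_fraction Fraction of reads drawn from unrelated genomes
#'   (default 0.45).
#' @param n_background_genomes Number of unrelated background genomes
#'   (default 3).
#' @param focal_species_fraction Total relative abundance of species 1, held
#'   constant over time; the sweep genotype replaces conspecific strains
#'   within it (default 0.52).
#' @param orf_length_bp,orf_spacing_bp Planted ORF annotation: forward-strand
#'   ORFs of `orf_length_bp` (divisible by 3) tiled every
#'   `orf_length_bp + orf_spacing_bp`, covering about half of each genome.
#' @param amplicon_error_rate Per-base error rate of amplicon pools
#'   (default 0.001, emulating quality-filtered, merged amplicon reads).
#' @param seed Integer seed; all simulation randomness derives from it.
#'
#' @return A validated list of class `community_config`.
#' @export
community_config <- function(genome_length_bp = NULL,
                             gc_fraction = 0.63,
                             n_species = 2,
                             interspecies_divergence = 0.12,
                             n_groups = 9,
                             genomes_per_group = 2,
                             intragroup_divergence = 0.002,
                             intergroup_divergence = 0.02,
                             island_intervals = list(c(30000L, 33000L)),
                             island_divergence = 0.30,
                             island_group_divergence = 0.10,
                             sweep_genotype_f0 = 1e-4,
                             sweep_f_end = 0.5,
                             timepoints_h = c(0, 72, 168, 336, 672),
                             reads_per_sample = 5000,
                             read_length_bp = 250,
                             error_rate = 0.005,
                             background_fraction = 0.45,
                             n_background_genomes = 3,
                             focal_species_fraction = 0.52,
                             orf_length_bp = 750,
                             orf_spacing_bp = 750,
                             amplicon_error_rate = 0.001,
                             seed = 1) {
  cfg <- list(genome_length_bp = genome_length_bp,
              gc_fraction = gc_fraction,
              n_species = n_species,
              interspecies_divergence = interspecies_divergence,
              n_groups = n_groups,
              genomes_per_group = genomes_per_group,
              intragroup_divergence = intragroup_divergence,
              intergroup_divergence = intergroup_divergence,
              island_intervals = island_intervals,
              island_divergence = island_divergence,
              island_group_divergence = island_group_divergence,
              sweep_genotype_f0 = sweep_genotype_f0,
              sweep_f_end = sweep_f_end,
              timepoints_h = timepoints_h,
              reads_per_sample = reads_per_sample,
              read_length_bp = read_length_bp,
              error_rate = error_rate,
              background_fraction = background_fraction,
              n_background_genomes = n_background_genomes,
              focal_species_fraction = focal_species_fraction,
              orf_length_bp = orf_length_bp,
              orf_spacing_bp = orf_spacing_bp,
              amplicon_error_rate = amplicon_error_rate,
              seed = seed)
  class(cfg) <- "community_config"
  validate_community_config(cfg)
  cfg
}

validate_community_config <- function(cfg) {
  props <- c("gc_fraction", "interspecies_divergence", "intragroup_divergence",
             "intergroup_divergence", "island_divergence",
             "island_group_divergence", "sweep_genotype_f0", "sweep_f_end",
             "error_rate", "background_fraction", "focal_species_fraction",
             "amplicon_error_rate")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("community_config: '", p, "' must be a proportion in [0, 1]")
  }
  if (!is.null(cfg$genome_length_bp) && cfg$genome_length_bp < 1)
    stop("community_config: genome_length_bp must be positive")
  if (cfg$n_species < 1 || cfg$n_groups < 1 || cfg$genomes_per_group < 1)
    stop("community_config: counts must be >= 1")
  if (is.unsorted(cfg$timepoints_h, strictly = TRUE))
    stop("community_config: timepoints_h must be strictly increasing")
  if (cfg$sweep_genotype_f0 > cfg$sweep_f_end)
    stop("community_config: sweep_genotype_f0 must not exceed sweep_f_end")
  if (cfg$sweep_f_end > cfg$focal_species_fraction)
    stop("community_config: sweep_f_end exceeds focal_species_fraction")
  if (cfg$background_fraction + cfg$focal_species_fraction > 1)
    stop("community_config: background + focal species fractions exceed 1")
  if (cfg$orf_length_bp %% 3 != 0)
    stop("community_config: orf_length_bp must be divisible by 3")
  # islands: 0-based half-open, non-overlapping, within bounds when known
  iv <- cfg$island_intervals
  if (length(iv)) {
    m <- do.call(rbind, iv)
    if (any(m[, 1] < 0) || any(m[, 2] <= m[, 1]))
      stop("community_config: malformed island interval")
    if (!is.null(cfg$genome_length_bp) && any(m[, 2] > cfg$genome_length_bp))
      stop("community_config: island interval outside genome bounds")
    o <- order(m[, 1])
    if (nrow(m) > 1 && any(m[o, 1][-1] < m[o, 2][-nrow(m)]))
      stop("community_config: island intervals overlap")
  }
  invisible(cfg)
}

#' Base composition for a GC fraction
#'
#' @param gc GC fraction.
#' @return Named numeric vector of A, C, G, T frequencies.
#' @export
base_frequencies <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

#' Expected pairwise divergence under i.i.d. site resampling
#'
#' Closed-form probability that a site differs between two lineages derived
#' from a common ancestor by resampling each site, independently, with
#' probabilities `p1` and `p2` from the base distribution implied by `gc`.
#' Resampling may restore the ancestral base (back-substitution), so the
#' realized divergence is lower than the resampling rates.
#'
#' @param p1,p2 Per-site resampling probabilities of the two lineages.
#' @param gc GC fraction of the base distribution.
#' @return Expected per-site mismatch probability.
#' @export
planted_divergence <- function(p1, p2 = p1, gc = 0.63) {
  q <- base_frequencies(gc)
  (p1 + p2 - p1 * p2) * (1 - sum(q^2))
}
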