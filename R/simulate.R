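BASES <- c("A", "C", "G", "T")

int_to_seq <- function(x) paste(BASES[x], collapse = "")
seq_to_int <- function(s) match(strsplit(s, "", fixed = TRUE)[[1]], BASES)

# Solve the ORF-codon GC parameter so that, after excluding stop codons,
# the expected GC per coding base equals the genome-wide target.
orf_gc_param <- function(target_gc) {
  exp_gc <- function(g) {
    at <- (1 - g) / 2; gc <- g / 2
    p_taa <- at^3; p_tag <- at^2 * gc; p_tga <- at^2 * gc
    p_stop <- p_taa + p_tag + p_tga
    (3 * g - (p_tag + p_tga)) / (1 - p_stop) / 3
  }
  uniroot(function(g) exp_gc(g) - target_gc, c(0.05, 0.95),
          tol = 1e-10)$root
}

# Draw n sense (non-stop) codons as integer base triples, GC-calibrated.
sample_codons <- function(n, q) {
  m <- matrix(sample.int(4L, 3L * n, replace = TRUE, prob = q),
              nrow = n, ncol = 3L)
  repeat {
    stop_row <- m[, 1] == 4L & m[, 2] == 1L & m[, 3] %in% c(1L, 3L) |
      m[, 1] == 4L & m[, 2] == 3L & m[, 3] == 1L
    if (!any(stop_row)) break
    k <- sum(stop_row)
    m[stop_row, ] <- matrix(sample.int(4L, 3L * k, replace = TRUE, prob = q),
                            nrow = k, ncol = 3L)
  }
  m
}

# Forward-strand ORF tiling covering ~orf_len/(orf_len+spacing) of the genome.
plant_orf_intervals <- function(len, orf_len, spacing) {
  starts <- seq(0L, len - orf_len, by = orf_len + spacing)
  data.frame(start = starts, end = starts + orf_len,
             strand = "+", stringsAsFactors = FALSE)
}

# Random backbone: intergenic bases i.i.d. from q; ORFs as ATG + sense
# codons + stop so planted frames are open and GC stays on target.
random_backbone <- function(len, gc, orfs) {
  q <- base_frequencies(gc)
  x <- sample.int(4L, len, replace = TRUE, prob = q)
  q_orf <- base_frequencies(orf_gc_param(gc))
  stops <- matrix(c(4L, 1L, 1L,  4L, 1L, 3L,  4L, 3L, 1L),
                  ncol = 3L, byrow = TRUE)  # TAA TAG TGA
  for (i in seq_len(nrow(orfs))) {
    s <- orfs$start[i]; e <- orfs$end[i]
    n_codon <- (e - s) %/% 3L
    body <- sample_codons(n_codon - 2L, q_orf)
    stop_codon <- stops[sample.int(3L, 1L), ]
    x[(s + 1L):e] <- c(1L, 4L, 3L, as.vector(t(body)), stop_codon)  # ATG ...
  }
  x
}

# i.i.d. site resampling at `rate` outside islands and `island_rate` inside.
mutate_lineage <- function(x, rate, q, islands = NULL, island_rate = rate) {
  r <- rep(rate, length(x))
  if (!is.null(islands)) {
    for (iv in islands) r[(iv[1] + 1L):iv[2]] <- island_rate
  }
  idx <- which(runif(length(x)) < r)
  if (length(idx))
    x[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = q)
  x
}

new_genome <- function(id, seq, orfs, species = NA_character_,
                       group = NA_character_, is_sweep = FALSE) {
  structure(list(id = id, seq = seq, orfs = orfs, species = species,
                 group = group, is_sweep = is_sweep),
            class = "ss_genome")
}

#' Simulate a two-species viral genus with planted strain structure
#'
#' Generates one genus backbone, derives species ancestors (hypervariable
#' islands diverging faster than the backbone), intra-species group
#' ancestors, and individual genomes, plus unrelated background genomes.
#' The last group of species 1 is a singleton: the sweep genotype. Planted
#' pairwise identities are verified by direct site comparison against the
#' ICTV-style constraints (within-species > 0.95; between-species within
#' 0.70-0.95 whenever a nonzero between-species divergence is requested).
#'
#' @param config A [community_config()].
#' @return A list with `genomes` (named list of genome objects) and `truth`
#'   (genome labels, island intervals, ORF annotation, per-timepoint
#'   abundances, sweep trajectory).
#' @export
simulate_genus <- function(config) {
  stopifnot(inherits(config, "community_config"))
  validate_community_config(config)
  q <- base_frequencies(config$gc_fraction)
  with_op_seed(config$seed, 11L, {
    len <- config$genome_length_bp %||% sample(44000:46000, 1L)
    islands <- lapply(config$island_intervals, as.integer)
    if (length(islands) && max(vapply(islands, `[`, integer(1), 2L)) > len)
      stop("island interval outside genome bounds (length ", len, ")")
    orfs <- plant_orf_intervals(len, config$orf_length_bp,
                                config$orf_spacing_bp)
    backbone <- random_backbone(len, config$gc_fraction, orfs)

    species_anc <- lapply(seq_len(config$n_species), function(i) {
      mutate_lineage(backbone, config$interspecies_divergence, q,
                     islands, config$island_divergence)
    })

    genomes <- list()
    sweep_id <- NULL
    for (sp in seq_len(config$n_species)) {
      sp_lab <- sprintf("sp%d", sp)
      if (sp == 1L) {
        for (gr in seq_len(config$n_groups)) {
          gr_lab <- sprintf("g%02d", gr)
          anc <- mutate_lineage(species_anc[[sp]],
                                config$intergroup_divergence, q,
                                islands, config$island_group_divergence)
          is_sweep_group <- gr == config$n_groups
          n_members <- if (is_sweep_group) 1L else config$genomes_per_group
          for (m in seq_len(n_members)) {
            id <- sprintf("%s_%s_i%d", sp_lab, gr_lab, m)
            gseq <- mutate_lineage(anc, config$intragroup_divergence, q)
            genomes[[id]] <- new_genome(id, int_to_seq(gseq), orfs,
                                        species = sp_lab, group = gr_lab,
                                        is_sweep = is_sweep_group)
            if (is_sweep_group) sweep_id <- id
          }
        }
      } else {
        id <- sprintf("%s_g01_i1", sp_lab)
        gseq <- mutate_lineage(species_anc[[sp]],
                               config$intragroup_divergence, q)
        genomes[[id]] <- new_genome(id, int_to_seq(gseq), orfs,
                                    species = sp_lab, group = "g01")
      }
    }
    for (b in seq_len(config$n_background_genomes)) {
      id <- sprintf("bg_%d", b)
      gseq <- sample.int(4L, len, replace = TRUE, prob = q)
      genomes[[id]] <- new_genome(id, int_to_seq(gseq), orfs = orfs[0, ],
                                  species = "background")
    }

    check_planted_identities(genomes, config)

    info <- data.frame(
      genome_id = names(genomes),
      species = vapply(genomes, `[[`, character(1), "species"),
      group = vapply(genomes, function(g) g$group %||% NA_character_,
                     character(1)),
      is_sweep = vapply(genomes, `[[`, logical(1), "is_sweep"),
      row.names = NULL, stringsAsFactors = FALSE)

    truth <- list(
      genome_info = info,
      genome_length = len,
      islands = islands,
      orfs = orfs,
      sweep_genome = sweep_id,
      sweep_trajectory = sweep_trajectory(config),
      abundances = planted_abundances(info, config),
      read_origin = list())
    list(genomes = genomes, truth = truth)
  })
}

# Direct site-count verification of the planted identity structure.
check_planted_identities <- function(genomes, config) {
  viral <- Filter(function(g) !identical(g$species, "background"), genomes)
  if (length(viral) < 2) return(invisible(TRUE))
  enc <- lapply(viral, function(g) charToRaw(g$seq))
  sp <- vapply(viral, `[[`, character(1), "species")
  ids <- names(viral)
  for (i in seq_along(viral)[-length(viral)]) {
    for (j in seq((i + 1), length(viral))) {
      ident <- mean(enc[[i]] == enc[[j]])
      if (sp[i] == sp[j]) {
        if (ident <= 0.95)
          stop("planted within-species identity ", round(ident, 4),
               " (", ids[i], " vs ", ids[j], ") violates the > 0.95 ",
               "species threshold; lower the intra-species divergences")
      } else if (config$interspecies_divergence > 0) {
        if (ident <= 0.70 || ident >= 0.95)
          stop("planted between-species identity ", round(ident, 4),
               " (", ids[i], " vs ", ids[j], ") outside (0.70, 0.95); ",
               "adjust interspecies/island divergence")
      }
    }
  }
  invisible(TRUE)
}

#' Sweep genotype trajectory
#'
#' Logistic interpolation of the sweep genotype's relative abundance, with
#' midpoint at the middle of the time course and endpoints pinned to
#' `sweep_genotype_f0` and `sweep_f_end`. A flat trajectory is returned when
#' the two are equal (null experiment).
#'
#' @param config A [community_config()].
#' @return Data frame with `timepoint_h` and `f` (relative abundance).
#' @export
sweep_trajectory <- function(config) {
  tp <- config$timepoints_h
  f0 <- config$sweep_genotype_f0
  f1 <- config$sweep_f_end
  if (f1 - f0 < 1e-12) {
    return(data.frame(timepoint_h = tp, f = rep(f0, length(tp))))
  }
  t0 <- min(tp); t1 <- max(tp)
  tmid <- (t0 + t1) / 2
  # f(t) = A / (1 + exp(-r (t - tmid))); A, r pinned by the two endpoints
  f_at <- function(r, t) {
    A <- f1 * (1 + exp(-r * (t1 - tmid)))
    A / (1 + exp(-r * (t - tmid)))
  }
  r <- uniroot(function(r) f_at(r, t0) - f0, c(1e-8, 10), tol = 1e-12)$root
  data.frame(timepoint_h = tp, f = f_at(r, tp))
}

# Per-timepoint relative abundances over every source genome (rows sum to 1):
# the sweep genotype follows its logistic trajectory and replaces conspecific
# strains inside a constant species-1 population share.
planted_abundances <- function(info, config) {
  traj <- sweep_trajectory(config)
  src <- info$genome_id
  n_bg <- sum(info$species == "background")
  other_sp <- info$species != "background" & info$species != "sp1"
  n_other <- sum(other_sp)
  other_share <- 1 - config$background_fraction -
    config$focal_species_fraction
  if (n_other == 0 && other_share > 1e-9)
    stop("no genomes to carry the non-focal species share")
  sp1_rest <- info$species == "sp1" & !info$is_sweep
  ab <- matrix(0, nrow = length(traj$f), ncol = length(src),
               dimnames = list(sprintf("t%04dh", traj$timepoint_h), src))
  for (i in seq_along(traj$f)) {
    f <- traj$f[i]
    ab[i, info$is_sweep] <- f
    ab[i, sp1_rest] <- (config$focal_species_fraction - f) / sum(sp1_rest)
    if (n_other > 0) ab[i, other_sp] <- other_share / n_other
    if (n_bg > 0)
      ab[i, info$species == "background"] <- config$background_fraction / n_bg
  }
  ab / rowSums(ab)
}

# Substitute sequencing errors: per base with prob `rate`, uniformly one of
# the three other bases.
add_read_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    x <- seq_to_int(seqs[i])
    pos <- sample.int(length(x), n_err[i])
    x[pos] <- ((x[pos] - 1L + sample.int(3L, n_err[i], replace = TRUE)) %% 4L) + 1L
    seqs[i] <- int_to_seq(x)
  }
  seqs
}

#' Simulate the metagenomic time course
#'
#' Draws `reads_per_sample` reads per time point from the community genomes
#' in proportion to the planted abundances, with uniform start positions,
#' fixed read length and per-base substitution errors. Read ids encode
#' nothing about their origin; origins are recorded only in the truth.
#'
#' @param genomes Named list of genome objects from [simulate_genus()].
#' @param truth Truth record from [simulate_genus()].
#' @param config A [community_config()].
#' @return A list with `samples` (one element per time point, each holding
#'   `sample_id`, `timepoint_h` and a named `reads` vector) and the updated
#'   `truth` carrying per-read origins.
#' @export
simulate_timecourse <- function(genomes, truth, config) {
  if (config$reads_per_sample <= 0)
    stop("reads_per_sample must be positive")
  rl <- config$read_length_bp
  ab <- truth$abundances
  samples <- vector("list", nrow(ab))
  names(samples) <- rownames(ab)
  for (ti in seq_len(nrow(ab))) {
    sample_id <- rownames(ab)[ti]
    res <- with_op_seed(config$seed, 100L + ti, {
      counts <- as.vector(rmultinom(1L, config$reads_per_sample, ab[ti, ]))
      names(counts) <- colnames(ab)
      seqs <- character(0); origin_gid <- character(0); origin_start <- integer(0)
      for (gid in names(counts)[counts > 0]) {
        g <- genomes[[gid]]
        n <- counts[[gid]]
        starts <- sample.int(nchar(g$seq) - rl + 1L, n, replace = TRUE) - 1L
        seqs <- c(seqs, substring(g$seq, starts + 1L, starts + rl))
        origin_gid <- c(origin_gid, rep(gid, n))
        origin_start <- c(origin_start, starts)
      }
      seqs <- add_read_errors(seqs, config$error_rate)
      perm <- sample.int(length(seqs))  # order must not encode origin
      ids <- sprintf("%s_read%06d", sample_id, seq_along(seqs))
      list(reads = setNames(seqs[perm], ids),
           origin = data.frame(read_id = ids,
                               genome_id = origin_gid[perm],
                               start = origin_start[perm],
                               end = origin_start[perm] + rl,
                               stringsAsFactors = FALSE))
    })
    samples[[ti]] <- list(sample_id = sample_id,
                          timepoint_h = config$timepoints_h[ti],
                          reads = res$reads)
    truth$read_origin[[sample_id]] <- res$origin
  }
  list(samples = samples, truth = truth)
}

#' Simulate an amplicon read pool
#'
#' Draws amplicon-length reads from named phylotype sequences at the given
#' frequencies with per-base substitution errors; the truth distribution is
#' returned alongside the reads.
#'
#' @param phylotypes Named character vector of phylotype sequences.
#' @param phylotype_freqs Frequencies summing to 1 (same length/order).
#' @param n_reads Number of reads to draw.
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @return List with `reads` (named vector) and `truth_freqs`.
#' @export
simulate_amplicon_pool <- function(phylotypes, phylotype_freqs, n_reads,
                                   error_rate = 0, seed = 1) {
  if (length(phylotype_freqs) == 0)
    stop("empty phylotype frequency vector")
  if (length(phylotypes) != length(phylotype_freqs))
    stop("phylotypes and frequencies differ in length")
  if (abs(sum(phylotype_freqs) - 1) > 1e-6)
    stop("phylotype frequencies must sum to 1")
  with_op_seed(seed, 300L, {
    counts <- as.vector(rmultinom(1L, n_reads, phylotype_freqs))
    seqs <- rep(unname(phylotypes), counts)
    seqs <- add_read_errors(seqs, error_rate)
    perm <- sample.int(length(seqs))
    ids <- sprintf("amp_read%06d", seq_along(seqs))
    list(reads = setNames(seqs[perm], ids),
         truth_freqs = setNames(phylotype_freqs, names(phylotypes)))
  })
}
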