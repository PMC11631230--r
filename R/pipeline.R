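#' Configuration for an end-to-end mesocosm replay
#'
#' Bundles the community generator settings with every stage threshold:
#' recruitment filters, identity tiers, island calling, taxonomy
#' thresholds, diversity settings and sketch parameters.
#'
#' @param community A [community_config()].
#' @param min_read_cov Read-coverage filter for recruitment (default 0.70).
#' @param species_identity Species-level identity tier (default 0.95).
#' @param island_identity_floor Identity floor of depth profiles used for
#'   island detection (default 0.95).
#' @param window_bp,ratio_max,min_island_len,min_detect_depth,fill_ratio
#'   Island-calling parameters (see [detect_islands()] and
#'   [island_timecourse()]).
#' @param derep_min_len,derep_min_id,derep_min_frac Dereplication settings
#'   (see [dereplicate_genomes()]).
#' @param species_thr,genus_thr ICTV-style thresholds in percent
#'   (default 95/70).
#' @param use_planted_orfs Use the simulator's ORF annotation (default) or
#'   run [predict_orfs()] on every genome.
#' @param amplicon_n_reads,rarefaction_depth Amplicon pool size and
#'   rarefaction depth per sample.
#' @param min_aa_cov,min_mut_codon_count,min_mut_codon_freq Codon-variant
#'   thresholds (see [codon_variant_counts()]).
#' @param sketch_k,sketch_s,sketch_min_count MinHash parameters
#'   (defaults 21/10000/2).
#' @param seed Integer seed (defaults to the community seed).
#' @return List of class `run_config`.
#' @export
run_config <- function(community = community_config(),
                       min_read_cov = 0.70,
                       species_identity = 0.95,
                       island_identity_floor = 0.95,
                       window_bp = 500, ratio_max = 0.2,
                       min_island_len = 1000, min_detect_depth = 5,
                       fill_ratio = 0.8,
                       derep_min_len = 43000, derep_min_id = 1.0,
                       derep_min_frac = 0.8,
                       species_thr = 95, genus_thr = 70,
                       use_planted_orfs = TRUE,
                       amplicon_n_reads = 2000, rarefaction_depth = 1000,
                       min_aa_cov = 5, min_mut_codon_count = 4,
                       min_mut_codon_freq = 1,
                       sketch_k = 21, sketch_s = 10000,
                       sketch_min_count = 2,
                       seed = NULL) {
  stopifnot(inherits(community, "community_config"))
  cfg <- as.list(environment())
  cfg$seed <- seed %||% community$seed
  for (p in c("min_read_cov", "species_identity", "island_identity_floor",
              "ratio_max", "fill_ratio"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop("run_config: '", p, "' outside [0, 1]")
  class(cfg) <- "run_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full mesocosm-replay pipeline
#'
#' Simulates the community and two ponds (an amended pond carrying the
#' genotype sweep and an unamended control), then runs taxonomy,
#' recruitment, abundance/fold-change, island dynamics, amplicon diversity,
#' codon-variant and metagenome-distance stages, returning a summary and
#' optionally writing all stage outputs (FASTA/FASTQ/BED/TSV/JSON) to
#' `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @return List of class `ss_report` with elements `taxonomy`, `abundance`,
#'   `fold_change`, `islands_t0`, `island_status`, `capture`, `shannon`,
#'   `pnps`, `mash`, `summary` and the simulation `truth`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cc <- config$community

  ## --- simulate both ponds -------------------------------------------------
  sim <- stage("simulate", {
    gen <- simulate_genus(cc)
    tc_a <- simulate_timecourse(gen$genomes, gen$truth, cc)
    cc_ctrl <- cc
    cc_ctrl$sweep_f_end <- cc$sweep_genotype_f0
    cc_ctrl$seed <- cc$seed + 977L  # independent read stream for the control
    truth_c <- gen$truth
    truth_c$sweep_trajectory <- sweep_trajectory(cc_ctrl)
    truth_c$abundances <- planted_abundances(gen$truth$genome_info, cc_ctrl)
    tc_c <- simulate_timecourse(gen$genomes, truth_c, cc_ctrl)
    list(genomes = gen$genomes, truth = tc_a$truth,
         truth_control = tc_c$truth,
         ponds = list(amended = tc_a$samples, control = tc_c$samples))
  })

  ## --- taxonomy ------------------------------------------------------------
  taxo <- stage("taxonomy", {
    viral <- Filter(function(g) !identical(g$species, "background"),
                    sim$genomes)
    derep <- dereplicate_genomes(viral, min_len = config$derep_min_len,
                                 min_id = config$derep_min_id,
                                 min_aligned_frac = config$derep_min_frac)
    sim_mat <- similarity_matrix(derep)
    sp_assign <- assign_species_genus(sim_mat,
                                      species_thr = config$species_thr,
                                      genus_thr = config$genus_thr)
    sp_assign$group <- NA_character_
    sp_assign$is_reference <- FALSE
    aai_mats <- list()
    for (sp in unique(sp_assign$species)) {
      members <- sp_assign$genome_id[sp_assign$species == sp]
      if (length(members) == 1) {
        sp_assign$group[sp_assign$genome_id == members] <- "group_1"
        sp_assign$is_reference[sp_assign$genome_id == members] <- TRUE
        next
      }
      prots <- lapply(derep[members], function(g)
        genome_proteins(g, orfs = if (config$use_planted_orfs) NULL else
          predict_orfs(g)))
      aai <- aai_matrix(prots)
      aai_mats[[sp]] <- aai
      grp <- cluster_intraspecies_groups(aai, genomes = derep[members])
      for (r in seq_len(nrow(grp))) {
        i <- sp_assign$genome_id == grp$genome_id[r]
        sp_assign$group[i] <- grp$group[r]
        sp_assign$is_reference[i] <- grp$is_reference[r]
      }
    }
    list(assignments = sp_assign, similarity = sim_mat, aai = aai_mats,
         references = sp_assign$genome_id[sp_assign$is_reference],
         n_genera = length(unique(sp_assign$genus)),
         n_species = length(unique(sp_assign$species)))
  })

  refs <- sim$genomes[taxo$references]
  ref_idx <- lapply(refs, genome_index)
  sweep_id <- sim$truth$sweep_genome
  sweep_ref <- sim$genomes[[sweep_id]]
  sweep_idx <- list(genome_index(sweep_ref))
  names(sweep_idx) <- sweep_id
  tp <- cc$timepoints_h

  ## --- recruitment, abundance, capture, islands ----------------------------
  recr <- stage("recruitment", {
    out <- list()
    for (pond in names(sim$ponds)) {
      samples <- sim$ponds[[pond]]
      hits_comp <- list(); profiles <- list()
      abund <- list(); capture <- list()
      for (si in seq_along(samples)) {
        smp <- samples[[si]]
        meta_nt <- sum(nchar(smp$reads))
        hc <- recruit_best_hits(smp$reads, ref_idx,
                                min_read_cov = config$min_read_cov)
        hs <- recruit_best_hits(smp$reads, sweep_idx,
                                min_read_cov = config$min_read_cov)
        hits_comp[[smp$sample_id]] <- hc
        profiles[[smp$sample_id]] <- depth_profile(
          hs, sweep_ref, sample_id = smp$sample_id,
          identity_floor = config$island_identity_floor)
        ab <- lapply(names(refs), function(gid)
          genotype_abundance(hc[hc$genome_id == gid, , drop = FALSE],
                             refs[[gid]], meta_nt,
                             sample_id = smp$sample_id,
                             min_read_cov = config$min_read_cov))
        ab <- do.call(rbind, ab)
        ab$pond <- pond
        ab$timepoint_h <- smp$timepoint_h
        abund[[smp$sample_id]] <- ab
        pc <- population_capture(hs, genome_id = sweep_id,
                                 sample_id = smp$sample_id,
                                 min_read_cov = config$min_read_cov,
                                 species_identity = config$species_identity)
        pc$pond <- pond
        pc$timepoint_h <- smp$timepoint_h
        capture[[smp$sample_id]] <- pc
      }
      out[[pond]] <- list(hits = hits_comp, profiles = profiles,
                          abundance = do.call(rbind, abund),
                          capture = do.call(rbind, capture))
    }
    out
  })
  abundance <- do.call(rbind, lapply(recr, `[[`, "abundance"))
  abundance$display_abundance <- abundance$normalized_abundance * 1000
  rownames(abundance) <- NULL
  capture <- do.call(rbind, lapply(recr, `[[`, "capture"))
  rownames(capture) <- NULL

  dyn <- stage("dynamics", {
    sweep_ab <- lapply(names(recr), function(pond) {
      a <- recr[[pond]]$abundance
      a <- a[a$genome_id == sweep_id, , drop = FALSE]
      a[order(a$timepoint_h), ]
    })
    names(sweep_ab) <- names(recr)
    fc <- lapply(names(sweep_ab), function(pond) {
      f <- fold_change_series(sweep_ab[[pond]]$normalized_abundance, tp)
      if (nrow(f)) f$pond <- pond
      f
    })
    islands_t0 <- detect_islands(recr$amended$profiles[[1]],
                                 window_bp = config$window_bp,
                                 ratio_max = config$ratio_max,
                                 min_island_len = config$min_island_len,
                                 min_detect_depth = config$min_detect_depth)
    status <- lapply(names(recr), function(pond) {
      if (nrow(islands_t0) == 0) return(NULL)
      s <- island_timecourse(recr[[pond]]$profiles, islands_t0,
                             fill_ratio = config$fill_ratio,
                             min_detect_depth = config$min_detect_depth)
      s$pond <- pond
      s
    })
    list(sweep_abundance = sweep_ab,
         fold_change = do.call(rbind, fc),
         islands_t0 = islands_t0,
         island_status = do.call(rbind, status))
  })

  ## --- amplicon diversity --------------------------------------------------
  div <- stage("diversity", {
    isl <- sim$truth$islands
    if (length(isl)) {
      locus <- c(isl[[1]][1] + 500L, isl[[1]][1] + 900L)
    } else {
      locus <- c(0L, min(400L, sim$truth$genome_length))
    }
    info <- sim$truth$genome_info
    sp1 <- info$genome_id[info$species == "sp1"]
    phylo_seqs <- vapply(sim$genomes[sp1], function(g)
      substr(g$seq, locus[1] + 1L, locus[2]), character(1))
    viral <- Filter(function(g) !identical(g$species, "background"),
                    sim$genomes)
    shannon <- list(); tables <- list()
    truths <- list(amended = sim$truth, control = sim$truth_control)
    for (pond in names(truths)) {
      ab <- truths[[pond]]$abundances
      for (si in seq_len(nrow(ab))) {
        sample_id <- rownames(ab)[si]
        freqs <- ab[si, sp1]
        freqs <- freqs / sum(freqs)
        pool <- simulate_amplicon_pool(
          phylo_seqs, unname(freqs), config$amplicon_n_reads,
          error_rate = cc$amplicon_error_rate,
          seed = cc$seed + 500L + si +
            1000L * match(pond, names(truths)))
        tab <- phylotype_profile(pool$reads, viral,
                                 locus_id = "island_locus",
                                 sample_id = sample_id)
        tab <- rarefy_phylotypes(tab, config$rarefaction_depth,
                                 seed = cc$seed + 700L + si)
        tables[[paste(pond, sample_id, sep = "_")]] <- tab
        shannon[[length(shannon) + 1L]] <- data.frame(
          pond = pond, sample_id = sample_id, timepoint_h = tp[si],
          n_phylotypes = nrow(tab), shannon = shannon_index(tab),
          stringsAsFactors = FALSE)
      }
    }
    list(locus = locus, tables = tables,
         shannon = do.call(rbind, shannon))
  })

  ## --- codon variants on the sweep reference (t0 vs final, amended) --------
  pnps <- stage("codon_variants", {
    orfs <- sweep_ref$orfs
    res <- list()
    for (si in c(1L, length(tp))) {
      smp <- sim$ponds$amended[[si]]
      hs <- recruit_best_hits(smp$reads, sweep_idx,
                              min_read_cov = config$min_read_cov,
                              min_identity = config$species_identity)
      for (oi in seq_len(nrow(orfs))) {
        ov <- hs[hs$g_end > orfs$start[oi] & hs$g_start < orfs$end[oi], ,
                 drop = FALSE]
        pil <- orf_pileup(ov, smp$reads, sweep_ref,
                          orfs$start[oi], orfs$end[oi], orfs$strand[oi])
        cv <- codon_variant_counts(pil, min_aa_cov = config$min_aa_cov,
                                   min_mut_codon_count =
                                     config$min_mut_codon_count,
                                   min_mut_codon_freq =
                                     config$min_mut_codon_freq)
        res[[length(res) + 1L]] <- data.frame(
          sample_id = smp$sample_id, timepoint_h = tp[si],
          orf_id = cv$orf_id, syn_count = cv$syn_count,
          nonsyn_count = cv$nonsyn_count, pn_fraction = cv$pn_fraction,
          n_codons_covered = cv$n_codons_covered,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, res)
  })

  ## --- metagenome distances ------------------------------------------------
  mash <- stage("distance", {
    sketches <- list()
    for (pond in names(sim$ponds)) {
      for (smp in sim$ponds[[pond]]) {
        sketches[[paste(pond, smp$sample_id, sep = "_")]] <-
          minhash_sketch(smp$reads, k = config$sketch_k,
                         s = config$sketch_s,
                         min_count = config$sketch_min_count)
      }
    }
    m <- mash_distance_matrix(sketches)
    first <- sprintf("t%04dh", tp[1])
    last <- sprintf("t%04dh", tp[length(tp)])
    list(matrix = m,
         amended_t0_tend = m[paste0("amended_", first),
                             paste0("amended_", last)],
         control_t0_tend = m[paste0("control_", first),
                             paste0("control_", last)])
  })

  summary <- list(
    seed = config$seed,
    n_genera = taxo$n_genera,
    n_species = taxo$n_species,
    n_groups = vapply(split(taxo$assignments$group,
                            taxo$assignments$species),
                      function(g) length(unique(g)), integer(1)),
    sweep_genome = sweep_id,
    sweep_abundance = lapply(dyn$sweep_abundance, function(a)
      setNames(a$normalized_abundance, a$sample_id)),
    sweep_reads = lapply(dyn$sweep_abundance, function(a)
      setNames(a$n_reads, a$sample_id)),
    islands_t0 = dyn$islands_t0[, c("start", "end", "ratio")],
    island_status = if (!is.null(dyn$island_status))
      dyn$island_status[, c("pond", "sample_id", "ratio", "status")],
    capture_pct = setNames(capture$capture_pct,
                           paste(capture$pond, capture$sample_id,
                                 sep = "_")),
    shannon = div$shannon,
    mash_amended_t0_tend = mash$amended_t0_tend,
    mash_control_t0_tend = mash$control_t0_tend)

  report <- structure(list(
    config = config, taxonomy = taxo, abundance = abundance,
    fold_change = dyn$fold_change, islands_t0 = dyn$islands_t0,
    island_status = dyn$island_status, capture = capture,
    shannon = div$shannon, phylotypes = div$tables, pnps = pnps,
    mash = mash, truth = sim$truth, summary = summary),
    class = "ss_report")

  if (!is.null(out_dir)) {
    stage("write_outputs",
          write_report_bundle(report, sim, recr, out_dir))
  }
  report
}

# Write every stage output as plain FASTA/FASTQ/BED/TSV/JSON. No
# timestamps: rerunning with the same config and seed is byte-identical.
write_report_bundle <- function(report, sim, recr, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("reads", "hits", "phylotypes"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  config <- report$config

  write_genomes_fasta(sim$genomes, file.path(out_dir, "genomes.fasta"))
  g1 <- sim$genomes[[1]]
  if (nrow(g1$orfs))
    write_intervals_bed(g1$orfs, g1$id, file.path(out_dir, "orfs.bed"))

  truth_out <- sim$truth
  truth_out$abundances <- as.data.frame(truth_out$abundances)
  truth_out$read_origin <- NULL  # per-read origin goes to its own files
  write_truth_json(truth_out, file.path(out_dir, "truth.json"))
  for (sid in names(sim$truth$read_origin))
    write.table(sim$truth$read_origin[[sid]],
                file.path(out_dir, "reads",
                          paste0("amended_", sid, "_origin.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)

  for (pond in names(sim$ponds)) {
    for (smp in sim$ponds[[pond]]) {
      base <- paste0(pond, "_", smp$sample_id)
      write_reads_fastq(smp$reads,
                        file.path(out_dir, "reads", paste0(base, ".fastq")))
      write_hits_tsv(recr[[pond]]$hits[[smp$sample_id]],
                     file.path(out_dir, "hits", paste0(base, ".tsv")))
    }
  }

  write.table(report$abundance, file.path(out_dir, "abundance.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$fold_change) && nrow(report$fold_change))
    write.table(report$fold_change, file.path(out_dir, "fold_change.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(report$islands_t0))
    write_intervals_bed(report$islands_t0, report$islands_t0$genome_id[1],
                        file.path(out_dir, "islands_t0.bed"))
  if (!is.null(report$island_status))
    write.table(report$island_status,
                file.path(out_dir, "island_status.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$capture, file.path(out_dir, "capture.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  write_matrix_tsv(report$taxonomy$similarity,
                   file.path(out_dir, "similarity.tsv"))
  for (sp in names(report$taxonomy$aai))
    write_matrix_tsv(report$taxonomy$aai[[sp]],
                     file.path(out_dir, paste0("aai_", sp, ".tsv")))
  write.table(report$taxonomy$assignments,
              file.path(out_dir, "assignments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  for (nm in names(report$phylotypes))
    write.table(report$phylotypes[[nm]],
                file.path(out_dir, "phylotypes", paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$shannon, file.path(out_dir, "shannon.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$pnps, file.path(out_dir, "pnps.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(report$mash$matrix,
                   file.path(out_dir, "mash_distances.tsv"))

  log <- list(package = "strainsweep",
              version = as.character(utils::packageVersion("strainsweep")),
              seed = config$seed,
              config = config[setdiff(names(config), "community")],
              community = unclass(config$community))
  write_truth_json(log, file.path(out_dir, "log.json"))
  write_truth_json(report$summary, file.path(out_dir, "summary.json"))
  invisible(out_dir)
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys override [run_config()] arguments; the optional
#' `community:` block overrides [community_config()] arguments.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  comm_args <- y$community %||% list()
  if (!is.null(comm_args$island_intervals))
    comm_args$island_intervals <- lapply(comm_args$island_intervals,
                                         as.integer)
  community <- do.call(community_config, comm_args)
  run_args <- y[setdiff(names(y), "community")]
  do.call(run_config, c(list(community = community), run_args))
}
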