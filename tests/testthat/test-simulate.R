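test_that("default community has the planted genome properties", {
  cc <- community_config(seed = 42)
  gen <- simulate_genus(cc)
  lens <- vapply(gen$genomes, function(g) nchar(g$seq), integer(1))
  expect_true(all(lens >= 44000 & lens <= 46000))
  expect_length(unique(lens), 1L)

  gc <- vapply(gen$genomes, function(g) {
    v <- strsplit(g$seq, "", fixed = TRUE)[[1]]
    mean(v %in% c("G", "C"))
  }, numeric(1))
  expect_true(all(abs(gc - 0.63) <= 0.01))

  info <- gen$truth$genome_info
  expect_identical(sum(info$species == "sp1"), 17L)
  expect_identical(sum(info$species == "sp2"), 1L)
  expect_identical(sum(info$is_sweep), 1L)
  expect_identical(length(unique(info$group[info$species == "sp1"])), 9L)

  # regenerating with the same seed is byte-identical
  gen2 <- simulate_genus(community_config(seed = 42))
  expect_identical(vapply(gen$genomes, `[[`, "", "seq"),
                   vapply(gen2$genomes, `[[`, "", "seq"))
})

test_that("planted identities respect the species/genus bands", {
  gen <- simulate_genus(community_config(seed = 5))
  viral <- Filter(function(g) !identical(g$species, "background"),
                  gen$genomes)
  enc <- lapply(viral, function(g) charToRaw(g$seq))
  sp <- vapply(viral, `[[`, "", "species")
  for (i in 1:(length(viral) - 1)) {
    for (j in (i + 1):length(viral)) {
      ident <- mean(enc[[i]] == enc[[j]])
      if (sp[i] == sp[j]) expect_gt(ident, 0.95)
      else {
        expect_gt(ident, 0.70)
        expect_lt(ident, 0.95)
      }
    }
  }
})

test_that("island divergence matches the site-resampling closed form", {
  cc <- community_config(seed = 8)
  gen <- simulate_genus(cc)
  isl <- gen$truth$islands[[1]]
  slice <- function(g) strsplit(substr(g$seq, isl[1] + 1, isl[2]), "",
                                fixed = TRUE)[[1]]
  a <- slice(gen$genomes[["sp1_g01_i1"]])
  b <- slice(gen$genomes[["sp2_g01_i1"]])
  mism <- mean(a != b)
  # lineage resample probabilities inside the island: species-level 0.30
  # (sp1 also carries group 0.10), genome-level 0.002 on both sides
  p1 <- 1 - (1 - 0.30) * (1 - 0.10) * (1 - 0.002)
  p2 <- 1 - (1 - 0.30) * (1 - 0.002)
  expected <- planted_divergence(p1, p2, 0.63)
  sd3 <- 4 * sqrt(expected * (1 - expected) / (isl[2] - isl[1]))
  expect_lt(abs(mism - expected), sd3)
})

test_that("zero divergence yields identical genomes; bad settings rejected", {
  cc0 <- community_config(seed = 2, interspecies_divergence = 0,
                          intergroup_divergence = 0,
                          intragroup_divergence = 0,
                          island_divergence = 0,
                          island_group_divergence = 0)
  gen <- simulate_genus(cc0)
  viral <- Filter(function(g) !identical(g$species, "background"),
                  gen$genomes)
  seqs <- vapply(viral, `[[`, "", "seq")
  expect_length(unique(seqs), 1L)

  # intra-species divergence so high the 0.95 species constraint breaks
  expect_error(simulate_genus(community_config(seed = 2,
                                               intergroup_divergence = 0.1)),
               "within-species identity")
})

test_that("time course draws reads proportional to planted abundances", {
  cc <- small_config(seed = 3)
  gen <- simulate_genus(cc)
  tc <- simulate_timecourse(gen$genomes, gen$truth, cc)
  for (smp in tc$samples)
    expect_length(smp$reads, cc$reads_per_sample)
  # every read id appears exactly once in the truth
  for (sid in names(tc$truth$read_origin)) {
    org <- tc$truth$read_origin[[sid]]
    expect_setequal(org$read_id, names(tc$samples[[sid]]$reads))
    expect_false(anyDuplicated(org$read_id) > 0)
  }

  # binomial check on a two-source community across 20 seeds
  g <- list(A = rand_seq(2000), B = rand_seq(2000))
  genomes <- list(A = structure(list(id = "A", seq = g$A, orfs = NULL,
                                     species = "x", is_sweep = FALSE),
                                class = "ss_genome"),
                  B = structure(list(id = "B", seq = g$B, orfs = NULL,
                                     species = "x", is_sweep = FALSE),
                                class = "ss_genome"))
  truth <- list(abundances = matrix(c(0.8, 0.2), nrow = 1,
                                    dimnames = list("t0000h", c("A", "B"))))
  n <- 10000
  for (seed in 1:20) {
    cc2 <- community_config(reads_per_sample = n, read_length_bp = 100,
                            error_rate = 0, timepoints_h = 0, seed = seed)
    tc2 <- simulate_timecourse(genomes, truth, cc2)
    nb <- sum(tc2$truth$read_origin[["t0000h"]]$genome_id == "B")
    expect_lt(abs(nb - n * 0.2), 3 * sqrt(n * 0.2 * 0.8))
  }
})

test_that("error-free reads are exact substrings of their source genome", {
  g <- rand_seq(5000)
  genomes <- list(G = structure(list(id = "G", seq = g, orfs = NULL,
                                     species = "x", is_sweep = FALSE),
                                class = "ss_genome"))
  truth <- list(abundances = matrix(1, 1, 1,
                                    dimnames = list("t0000h", "G")))
  cc <- community_config(reads_per_sample = 200, read_length_bp = 150,
                         error_rate = 0, timepoints_h = 0, seed = 4)
  tc <- simulate_timecourse(genomes, truth, cc)
  org <- tc$truth$read_origin[["t0000h"]]
  reads <- tc$samples[[1]]$reads[org$read_id]
  expect_identical(unname(reads),
                   substring(g, org$start + 1, org$end))
  expect_error(simulate_timecourse(genomes, truth,
                                   community_config(reads_per_sample = 0,
                                                    timepoints_h = 0)),
               "positive")
})

test_that("sweep trajectory interpolates the planted endpoints", {
  cc <- community_config(seed = 1)
  tr <- sweep_trajectory(cc)
  expect_equal(tr$f[1], cc$sweep_genotype_f0, tolerance = 1e-8)
  expect_equal(tr$f[length(tr$f)], cc$sweep_f_end, tolerance = 1e-8)
  expect_true(all(diff(tr$f) > 0))
  # null experiment: flat trajectory
  cc0 <- community_config(sweep_f_end = 1e-4)
  expect_true(all(sweep_trajectory(cc0)$f == 1e-4))
})

test_that("amplicon pools reproduce planted phylotype frequencies", {
  ph <- c(p1 = rand_seq(300), p2 = rand_seq(300))
  # single phylotype, no errors: all reads identical
  pool <- simulate_amplicon_pool(ph[1], 1, 50, error_rate = 0, seed = 1)
  expect_length(unique(unname(pool$reads)), 1L)
  # binomial check over 20 seeds
  for (seed in 1:20) {
    pool <- simulate_amplicon_pool(ph, c(0.9, 0.1), 1000,
                                   error_rate = 0, seed = seed)
    n2 <- sum(unname(pool$reads) == ph[["p2"]])
    expect_lt(abs(n2 - 100), 3 * sqrt(1000 * 0.9 * 0.1))
  }
  expect_error(simulate_amplicon_pool(character(0), numeric(0), 10),
               "empty")
})
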