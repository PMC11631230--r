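test_that("exact and reverse-complement reads align perfectly", {
  set.seed(11)
  g <- rand_seq(2000, gc = 0.63)
  r <- substr(g, 501, 650)
  h <- align_read_local(r, g)
  expect_equal(h[, c("g_start", "g_end", "strand", "identity", "read_cov")],
               data.frame(g_start = 500L, g_end = 650L, strand = "+",
                          identity = 1, read_cov = 1))
  hrc <- align_read_local(revcomp_str(r), g)
  expect_equal(hrc$g_start, 500L)
  expect_equal(hrc$strand, "-")
  expect_equal(hrc$identity, 1)
})

test_that("planted substitutions give the expected identity", {
  set.seed(12)
  for (i in 1:20) {
    g <- rand_seq(1000)
    r <- plant_subs(substr(g, 301, 400), 2, positions = c(30, 70))
    h <- align_read_local(r, g)
    expect_equal(h$identity, 0.98)
    expect_equal(c(h$g_start, h$g_end), c(300L, 400L))
  }
})

test_that("short genomes and too-short reads are handled", {
  expect_null(align_read_local(rand_seq(30), rand_seq(10)))
  expect_error(align_read_local("ACGT", rand_seq(100)), "seed size")
})

test_that("best-hit recruitment filters and tie-breaks deterministically", {
  set.seed(13)
  g1 <- rand_seq(3000)
  reads <- c(full = substr(g1, 1001, 1250),
             half = paste0(substr(g1, 2001, 2100), rand_seq(150)))
  genomes <- list(b_copy = g1, a_copy = g1)
  hits <- recruit_best_hits(reads, genomes, min_read_cov = 0.7)
  # read aligning over <70% of its length is filtered out
  expect_identical(hits$read_id, "full")
  # identical placement on two genomes: lexicographically smallest id wins
  expect_identical(hits$genome_id, "a_copy")
  expect_error(recruit_best_hits(reads, list()), "empty genome set")
})

test_that("error-free simulated reads all map to their source genome", {
  cc <- small_config(seed = 6, error_rate = 0, background_fraction = 0,
                     reads_per_sample = 600)
  gen <- simulate_genus(cc)
  tc <- simulate_timecourse(gen$genomes, gen$truth, cc)
  smp <- tc$samples[[1]]
  viral <- Filter(function(g) !identical(g$species, "background"),
                  gen$genomes)
  hits <- recruit_best_hits(smp$reads, viral, min_read_cov = 0.7)
  org <- tc$truth$read_origin[[smp$sample_id]]
  expect_identical(nrow(hits), length(smp$reads))
  truth_gid <- org$genome_id[match(hits$read_id, org$read_id)]
  # perfect-identity placement; ties between near-identical strains are
  # resolved within the true group
  expect_true(all(hits$identity == 1))
  truth_group <- gen$truth$genome_info$group[
    match(truth_gid, gen$truth$genome_info$genome_id)]
  hit_group <- gen$truth$genome_info$group[
    match(hits$genome_id, gen$truth$genome_info$genome_id)]
  expect_gt(mean(hit_group == truth_group), 0.99)
})

test_that("raising filters never increases the number of hits", {
  cc <- small_config(seed = 9, reads_per_sample = 400)
  gen <- simulate_genus(cc)
  tc <- simulate_timecourse(gen$genomes, gen$truth, cc)
  refs <- gen$genomes[grep("i1$", names(gen$genomes), value = TRUE)[1:4]]
  n_prev <- Inf
  for (thr in c(0, 0.9, 0.95, 0.99, 1)) {
    n <- nrow(recruit_best_hits(tc$samples[[1]]$reads, refs,
                                min_read_cov = 0.7, min_identity = thr))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  n_prev <- Inf
  for (cov in c(0.2, 0.5, 0.7, 0.9, 1)) {
    n <- nrow(recruit_best_hits(tc$samples[[1]]$reads, refs,
                                min_read_cov = cov))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("depth profiles conserve aligned nucleotides", {
  g <- rand_seq(1000)
  empty <- recruit_best_hits(character(0) , list(g = g))
  p0 <- depth_profile(empty, g)
  expect_true(all(p0$depth == 0))

  one <- data.frame(read_id = "r", genome_id = "genome", g_start = 10L,
                    g_end = 110L, strand = "+", identity = 1,
                    read_cov = 1, aligned_nt = 100L)
  p1 <- depth_profile(one, g)
  expect_identical(sum(p1$depth), 100L)
  expect_true(all(p1$depth[11:110] == 1L) && all(p1$depth[-(11:110)] == 0L))

  bad <- one; bad$g_end <- 2000L
  expect_error(depth_profile(bad, g), "corrupt")
})

test_that("uniform simulated coverage matches brute-force counting", {
  set.seed(20)
  g <- structure(list(id = "G", seq = rand_seq(8000), orfs = NULL,
                      species = "x", is_sweep = FALSE), class = "ss_genome")
  truth <- list(abundances = matrix(1, 1, 1,
                                    dimnames = list("t0000h", "G")))
  cc <- community_config(reads_per_sample = 1600, read_length_bp = 100,
                         error_rate = 0, timepoints_h = 0, seed = 17)
  tc <- simulate_timecourse(list(G = g), truth, cc)
  hits <- recruit_best_hits(tc$samples[[1]]$reads, list(G = g))
  prof <- depth_profile(hits, g)
  expect_identical(sum(prof$depth), sum(hits$aligned_nt))
  expect_lt(abs(mean(prof$depth) - 20), 2)
  # brute-force interval stabbing at 50 random positions
  pos <- sample(8000, 50)
  brute <- vapply(pos, function(p)
    sum(hits$g_start < p & hits$g_end >= p), integer(1))
  expect_identical(prof$depth[pos], brute)
})
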