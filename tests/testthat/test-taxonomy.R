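test_that("dereplication drops short and identical genomes", {
  set.seed(41)
  a <- rand_seq(45000)
  b <- rand_seq(40000)
  out <- dereplicate_genomes(list(A = a, A_copy = a, B = b))
  expect_identical(names(out), "A")
  # one substitution breaks perfect identity: both retained
  a1 <- plant_subs(a, 1, positions = 22000)
  out2 <- dereplicate_genomes(list(A = a, A1 = a1))
  expect_setequal(names(out2), c("A", "A1"))
  expect_error(dereplicate_genomes(list()), "empty")
})

test_that("dereplication recovers planted duplicates in a genome set", {
  set.seed(42)
  base <- replicate(5, rand_seq(44000))
  genomes <- as.list(setNames(base, sprintf("g%d", 1:5)))
  genomes <- c(genomes,
               setNames(as.list(base[c(1, 3, 5)]), sprintf("dup%d", 1:3)))
  out <- dereplicate_genomes(genomes)
  expect_identical(length(out), 5L)
  # exactly one representative of each identical pair survives
  expect_setequal(unlist(out, use.names = FALSE), base)
})

test_that("intergenomic similarity matches a site-count oracle", {
  set.seed(43)
  g <- rand_seq(30000, gc = 0.63)
  expect_equal(intergenomic_similarity(g, g)$intergenomic_sim, 100)
  # 4% uniformly planted substitutions
  g4 <- plant_subs(g, 1200)
  s <- intergenomic_similarity(g, g4)
  planted_id <- mean(strsplit(g, "", fixed = TRUE)[[1]] ==
                       strsplit(g4, "", fixed = TRUE)[[1]])
  expect_lt(abs(s$intergenomic_sim - 100 * planted_id), 0.5)
  expect_gt(s$aligned_frac_a, 0.99)
  # unrelated random genomes share nothing
  u <- intergenomic_similarity(rand_seq(20000), rand_seq(20000))
  expect_lt(u$intergenomic_sim, 5)
  expect_lt(u$aligned_frac_a, 0.05)
})

test_that("similarity is reciprocal within the fragment-sampling tolerance", {
  set.seed(44)
  g <- rand_seq(25000)
  g2 <- plant_subs(g, 700)
  ab <- intergenomic_similarity(g, g2)$intergenomic_sim
  ba <- intergenomic_similarity(g2, g)$intergenomic_sim
  expect_lt(abs(ab - ba), 1)
})

test_that("species/genus assignment applies the ICTV-style thresholds", {
  m <- matrix(c(100, 96, 96, 100), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  a <- assign_species_genus(m)
  expect_identical(a$species[1], a$species[2])
  expect_identical(a$genus[1], a$genus[2])
  m[1, 2] <- m[2, 1] <- 85
  a2 <- assign_species_genus(m)
  expect_identical(a2$genus[1], a2$genus[2])
  expect_false(a2$species[1] == a2$species[2])
  m[1, 2] <- m[2, 1] <- 50
  a3 <- assign_species_genus(m)
  expect_false(a3$genus[1] == a3$genus[2])
  # boundary: exactly 95 is the same genus but NOT the same species
  m[1, 2] <- m[2, 1] <- 95
  a4 <- assign_species_genus(m)
  expect_false(a4$species[1] == a4$species[2])
  bad <- m; bad[1, 2] <- 60
  expect_error(assign_species_genus(bad), "symmetric")
})

test_that("assignment is invariant to input order", {
  cc <- small_config(seed = 45)
  gen <- simulate_genus(cc)
  viral <- Filter(function(g) !identical(g$species, "background"),
                  gen$genomes)
  m <- similarity_matrix(viral)
  perm <- sample(rownames(m))
  a1 <- assign_species_genus(m)
  a2 <- assign_species_genus(m[perm, perm])
  expect_identical(a1, a2)
  # default community structure is recovered
  expect_identical(length(unique(a1$genus)), 1L)
  expect_identical(length(unique(a1$species)), 2L)
})

test_that("ORF prediction matches an exhaustive frame scan", {
  set.seed(46)
  # one planted 600 nt ORF inside stop-rich flanks
  orf_nt <- paste0("ATG",
                   paste(rep("GCT", 198), collapse = ""), "TAA")
  flank <- paste(rep("TAA", 40), collapse = "")
  g <- paste0(flank, orf_nt, flank)
  orfs <- predict_orfs(g, min_len = 300)
  fwd <- orfs[orfs$strand == "+", ]
  expect_identical(nrow(fwd), 1L)
  expect_identical(c(fwd$start, fwd$end), c(120L, 720L))
  # all-stop sequence has no ORFs
  expect_identical(nrow(predict_orfs(paste(rep("TAA", 200),
                                           collapse = ""))), 0L)
  # reverse-complement symmetry
  orfs_rc <- predict_orfs(revcomp_str(g), min_len = 300)
  len <- nchar(g)
  expect_setequal(paste(len - orfs$end, len - orfs$start),
                  paste(orfs_rc$start, orfs_rc$end))
})

test_that("planted ORFs translate to stop-free proteins", {
  gen <- simulate_genus(small_config(seed = 47,
                                     interspecies_divergence = 0,
                                     intergroup_divergence = 0,
                                     intragroup_divergence = 0,
                                     island_divergence = 0,
                                     island_group_divergence = 0))
  g <- gen$genomes[[1]]
  prots <- genome_proteins(g)
  expect_identical(length(prots), nrow(g$orfs))
  # ATG + body, terminal stop trimmed; planted frames carry no internal stop
  expect_identical(unique(nchar(prots)),
                   as.integer((g$orfs$end[1] - g$orfs$start[1]) / 3 - 1))
})

test_that("reciprocal best-match AAI averages mutual pairs", {
  prots <- c(a = paste(rep("M", 40), collapse = ""),
             b = paste(rep("W", 60), collapse = ""))
  self <- pairwise_aai(prots, prots, min_aa_len = 0)
  expect_equal(self$aai, 100)
  expect_identical(self$n_pairs, 2L)
  # one 10-residue protein with a single substitution: that pair is 90%
  p1 <- c(x = "MAAAAAAAAA", y = paste(rep("C", 30), collapse = ""))
  p2 <- c(x = "MAAAAAAAAW", y = paste(rep("C", 30), collapse = ""))
  r <- pairwise_aai(p1, p2, min_aa_len = 0)
  expect_equal(r$aai, mean(c(90, 100)))
  # unrelated random proteins fall below the reciprocity identity floor
  set.seed(48)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  rp <- function() paste(sample(aa, 80, TRUE), collapse = "")
  miss <- pairwise_aai(c(rp(), rp()), c(rp(), rp()), min_aa_len = 0)
  expect_true(is.na(miss$aai))
  expect_error(pairwise_aai(character(0), "MA"), "empty ORF set")
})

test_that("group clustering recovers planted structure and references", {
  # all-identical genomes collapse to one group
  aai1 <- matrix(100, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  g1 <- cluster_intraspecies_groups(aai1)
  expect_identical(unique(g1$group), "group_1")
  # reference = the longest genome of the group
  genomes <- list(a = rand_seq(45000), b = rand_seq(45010))
  aai2 <- matrix(c(100, 99, 99, 100), 2, 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
  g2 <- cluster_intraspecies_groups(aai2, genomes = genomes, n_groups = 1)
  expect_identical(g2$genome_id[g2$is_reference], "b")
  # missing entries are an error naming the pair
  aai3 <- aai2; aai3[1, 2] <- aai3[2, 1] <- NA
  expect_error(cluster_intraspecies_groups(aai3), "missing AAI")
  # small simulated community: default gap cut finds the 3 planted groups
  gen <- simulate_genus(small_config(seed = 49))
  sp1 <- gen$genomes[grep("^sp1", names(gen$genomes))]
  aai <- aai_matrix(lapply(sp1, genome_proteins))
  grp <- cluster_intraspecies_groups(aai, genomes = sp1)
  expect_identical(length(unique(grp$group)), 3L)
  truthg <- gen$truth$genome_info$group[
    match(grp$genome_id, gen$truth$genome_info$genome_id)]
  expect_true(all(rowSums(table(grp$group, truthg) > 0) == 1))
  expect_identical(sum(grp$is_reference), 3L)
})
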