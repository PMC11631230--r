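test_that("phylotype profiling collapses at 100% identity and coverage", {
  set.seed(51)
  ref <- rand_seq(400)
  a <- substr(ref, 1, 60)
  b <- plant_subs(a, 1, positions = 30)
  reads <- setNames(c(rep(a, 3), rep(b, 2)), sprintf("r%d", 1:5))
  tab <- phylotype_profile(reads, list(ref = ref))
  expect_identical(nrow(tab), 2L)
  expect_identical(sort(tab$count), c(2L, 3L))

  # a read that is an exact substring merges into the longer phylotype
  reads2 <- setNames(c(a, substr(a, 10, 50)), c("long", "short"))
  tab2 <- phylotype_profile(reads2, list(ref = ref))
  expect_identical(nrow(tab2), 1L)
  expect_identical(tab2$count, 2L)
  expect_identical(tab2$phylotype, a)
  # containment also applies on the reverse strand
  reads3 <- setNames(c(a, revcomp_str(substr(a, 10, 50))), c("l", "s"))
  tab3 <- phylotype_profile(reads3, list(ref = ref))
  expect_identical(nrow(tab3), 1L)

  # spiked non-matching random read is filtered out
  reads4 <- setNames(c(a, rand_seq(60)), c("good", "spike"))
  tab4 <- phylotype_profile(reads4, list(ref = ref))
  expect_identical(sum(tab4$count), 1L)
  expect_identical(attr(tab4, "n_filtered"), 1L)
})

test_that("rarefaction is deterministic and hypergeometric in expectation", {
  tab <- data.frame(phylotype = c("A", "B"), count = c(900L, 100L))
  same <- rarefy_phylotypes(tab, 1000, seed = 1)
  expect_identical(sort(same$count), c(100L, 900L))
  r1 <- rarefy_phylotypes(tab, 100, seed = 7)
  r2 <- rarefy_phylotypes(tab, 100, seed = 7)
  expect_identical(r1, r2)
  expect_identical(sum(r1$count), 100L)
  expect_error(rarefy_phylotypes(tab, 2000), "exceeds")

  props <- vapply(1:500, function(seed) {
    r <- rarefy_phylotypes(tab, 100, seed = seed)
    sum(r$count[r$phylotype == "B"]) / 100
  }, numeric(1))
  # hypergeometric mean 0.1; SE of the mean over 500 draws
  se <- sqrt(0.1 * 0.9 * (1000 - 100) / (1000 - 1) / 100) / sqrt(500)
  expect_lt(abs(mean(props) - 0.1), 3 * se)
})

test_that("Shannon index matches closed forms and its invariances", {
  expect_equal(shannon_index(c(10)), 0, tolerance = 1e-12)
  expect_equal(shannon_index(rep(5, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon_index(c(2, 1, 1)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)), tolerance = 1e-12)
  # invariant under count rescaling
  expect_equal(shannon_index(c(2, 1, 1)), shannon_index(c(200, 100, 100)))
  # maximized at the uniform composition for n <= 6
  set.seed(52)
  for (n in 2:6) {
    h_uni <- shannon_index(rep(10, n))
    for (i in 1:20) {
      w <- sample(1:50, n, replace = TRUE)
      expect_lte(shannon_index(w), h_uni + 1e-12)
    }
  }
  expect_error(shannon_index(integer(0)), "empty")
})

mk_pileup_reads <- function(codons, genome, orf = c(0L, 9L)) {
  # reads spanning the full 9 nt ORF, middle codon set per read
  reads <- vapply(codons, function(cd)
    paste0(substr(genome, 1, 3), cd, substr(genome, 7, 9)), character(1))
  names(reads) <- sprintf("r%03d", seq_along(reads))
  hits <- data.frame(read_id = names(reads), genome_id = "genome",
                     g_start = 0L, g_end = 9L, r_start = 0L, r_end = 9L,
                     strand = "+", identity = 1, read_cov = 1,
                     aligned_nt = 9L)
  orf_pileup(hits, reads, genome, orf[1], orf[2])
}

test_that("codon variants classify against the standard code", {
  genome <- "ATGAAATAA"  # M K stop; middle codon AAA (Lys)
  # 10x coverage, 4 reads AAG (Lys): synonymous
  p <- mk_pileup_reads(c(rep("AAA", 6), rep("AAG", 4)), genome)
  cv <- codon_variant_counts(p)
  expect_identical(cv$syn_count, 4L)
  expect_identical(cv$nonsyn_count, 0L)
  # same with AAC (Asn): nonsynonymous
  cv2 <- codon_variant_counts(mk_pileup_reads(c(rep("AAA", 6),
                                                rep("AAC", 4)), genome))
  expect_identical(cv2$nonsyn_count, 4L)
  expect_equal(cv2$pn_fraction, 1)
  # no mismatching reads: undefined fraction
  cv3 <- codon_variant_counts(mk_pileup_reads(rep("AAA", 10), genome))
  expect_identical(cv3$syn_count + cv3$nonsyn_count, 0L)
  expect_true(is.na(cv3$pn_fraction))
  # coverage 4 with 4 variant reads: skipped below min_aa_cov
  cv4 <- codon_variant_counts(mk_pileup_reads(rep("AAG", 4), genome))
  expect_identical(cv4$syn_count + cv4$nonsyn_count, 0L)
  expect_identical(cv4$n_codons_covered, 0L)
  # minority codon below min_mut_codon_count not counted
  cv5 <- codon_variant_counts(mk_pileup_reads(c(rep("AAA", 7),
                                                rep("AAG", 3)), genome))
  expect_identical(cv5$syn_count, 0L)
  expect_error(orf_pileup(data.frame(), character(0), genome, 0L, 8L),
               "divisible")
})

test_that("percent frequency threshold is applied on both sides", {
  genome <- "ATGAAATAA"
  # coverage 400 with 4 alternates: exactly 1% -> counted
  cv <- codon_variant_counts(mk_pileup_reads(c(rep("AAA", 396),
                                               rep("AAG", 4)), genome))
  expect_identical(cv$syn_count, 4L)
  # coverage 401: 0.997% -> rejected
  cv2 <- codon_variant_counts(mk_pileup_reads(c(rep("AAA", 397),
                                                rep("AAG", 4)), genome))
  expect_identical(cv2$syn_count, 0L)
})

test_that("reverse-strand ORFs are counted in coding orientation", {
  # genome '-' strand carries ATG AAA TAA; forward genome is its revcomp
  genome <- revcomp_str("ATGAAATAA")
  reads <- setNames(c(rep(genome, 6),
                      rep(revcomp_str("ATGAAGTAA"), 4)),
                    sprintf("r%d", 1:10))
  hits <- data.frame(read_id = names(reads), genome_id = "genome",
                     g_start = 0L, g_end = 9L, r_start = 0L, r_end = 9L,
                     strand = "+", identity = 1, read_cov = 1,
                     aligned_nt = 9L)
  p <- orf_pileup(hits, reads, genome, 0L, 9L, orf_strand = "-")
  expect_identical(p$ref_codons, c("ATG", "AAA", "TAA"))
  cv <- codon_variant_counts(p)
  expect_identical(cv$syn_count, 4L)  # AAG vs AAA on the coding strand
})
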