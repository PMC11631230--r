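# Shared fixtures and independent oracles, built in code at test time.

rand_seq <- function(n, gc = 0.5) {
  q <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(q), n, replace = TRUE, prob = q), collapse = "")
}

revcomp_str <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = ""), character(1), USE.NAMES = FALSE)
}

# Plant exactly `n_sub` substitutions at the given (or random interior)
# 1-based positions; each becomes a different base.
plant_subs <- function(seq, n_sub, positions = NULL) {
  if (n_sub == 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (is.null(positions))
    positions <- sample(seq_along(v), n_sub)
  for (p in positions) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  }
  paste(v, collapse = "")
}

# Independent oracle: optimal ungapped local alignment by per-diagonal
# prefix-sum maximization (canonical optimum: maximal score, then '+'
# strand, then smaller genome start, then the shortest segment).
oracle_align <- function(read, genome) {
  best <- NULL
  for (st in c("+", "-")) {
    r <- if (st == "+") read else revcomp_str(read)
    rv <- strsplit(r, "", fixed = TRUE)[[1]]
    gv <- strsplit(genome, "", fixed = TRUE)[[1]]
    n <- length(rv); m <- length(gv)
    for (diag in (-(n - 1)):(m - 1)) {
      lo <- max(0L, -diag)             # 0-based read index range [lo, hi)
      hi <- min(n, m - diag)
      if (hi - lo < 1) next
      s <- ifelse(rv[(lo + 1):hi] == gv[(lo + diag + 1):(hi + diag)], 1L, -1L)
      P <- c(0L, cumsum(s))
      prevmin <- cummin(P)[seq_along(s)]      # min of P[0..t-1]
      M <- P[-1] - prevmin
      sc <- max(M)
      if (sc <= 0) next
      j <- which.max(M)                       # first maximal end
      i <- max(which(P[1:j] == min(P[1:j]))) - 1L  # latest minimal start
      cand <- list(score = sc, strand = st,
                   g_start = lo + i + diag, g_end = lo + j + diag,
                   alen = j - i,
                   matches = (sc + (j - i)) / 2)
      if (is.null(best)) best <- cand
      else {
        b <- best
        better <- cand$score > b$score ||
          (cand$score == b$score && cand$strand < b$strand) ||
          (cand$score == b$score && cand$strand == b$strand &&
             cand$g_start < b$g_start) ||
          (cand$score == b$score && cand$strand == b$strand &&
             cand$g_start == b$g_start && cand$alen < b$alen)
        if (better) best <- cand
      }
    }
  }
  best
}

# Small community for integration tests: 2 species, 3 groups, short course.
small_config <- function(seed = 1, reads_per_sample = 1200, ...) {
  community_config(genome_length_bp = 44500,
                   n_groups = 3,
                   timepoints_h = c(0, 336, 672),
                   reads_per_sample = reads_per_sample,
                   amplicon_error_rate = 0.001,
                   seed = seed, ...)
}

# Genetic-code classification used by test oracles (shared constant with
# the implementation; the counting logic is independent).
codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

# Exact canonical k-mer set of a read set, for the sketch-accuracy oracle.
exact_kmer_set <- function(reads, k = 21, min_count = 2) {
  kmers <- unlist(lapply(reads, function(r) {
    n <- nchar(r)
    if (n < k) return(character(0))
    substring(r, 1:(n - k + 1), k:n)
  }), use.names = FALSE)
  rc <- revcomp_str(kmers)
  canon <- ifelse(kmers <= rc, kmers, rc)
  tab <- table(canon)
  names(tab)[tab >= min_count]
}

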