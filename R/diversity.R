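revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Phylotype profile of an amplicon pool
#'
#' Discards reads sharing no exact k-mer with the reference genomes (either
#' strand), then collapses survivors at 100% identity and coverage: exact
#' duplicates, and shorter reads that are exact substrings of a longer
#' retained read (on either strand), merge into one phylotype represented
#' by the longest sequence.
#'
#' @param reads Named character vector of amplicon reads.
#' @param reference_genomes Named list of genome objects/sequences used by
#'   the spurious-sequence filter.
#' @param k K-mer size of the reference-match filter (default 21).
#' @param locus_id,sample_id Labels carried in the output attributes.
#' @return Data frame of class `phylotype_table`: `phylotype` (sequence),
#'   `count`, ordered by decreasing count; attributes `locus_id`,
#'   `sample_id`, `n_total`, `n_filtered`.
#' @export
phylotype_profile <- function(reads, reference_genomes, k = 21,
                              locus_id = "locus", sample_id = "sample") {
  refs <- vapply(reference_genomes, genome_seq, character(1))
  ok <- .cpp_kmer_match(unname(reads), unname(refs), as.integer(k))
  n_filtered <- sum(!ok)
  kept <- unname(reads)[ok]
  mk <- function(df) {
    attr(df, "locus_id") <- locus_id
    attr(df, "sample_id") <- sample_id
    attr(df, "n_total") <- sum(df$count)
    attr(df, "n_filtered") <- n_filtered
    class(df) <- c("phylotype_table", "data.frame")
    df
  }
  if (!length(kept)) {
    message("phylotype_profile: no reads survive the reference filter (",
            locus_id, "/", sample_id, ")")
    return(mk(data.frame(phylotype = character(0), count = integer(0),
                         stringsAsFactors = FALSE)))
  }
  tab <- table(kept)
  useq <- names(tab)
  cnt <- as.integer(tab)
  ord <- order(-nchar(useq), useq)
  useq <- useq[ord]; cnt <- cnt[ord]
  rc_useq <- revcomp_chr(useq)  # one vectorized call
  rep_idx <- integer(0)
  rep_cnt <- integer(0)
  for (i in seq_along(useq)) {
    merged <- FALSE
    for (j in seq_along(rep_idx)) {
      if (grepl(useq[i], useq[rep_idx[j]], fixed = TRUE) ||
          grepl(useq[i], rc_useq[rep_idx[j]], fixed = TRUE)) {
        rep_cnt[j] <- rep_cnt[j] + cnt[i]
        merged <- TRUE
        break
      }
    }
    if (!merged) {
      rep_idx <- c(rep_idx, i)
      rep_cnt <- c(rep_cnt, cnt[i])
    }
  }
  rep_seq <- useq[rep_idx]
  ord <- order(-rep_cnt, rep_seq)
  mk(data.frame(phylotype = rep_seq[ord], count = rep_cnt[ord],
                stringsAsFactors = FALSE))
}

#' Rarefy a phylotype table
#'
#' Subsamples `n` reads uniformly without replacement (one draw, no
#' averaging), deterministically for a given seed.
#'
#' @param table A [phylotype_profile()] table (or any data frame with
#'   `phylotype` and `count`).
#' @param n Target depth; must not exceed the total count.
#' @param seed Integer seed.
#' @return A phylotype table at depth `n` (zero-count phylotypes dropped).
#' @export
rarefy_phylotypes <- function(table, n, seed = 1) {
  total <- sum(table$count)
  if (n > total)
    stop("rarefaction depth ", n, " exceeds total count ", total)
  newc <- with_op_seed(seed, 400L, {
    drawn <- sample(rep.int(seq_len(nrow(table)), table$count), n)
    tabulate(drawn, nbins = nrow(table))
  })
  out <- table
  out$count <- newc
  out <- out[out$count > 0, , drop = FALSE]
  out <- out[order(-out$count, out$phylotype), , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("locus_id", "sample_id", "n_filtered"))
    attr(out, a) <- attr(table, a)
  attr(out, "n_total") <- sum(out$count)
  class(out) <- class(table)
  out
}

#' Shannon diversity index
#'
#' `H' = -sum(p_i * ln(p_i))` over phylotype frequencies (natural log).
#'
#' @param table A phylotype table, or a numeric vector of counts.
#' @return The Shannon index.
#' @export
shannon_index <- function(table) {
  counts <- if (is.data.frame(table)) table$count else as.numeric(table)
  counts <- counts[counts > 0]
  if (!length(counts)) stop("empty phylotype table")
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Codon pileup of reads over an ORF
#'
#' Collects, from ungapped recruitment hits, the read codons spanning every
#' complete codon of an ORF. Only reads covering all three positions of a
#' codon contribute to it.
#'
#' @param hits Recruitment hits on this genome (with read-side coordinates,
#'   see [recruit_best_hits()]).
#' @param reads Named character vector of the read sequences.
#' @param genome Genome object or character sequence.
#' @param orf_start,orf_end 0-based half-open ORF interval; length must be
#'   divisible by 3.
#' @param orf_strand ORF strand (`"+"` or `"-"`).
#' @return Object of class `ss_pileup`: `orf_id`, `ref_codons` (coding
#'   orientation), and `codons` (data frame: `codon_index` 1-based,
#'   `codon`, `count`).
#' @export
orf_pileup <- function(hits, reads, genome, orf_start, orf_end,
                       orf_strand = "+") {
  if ((orf_end - orf_start) %% 3 != 0)
    stop("ORF length not divisible by 3")
  sq <- genome_seq(genome)
  gid <- genome_id_of(genome)
  if ("genome_id" %in% names(hits) && any(hits$genome_id == gid))
    hits <- hits[hits$genome_id == gid, , drop = FALSE]
  n_codon <- (orf_end - orf_start) %/% 3L
  ref_nt <- substring(sq, orf_start + 1L, orf_end)
  ci_all <- integer(0)
  cs_all <- character(0)
  oriented_all <- character(nrow(hits))
  if (nrow(hits) > 0) {
    oriented_all <- unname(reads[hits$read_id])
    neg <- hits$strand == "-"
    if (any(neg)) oriented_all[neg] <- revcomp_chr(oriented_all[neg])
  }
  for (h in seq_len(nrow(hits))) {
    gs <- hits$g_start[h]; ge <- hits$g_end[h]
    lo <- max(gs, orf_start); hi <- min(ge, orf_end)
    if (hi - lo < 3L) next
    c0 <- ceiling((lo - orf_start) / 3)          # first full codon (0-based)
    c1 <- floor((hi - orf_start) / 3) - 1L       # last full codon
    if (c1 < c0) next
    cod_g <- orf_start + 3L * (c0:c1)            # genome start of each codon
    off <- cod_g - gs + hits$r_start[h]          # offset in oriented read
    cods <- substring(oriented_all[h], off + 1L, off + 3L)
    ci_all <- c(ci_all, c0:c1 + 1L)
    cs_all <- c(cs_all, cods)
  }
  if (orf_strand == "-") {
    # coding orientation: reverse-complement codons, flip indices
    cs_all <- if (length(cs_all)) revcomp_chr(cs_all) else cs_all
    ci_all <- n_codon + 1L - ci_all
    ref_nt <- revcomp_chr(ref_nt)
  }
  ref_codons <- substring(ref_nt, 3L * (seq_len(n_codon) - 1L) + 1L,
                          3L * seq_len(n_codon))
  if (length(ci_all)) {
    agg <- as.data.frame(table(codon_index = ci_all, codon = cs_all),
                         stringsAsFactors = FALSE)
    agg <- agg[agg$Freq > 0, , drop = FALSE]
    codons <- data.frame(codon_index = as.integer(agg$codon_index),
                         codon = agg$codon, count = agg$Freq,
                         stringsAsFactors = FALSE)
    codons <- codons[order(codons$codon_index, codons$codon), , drop = FALSE]
    rownames(codons) <- NULL
  } else {
    codons <- data.frame(codon_index = integer(0), codon = character(0),
                         count = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(orf_id = sprintf("%s_orf_%d_%d_%s", gid, orf_start,
                                  orf_end, orf_strand),
                 ref_codons = ref_codons, codons = codons),
            class = "ss_pileup")
}

#' Synonymous/nonsynonymous codon variant counts
#'
#' For every codon with coverage at least `min_aa_cov`, counts alternative
#' codons supported by at least `min_mut_codon_count` reads and at least
#' `min_mut_codon_freq` percent of the codon's coverage, classifying each
#' as synonymous or nonsynonymous against the reference codon under the
#' standard genetic code. Per-ORF totals sum read support: `pn` is the
#' summed nonsynonymous read count, `ps` the synonymous one, and
#' `pn_fraction = pn / (pn + ps)` (NA when no variant is counted).
#'
#' @param pileup An [orf_pileup()].
#' @param min_aa_cov Minimum codon coverage (default 5).
#' @param min_mut_codon_count Minimum reads supporting an alternative codon
#'   (default 4).
#' @param min_mut_codon_freq Minimum alternative-codon frequency in percent
#'   (default 1).
#' @return List of class `codon_variant_table`: `orf_id`, `variants`
#'   (data frame: `codon_index`, `coverage`, `ref_codon`, `alt_codon`,
#'   `count`, `aa_ref`, `aa_alt`, `type`), `syn_count`, `nonsyn_count`,
#'   `pn_fraction`, `n_codons_covered`.
#' @export
codon_variant_counts <- function(pileup, min_aa_cov = 5,
                                 min_mut_codon_count = 4,
                                 min_mut_codon_freq = 1) {
  stopifnot(inherits(pileup, "ss_pileup"))
  gcode <- Biostrings::GENETIC_CODE
  cod <- pileup$codons
  cov_by_idx <- tapply(cod$count, cod$codon_index, sum)
  vars <- list()
  n_cov <- 0L
  for (idx_chr in names(cov_by_idx)) {
    coverage <- cov_by_idx[[idx_chr]]
    if (coverage < min_aa_cov) next
    n_cov <- n_cov + 1L
    idx <- as.integer(idx_chr)
    ref <- pileup$ref_codons[idx]
    rows <- cod[cod$codon_index == idx & cod$codon != ref, , drop = FALSE]
    if (!nrow(rows)) next
    rows <- rows[rows$count >= min_mut_codon_count &
                   100 * rows$count / coverage >= min_mut_codon_freq, ,
                 drop = FALSE]
    rows <- rows[!grepl("[^ACGT]", rows$codon), , drop = FALSE]
    if (!nrow(rows)) next
    aa_ref <- unname(gcode[ref])
    aa_alt <- unname(gcode[rows$codon])
    vars[[length(vars) + 1L]] <- data.frame(
      codon_index = idx, coverage = coverage, ref_codon = ref,
      alt_codon = rows$codon, count = rows$count,
      aa_ref = aa_ref, aa_alt = aa_alt,
      type = ifelse(aa_alt == aa_ref, "synonymous", "nonsynonymous"),
      stringsAsFactors = FALSE)
  }
  variants <- if (length(vars)) do.call(rbind, vars) else
    data.frame(codon_index = integer(0), coverage = integer(0),
               ref_codon = character(0), alt_codon = character(0),
               count = integer(0), aa_ref = character(0),
               aa_alt = character(0), type = character(0),
               stringsAsFactors = FALSE)
  syn <- sum(variants$count[variants$type == "synonymous"])
  nonsyn <- sum(variants$count[variants$type == "nonsynonymous"])
  structure(list(orf_id = pileup$orf_id, variants = variants,
                 syn_count = syn, nonsyn_count = nonsyn,
                 pn_fraction = if (syn + nonsyn == 0) NA_real_ else
                   nonsyn / (syn + nonsyn),
                 n_codons_covered = n_cov),
            class = "codon_variant_table")
}
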