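# Total length of the union of 0-based half-open intervals.
interval_union_length <- function(starts, ends) {
  if (!length(starts)) return(0L)
  sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(start = starts + 1L, end = ends))))
}

#' Whole-genome intergenomic similarity (VIRIDIC-style)
#'
#' Fragments the shorter genome into overlapping windows, places each window
#' on the other genome with the seed-and-extend aligner, and summarizes:
#' identity is the alignment-length-weighted mean over placed windows, the
#' aligned fraction of each genome is the union of aligned spans over its
#' length, and the intergenomic similarity is
#' `100 * identity * min(aligned_frac_a, aligned_frac_b)`.
#'
#' @param g1,g2 Genome objects or character sequences.
#' @param window_bp Fragment length (default 1000).
#' @param step_bp Fragment step (default 500).
#' @param k Seed k-mer size for window placement.
#' @return One-row data frame: `genome_a`, `genome_b`, `identity`,
#'   `aligned_frac_a`, `aligned_frac_b`, `intergenomic_sim` (percent).
#' @export
intergenomic_similarity <- function(g1, g2, window_bp = 1000, step_bp = 500,
                                    k = 15) {
  s1 <- genome_seq(g1); s2 <- genome_seq(g2)
  id1 <- genome_id_of(g1, "genome_a"); id2 <- genome_id_of(g2, "genome_b")
  if (nchar(s1) == 0 || nchar(s2) == 0) stop("empty genome sequence")
  swap <- nchar(s1) < nchar(s2)  # fragment the shorter genome
  qry <- if (swap) s1 else s2
  tgt <- if (swap) g2 else g1    # index reused when one was precomputed
  qlen <- nchar(qry); tlen <- nchar(genome_seq(tgt))
  win <- min(window_bp, qlen)
  starts <- unique(c(seq(0L, qlen - win, by = step_bp), qlen - win))
  frags <- substring(qry, starts + 1L, starts + win)
  h <- map_reads_to(frags, tgt, k)
  ok <- which(!is.na(h$g_start))
  if (!length(ok)) {
    out <- data.frame(genome_a = id1, genome_b = id2, identity = 0,
                      aligned_frac_a = 0, aligned_frac_b = 0,
                      intergenomic_sim = 0, stringsAsFactors = FALSE)
    return(out)
  }
  identity <- sum(h$matches[ok]) / sum(h$alen[ok])
  q_cov <- interval_union_length(starts[ok] + h$r_start[ok],
                                 starts[ok] + h$r_end[ok]) / qlen
  t_cov <- interval_union_length(h$g_start[ok], h$g_end[ok]) / tlen
  af1 <- if (swap) q_cov else t_cov
  af2 <- if (swap) t_cov else q_cov
  data.frame(genome_a = id1, genome_b = id2, identity = identity,
             aligned_frac_a = af1, aligned_frac_b = af2,
             intergenomic_sim = 100 * identity * min(af1, af2),
             stringsAsFactors = FALSE)
}

#' Pairwise intergenomic similarity matrix
#'
#' @param genomes Named list of genome objects or sequences.
#' @param ... Passed to [intergenomic_similarity()].
#' @return Symmetric percent-similarity matrix with 100 on the diagonal.
#' @export
similarity_matrix <- function(genomes, ...) {
  ids <- names(genomes)
  if (is.null(ids)) stop("genomes must be named")
  n <- length(ids)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n < 2) return(m)
  idx <- lapply(genomes, function(g)
    if (inherits(g, "ss_genome_index")) g else genome_index(g))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      s <- intergenomic_similarity(idx[[i]], idx[[j]], ...)
      m[i, j] <- m[j, i] <- s$intergenomic_sim
    }
  }
  m
}

#' Remove redundant genomes
#'
#' Drops genomes shorter than `min_len`, then greedily retains genomes
#' longest-first: a candidate is redundant when it aligns to an already
#' retained genome with overall identity at least `min_id` over at least
#' `min_aligned_frac` of its own length.
#'
#' @param genomes Named list of genome objects or sequences.
#' @param min_len Minimum genome length (default 43000; shorter genomes are
#'   dropped before clustering).
#' @param min_id Identity required to call redundancy (default 1.0).
#' @param min_aligned_frac Aligned fraction of the candidate required
#'   (default 0.8).
#' @param ... Passed to [intergenomic_similarity()].
#' @return The retained named list, longest first.
#' @export
dereplicate_genomes <- function(genomes, min_len = 43000, min_id = 1.0,
                                min_aligned_frac = 0.8, ...) {
  if (!length(genomes)) stop("empty genome set")
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, genome_id_of, character(1))
  lens <- vapply(genomes, function(g) nchar(genome_seq(g)), integer(1))
  genomes <- genomes[lens >= min_len]
  lens <- lens[lens >= min_len]
  ord <- order(-lens, names(genomes))
  genomes <- genomes[ord]
  retained <- list()
  for (id in names(genomes)) {
    redundant <- FALSE
    cand <- genome_index(genomes[[id]])
    for (rid in names(retained)) {
      s <- intergenomic_similarity(cand, retained[[rid]], ...)
      if (s$identity >= min_id && s$aligned_frac_a >= min_aligned_frac) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) retained[[id]] <- genomes[[id]]
  }
  retained
}

#' Assign genus and species from a similarity matrix
#'
#' ICTV-style operational clustering: genera are single-linkage connected
#' components at `genus_thr` or above; species are components, within each
#' genus, connected strictly above `species_thr`.
#'
#' @param sim Symmetric percent-similarity matrix (100 on the diagonal).
#' @param species_thr Species threshold (default 95, strict).
#' @param genus_thr Genus threshold (default 70, inclusive).
#' @return Data frame: `genome_id`, `genus`, `species`.
#' @export
assign_species_genus <- function(sim, species_thr = 95, genus_thr = 70) {
  if (!isTRUE(all.equal(sim, t(sim), tolerance = 1e-8)))
    stop("similarity matrix is not symmetric")
  ids <- sort(rownames(sim))  # canonical order: input-order invariant
  sim <- sim[ids, ids, drop = FALSE]
  comp_labels <- function(adj) {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    igraph::components(g)$membership
  }
  genus_m <- comp_labels(sim >= genus_thr)
  species_m <- comp_labels(sim > species_thr)
  # number clusters by first (sorted) member for determinism
  renum <- function(m) {
    first <- vapply(split(seq_along(m), m), min, integer(1))
    rank <- rank(first)
    as.integer(rank[as.character(m)])
  }
  genus_i <- renum(genus_m)
  # species are nested within genera by construction (thresholds nested)
  species_i <- renum(as.integer(factor(paste(genus_m, species_m))))
  data.frame(genome_id = ids,
             genus = sprintf("genus_%d", genus_i),
             species = sprintf("species_%d", species_i),
             stringsAsFactors = FALSE)
}

#' Predict open reading frames
#'
#' Finds maximal start-to-stop ORFs (ATG through stop, standard code) of at
#' least `min_len` nucleotides in all six frames, then keeps a
#' non-overlapping set by longest-first selection. Intervals are 0-based
#' half-open and include the stop codon.
#'
#' @param genome Genome object or character sequence.
#' @param min_len Minimum ORF length in nt, stop codon included
#'   (default 300).
#' @return Data frame: `start`, `end`, `strand`.
#' @export
predict_orfs <- function(genome, min_len = 300) {
  sq <- genome_seq(genome)
  len <- nchar(sq)
  scan_strand <- function(s, strand) {
    out <- list()
    n <- nchar(s)
    for (frame in 0:2) {
      n_codon <- (n - frame) %/% 3L
      if (n_codon < 2) next
      cod_start <- frame + 3L * (seq_len(n_codon) - 1L)
      codons <- substring(s, cod_start + 1L, cod_start + 3L)
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      is_atg <- codons == "ATG"
      prev_stop <- 0L  # codon index (1-based) of last stop seen
      for (ci in which(is_stop)) {
        cand <- which(is_atg[(prev_stop + 1L):(ci - 1L)])
        if (length(cand)) {
          a <- prev_stop + cand[1L]  # earliest ATG: maximal ORF
          o_start <- cod_start[a]
          o_end <- cod_start[ci] + 3L
          if (o_end - o_start >= min_len)
            out[[length(out) + 1L]] <- c(o_start, o_end)
        }
        prev_stop <- ci
      }
    }
    if (!length(out)) return(NULL)
    m <- do.call(rbind, out)
    if (strand == "-") m <- cbind(n - m[, 2], n - m[, 1])
    data.frame(start = m[, 1], end = m[, 2], strand = strand,
               stringsAsFactors = FALSE)
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
  orfs <- rbind(scan_strand(sq, "+"), scan_strand(rc, "-"))
  if (is.null(orfs) || nrow(orfs) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  orfs <- orfs[order(-(orfs$end - orfs$start), orfs$start), , drop = FALSE]
  keep <- logical(nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (orfs$start[i] < orfs$end[j] && orfs$start[j] < orfs$end[i]) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  orfs <- orfs[keep, , drop = FALSE]
  orfs <- orfs[order(orfs$start), , drop = FALSE]
  rownames(orfs) <- NULL
  orfs
}

#' Translate a genome's ORFs to proteins
#'
#' Extracts each ORF (reverse-complemented for '-' strand), translates with
#' the standard code, removes the terminal stop and truncates at the first
#' internal stop.
#'
#' @param genome Genome object (its `orfs` are used) or character sequence.
#' @param orfs Optional ORF data frame overriding the genome annotation.
#' @return Named character vector of protein sequences (may be empty).
#' @export
genome_proteins <- function(genome, orfs = NULL) {
  sq <- genome_seq(genome)
  if (is.null(orfs)) {
    orfs <- if (inherits(genome, "ss_genome")) genome$orfs else
      predict_orfs(genome)
  }
  if (is.null(orfs) || nrow(orfs) == 0) return(character(0))
  if (any((orfs$end - orfs$start) %% 3 != 0))
    stop("ORF length not divisible by 3")
  nt <- substring(sq, orfs$start + 1L, orfs$end)
  rev_idx <- orfs$strand == "-"
  if (any(rev_idx)) {
    nt[rev_idx] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(nt[rev_idx])))
  }
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAStringSet(nt),
                          if.fuzzy.codon = "solve")))
  aa <- sub("\\*.*$", "", aa)  # trim terminal stop and anything after one
  setNames(aa, sprintf("orf_%d_%d_%s", orfs$start, orfs$end, orfs$strand))
}

#' Average amino-acid identity over reciprocal best matches
#'
#' Compares all proteins of one genome against all of another (positional
#' identity over the aligned overlap, i.e. matches over the shorter
#' length -- no indels are modelled, mirroring the local-alignment
#' semantics of reciprocal-best-match AAI), keeps pairs that are mutual
#' best matches, and averages their identities. Proteins shorter than
#' `min_aa_len` are excluded: heavily truncated products (premature stops)
#' otherwise form spurious perfect-identity matches over a few residues,
#' the role the e-value floor plays in alignment-based AAI tools.
#'
#' @param proteins_a,proteins_b Character vectors of protein sequences.
#' @param min_aa_len Minimum protein length in residues (default 50).
#' @param min_identity Identity floor for a reciprocal pair to count as a
#'   match (default 0.3); unrelated protein sets therefore report a
#'   missing AAI rather than averaging random-background identities.
#' @return One-row data frame: `aai` (percent, `NA` when no reciprocal
#'   pair passes), `n_pairs`.
#' @export
pairwise_aai <- function(proteins_a, proteins_b, min_aa_len = 50,
                         min_identity = 0.3) {
  proteins_a <- proteins_a[nchar(proteins_a) >= max(1, min_aa_len)]
  proteins_b <- proteins_b[nchar(proteins_b) >= max(1, min_aa_len)]
  if (!length(proteins_a) || !length(proteins_b))
    stop("empty ORF set: translated proteins required on both sides")
  idm <- .cpp_protein_identity(unname(proteins_a), unname(proteins_b))
  best_for_a <- max.col(idm, ties.method = "first")
  best_for_b <- max.col(t(idm), ties.method = "first")
  mutual_a <- which(best_for_b[best_for_a] == seq_along(best_for_a))
  ident <- idm[cbind(mutual_a, best_for_a[mutual_a])]
  keep <- ident >= min_identity
  if (!any(keep))
    return(data.frame(aai = NA_real_, n_pairs = 0L))
  data.frame(aai = 100 * mean(ident[keep]), n_pairs = sum(keep))
}

#' AAI matrix over a set of genomes
#'
#' @param protein_sets Named list of protein vectors (see
#'   [genome_proteins()]).
#' @param min_aa_len Minimum protein length (see [pairwise_aai()]).
#' @return Symmetric percent-AAI matrix with 100 on the diagonal; `NA`
#'   where no reciprocal best-match pair exists.
#' @export
aai_matrix <- function(protein_sets, min_aa_len = 50) {
  ids <- names(protein_sets)
  n <- length(ids)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      m[i, j] <- m[j, i] <- pairwise_aai(protein_sets[[i]],
                                         protein_sets[[j]],
                                         min_aa_len = min_aa_len)$aai
    }
  }
  m
}

#' Cluster genomes of one species into groups and pick references
#'
#' Derives a dissimilarity from the pairwise AAI values (default
#' `1 - AAI/100`; alternatively Bray-Curtis over the rows of the AAI
#' matrix, treating each genome as its profile of AAI values), clusters by
#' average linkage, and cuts either at a requested group count, a requested
#' height, or (default) in the largest gap between consecutive merge
#' heights. Within each group the longest genome is flagged as the
#' reference (ties: fewest ambiguous bases, then lexicographically smallest
#' id).
#'
#' @param aai Symmetric AAI matrix (see [aai_matrix()]); missing entries
#'   are an error.
#' @param genomes Optional named list of genome objects/sequences used for
#'   reference selection; ids must cover the matrix rows.
#' @param n_groups Cut to exactly this many groups (optional).
#' @param cut_height Cut at this dissimilarity height (optional).
#' @param method Dissimilarity: `"aai"` (default) or `"bray_profile"`.
#' @return Data frame: `genome_id`, `group`, `is_reference`.
#' @export
cluster_intraspecies_groups <- function(aai, genomes = NULL,
                                        n_groups = NULL, cut_height = NULL,
                                        method = c("aai", "bray_profile")) {
  method <- match.arg(method)
  if (any(is.na(aai))) {
    bad <- which(is.na(aai), arr.ind = TRUE)[1, ]
    stop("missing AAI for pair ", rownames(aai)[bad[1]], " vs ",
         colnames(aai)[bad[2]])
  }
  ids <- rownames(aai)
  n <- length(ids)
  if (n == 1) {
    memb <- setNames(1L, ids)
  } else {
    d <- if (method == "bray_profile") vegan::vegdist(aai, method = "bray")
    else as.dist((100 - aai) / 100)
    hc <- hclust(d, method = "average")
    if (!is.null(n_groups)) {
      memb <- cutree(hc, k = n_groups)
    } else if (!is.null(cut_height)) {
      memb <- cutree(hc, h = cut_height)
    } else if (max(hc$height) < 1e-12) {
      memb <- setNames(rep(1L, n), ids)
    } else {
      gaps <- diff(c(0, sort(hc$height)))  # cut in the largest height gap
      memb <- cutree(hc, k = n - (which.max(gaps) - 1L))
    }
  }
  # stable group labels: by smallest member id
  first <- vapply(split(ids, memb), min, character(1))
  lab <- sprintf("group_%d", rank(first)[as.character(memb)])
  out <- data.frame(genome_id = ids, group = lab, is_reference = FALSE,
                    stringsAsFactors = FALSE)
  for (g in unique(out$group)) {
    members <- out$genome_id[out$group == g]
    if (!is.null(genomes)) {
      seqs <- vapply(genomes[members], genome_seq, character(1))
      len <- nchar(seqs)
      n_amb <- nchar(gsub("[ACGT]", "", seqs))
      ref <- members[order(-len, n_amb, members)][1]
    } else {
      ref <- sort(members)[1]
    }
    out$is_reference[out$genome_id == ref] <- TRUE
  }
  out[order(out$group, out$genome_id), ]
}
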