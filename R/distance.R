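#' Bottom-s MinHash sketch of a read set
#'
#' Counts canonical k-mers (the lexicographically smaller of a k-mer and
#' its reverse complement), discards those occurring fewer than `min_count`
#' times (sequencing-error artifacts), hashes the survivors with a fixed
#' 64-bit mixer (truncated to 53 bits so values are exact doubles), and
#' keeps the `s` smallest distinct hash values.
#'
#' @param reads Character vector of read (or genome) sequences.
#' @param k K-mer size (default 21).
#' @param s Sketch size (default 10000).
#' @param min_count Minimum k-mer multiplicity (default 2).
#' @return Object of class `ss_sketch`: `k`, `s`, `min_count`, `n_kept`
#'   (distinct k-mers passing the multiplicity filter), sorted `hashes`.
#' @export
minhash_sketch <- function(reads, k = 21, s = 10000, min_count = 2) {
  if (!length(reads)) stop("empty read set")
  if (max(nchar(reads)) < k)
    stop("k = ", k, " exceeds every read length")
  h <- .cpp_minhash(unname(reads), as.integer(k), as.integer(s),
                    as.integer(min_count))
  structure(list(k = as.integer(k), s = as.integer(s),
                 min_count = as.integer(min_count),
                 n_kept = length(h), hashes = h),
            class = "ss_sketch")
}

#' Mash distance between two sketches
#'
#' Estimates the Jaccard index from the bottom-s' sketch of the merged hash
#' sets (s' = min(s, available distinct hashes)) and converts it to a
#' distance `D = -(1/k) * ln(2j / (1 + j))`; an empty intersection is
#' reported as the capped distance 1.
#'
#' @param sk1,sk2 Sketches from [minhash_sketch()] with equal `k` and `s`.
#' @return List: `jaccard`, `distance`, `shared` (hashes shared in the
#'   merged bottom sketch), `s_used`.
#' @export
mash_distance <- function(sk1, sk2) {
  stopifnot(inherits(sk1, "ss_sketch"), inherits(sk2, "ss_sketch"))
  if (sk1$k != sk2$k) stop("sketches built with different k")
  if (sk1$s != sk2$s) stop("sketches built with different sketch size s")
  u <- sort(unique(c(sk1$hashes, sk2$hashes)))
  s_used <- min(sk1$s, length(u))
  bottom <- u[seq_len(s_used)]
  shared <- sum(bottom %in% sk1$hashes & bottom %in% sk2$hashes)
  j <- if (s_used > 0) shared / s_used else 0
  d <- if (j <= 0) 1 else max(0, -(1 / sk1$k) * log(2 * j / (1 + j)))
  list(jaccard = j, distance = d, shared = shared, s_used = s_used)
}

#' Pairwise Mash distance matrix
#'
#' @param sketches Named list of sketches.
#' @return Symmetric distance matrix with 0 on the diagonal.
#' @export
mash_distance_matrix <- function(sketches) {
  ids <- names(sketches)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      m[i, j] <- m[j, i] <- mash_distance(sketches[[i]],
                                          sketches[[j]])$distance
    }
  }
  m
}
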