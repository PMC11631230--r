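#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// 2-bit base encoding; -1 marks non-ACGT (treated as never matching)
static inline int encode_base(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::vector<int> encode_seq(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = encode_base(s[i]);
  return v;
}

static std::vector<int> revcomp_enc(const std::vector<int>& v) {
  std::vector<int> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int b = v[v.size() - 1 - i];
    r[i] = (b < 0) ? -1 : 3 - b;
  }
  return r;
}

// k-mer index of a genome: flat (packed k-mer, position) table sorted by
// k-mer value, with a 16-bit-prefix bucket table for O(1) lookups
struct KmerIndex {
  int k;
  int shift;  // kmer >> shift gives the bucket
  std::vector<int> genome;
  std::vector<std::pair<uint64_t, int> > tab;
  std::vector<int> bucket;  // size n_buckets + 1, offsets into tab
};

static void build_index(const std::string& genome, int k, KmerIndex& idx) {
  idx.k = k;
  idx.genome = encode_seq(genome);
  const std::vector<int>& g = idx.genome;
  int bucket_bits = std::min(16, 2 * k);
  idx.shift = 2 * k - bucket_bits;
  size_t nb = (size_t)1 << bucket_bits;
  idx.bucket.assign(nb + 1, 0);
  if ((int)g.size() < k) return;
  idx.tab.reserve(g.size());
  uint64_t kmer = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0;
  for (size_t i = 0; i < g.size(); ++i) {
    if (g[i] < 0) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)g[i]) & mask;
    if (++valid >= k)
      idx.tab.push_back(std::make_pair(kmer, (int)(i - k + 1)));
  }
  std::sort(idx.tab.begin(), idx.tab.end());
  for (size_t t = 0; t < idx.tab.size(); ++t)
    ++idx.bucket[(idx.tab[t].first >> idx.shift) + 1];
  for (size_t b = 1; b <= nb; ++b) idx.bucket[b] += idx.bucket[b - 1];
}

// Best ungapped local segment on one diagonal.
// Canonical optimum: maximal score; among ties the latest-starting,
// shortest segment (Kadane with reset on cur <= 0, update on strict >).
struct Seg { int score, r_start, r_end; bool found; };

static Seg diag_best(const std::vector<int>& read, const std::vector<int>& gen,
                     int diag) {
  // genome position = read position + diag
  int lo = std::max(0, -diag);
  int hi = std::min((int)read.size(), (int)gen.size() - diag);
  Seg best; best.found = false; best.score = 0; best.r_start = 0; best.r_end = 0;
  int cur = 0, start = lo;
  for (int r = lo; r < hi; ++r) {
    int s = (read[r] >= 0 && read[r] == gen[r + diag]) ? 1 : -1;
    cur += s;
    if (cur > best.score || !best.found) {
      if (cur > 0) { best.score = cur; best.r_start = start; best.r_end = r + 1; best.found = true; }
    }
    if (cur <= 0) { cur = 0; start = r + 1; }
  }
  return best;
}

// [[Rcpp::export(name = ".cpp_build_index")]]
SEXP cpp_build_index(std::string genome, int k) {
  KmerIndex* idx = new KmerIndex();
  build_index(genome, k, *idx);
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

static DataFrame map_reads_impl(CharacterVector reads, const KmerIndex& idx) {
  int n = reads.size();
  int k = idx.k;
  const std::vector<int>& g = idx.genome;
  IntegerVector g_start(n, NA_INTEGER), g_end(n, NA_INTEGER),
    r_start(n, NA_INTEGER), r_end(n, NA_INTEGER),
    matches(n, NA_INTEGER), alen(n, NA_INTEGER), score(n, NA_INTEGER);
  CharacterVector strand(n, NA_STRING);

  std::vector<int> diags;
  for (int i = 0; i < n; ++i) {
    std::string rs = as<std::string>(reads[i]);
    if ((int)rs.size() < k || idx.tab.empty()) continue;
    std::vector<int> enc = encode_seq(rs);
    int best_score = 0, best_gs = 0, best_len = 0, best_strand = -1,
      best_rs = 0;
    bool found = false;
    for (int st = 0; st < 2; ++st) {
      std::vector<int> rd = (st == 0) ? enc : revcomp_enc(enc);
      // collect candidate diagonals from exact k-mer seeds
      diags.clear();
      uint64_t kmer = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
      int valid = 0;
      for (size_t p = 0; p < rd.size(); ++p) {
        if (rd[p] < 0) { valid = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | (uint64_t)rd[p]) & mask;
        if (++valid >= k) {
          size_t b = kmer >> idx.shift;
          int roff = (int)p - k + 1;
          for (int t = idx.bucket[b]; t < idx.bucket[b + 1]; ++t)
            if (idx.tab[t].first == kmer)
              diags.push_back(idx.tab[t].second - roff);
        }
      }
      std::sort(diags.begin(), diags.end());
      diags.erase(std::unique(diags.begin(), diags.end()), diags.end());
      for (size_t d = 0; d < diags.size(); ++d) {
        Seg sg = diag_best(rd, g, diags[d]);
        if (!sg.found) continue;
        int gs = sg.r_start + diags[d];
        int len = sg.r_end - sg.r_start;
        // order: score desc, '+' before '-', genome start asc, shorter first
        bool better = false;
        if (!found) better = true;
        else if (sg.score != best_score) better = sg.score > best_score;
        else if (st != best_strand) better = st < best_strand;
        else if (gs != best_gs) better = gs < best_gs;
        else better = len < best_len;
        if (better) {
          found = true; best_score = sg.score; best_gs = gs;
          best_len = len; best_strand = st; best_rs = sg.r_start;
        }
      }
    }
    if (found) {
      g_start[i] = best_gs;
      g_end[i] = best_gs + best_len;
      // read coords are in the orientation that aligned forward to the
      // genome (reverse-complemented read for '-' hits)
      r_start[i] = best_rs;
      r_end[i] = best_rs + best_len;
      strand[i] = (best_strand == 0) ? "+" : "-";
      matches[i] = (best_score + best_len) / 2;
      alen[i] = best_len;
      score[i] = best_score;
    }
  }
  return DataFrame::create(_["g_start"] = g_start, _["g_end"] = g_end,
                           _["r_start"] = r_start, _["r_end"] = r_end,
                           _["strand"] = strand, _["matches"] = matches,
                           _["alen"] = alen, _["score"] = score,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export(name = ".cpp_map_reads_idx")]]
DataFrame cpp_map_reads_idx(CharacterVector reads, SEXP idx_ptr) {
  XPtr<KmerIndex> ptr(idx_ptr);
  return map_reads_impl(reads, *ptr);
}

// [[Rcpp::export(name = ".cpp_map_reads")]]
DataFrame cpp_map_reads(CharacterVector reads, std::string genome, int k) {
  KmerIndex idx;
  build_index(genome, k, idx);
  return map_reads_impl(reads, idx);
}

// Positional identity matrix between two protein sets: matches over the
// aligned overlap (the shorter length; no indels are modelled), the
// BLAST-local semantics used by reciprocal-best-match AAI.
// [[Rcpp::export(name = ".cpp_protein_identity")]]
NumericMatrix cpp_protein_identity(CharacterVector a, CharacterVector b) {
  int na = a.size(), nb = b.size();
  NumericMatrix out(na, nb);
  std::vector<std::string> as_(na), bs(nb);
  for (int i = 0; i < na; ++i) as_[i] = as<std::string>(a[i]);
  for (int j = 0; j < nb; ++j) bs[j] = as<std::string>(b[j]);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      size_t lmin = std::min(as_[i].size(), bs[j].size());
      if (lmin == 0) { out(i, j) = 0.0; continue; }
      size_t m = 0;
      for (size_t p = 0; p < lmin; ++p) if (as_[i][p] == bs[j][p]) ++m;
      out(i, j) = (double)m / (double)lmin;
    }
  }
  return out;
}

// splitmix64 finalizer, truncated to 53 bits so hashes are exact doubles
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  x = x ^ (x >> 31);
  return x & ((1ULL << 53) - 1);
}

static inline uint64_t revcomp_kmer(uint64_t kmer, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (kmer & 3ULL));
    kmer >>= 2;
  }
  return rc;
}

// Bottom-s MinHash sketch of canonical k-mers with a multiplicity floor.
// [[Rcpp::export(name = ".cpp_minhash")]]
NumericVector cpp_minhash(CharacterVector seqs, int k, int s, int min_count) {
  std::unordered_map<uint64_t, int> counts;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int i = 0; i < seqs.size(); ++i) {
    std::string sq = as<std::string>(seqs[i]);
    uint64_t kmer = 0;
    int valid = 0;
    for (size_t p = 0; p < sq.size(); ++p) {
      int b = encode_base(sq[p]);
      if (b < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        uint64_t canon = std::min(kmer, revcomp_kmer(kmer, k));
        ++counts[canon];
      }
    }
  }
  std::vector<double> hashes;
  hashes.reserve(counts.size());
  for (std::unordered_map<uint64_t, int>::const_iterator it = counts.begin();
       it != counts.end(); ++it)
    if (it->second >= min_count) hashes.push_back((double)mix64(it->first));
  if ((int)hashes.size() > s) {
    std::nth_element(hashes.begin(), hashes.begin() + s, hashes.end());
    hashes.resize(s);
  }
  std::sort(hashes.begin(), hashes.end());
  return NumericVector(hashes.begin(), hashes.end());
}

// TRUE for reads sharing at least one exact k-mer (either strand) with refs.
// [[Rcpp::export(name = ".cpp_kmer_match")]]
LogicalVector cpp_kmer_match(CharacterVector reads, CharacterVector refs, int k) {
  std::unordered_set<uint64_t> refset;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int i = 0; i < refs.size(); ++i) {
    std::string sq = as<std::string>(refs[i]);
    uint64_t kmer = 0; int valid = 0;
    for (size_t p = 0; p < sq.size(); ++p) {
      int b = encode_base(sq[p]);
      if (b < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)b) & mask;
      if (++valid >= k) refset.insert(kmer);
    }
  }
  int n = reads.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string sq = as<std::string>(reads[i]);
    bool hit = false;
    uint64_t kmer = 0; int valid = 0;
    for (size_t p = 0; p < sq.size() && !hit; ++p) {
      int b = encode_base(sq[p]);
      if (b < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        if (refset.count(kmer) || refset.count(revcomp_kmer(kmer, k))) hit = true;
      }
    }
    out[i] = hit;
  }
  return out;
}
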