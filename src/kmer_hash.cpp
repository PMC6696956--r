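#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_set>
#include <vector>

// Hashing for MinHash sketches of DNA sequences.
//
// Each canonical k-mer (lexicographic minimum of the k-mer and its reverse
// complement) is hashed with 64-bit FNV-1a seeded by a fixed sketch seed,
// then passed through the splitmix64 finaliser for avalanche. The result
// is truncated to its top 53 bits so every hash is exactly representable
// as an R double; ordering (and hence bottom-s sketches) is preserved.

static inline uint64_t splitmix64_fin(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 0;  // non-ACGT: k-mer is skipped
  }
}

// [[Rcpp::export(name = ".canonical_kmer_hashes")]]
Rcpp::NumericVector canonical_kmer_hashes(const std::string& seq, int k,
                                          double seed = 42) {
  if (k < 1) Rcpp::stop("k must be >= 1");
  const uint64_t seed64 = static_cast<uint64_t>(seed);
  const size_t n = seq.size();
  std::unordered_set<uint64_t> seen;
  std::string rc(k, 'N');
  if (n >= static_cast<size_t>(k)) {
    for (size_t i = 0; i + k <= n; ++i) {
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        char c = comp(seq[i + k - 1 - j]);
        if (!c) { ok = false; break; }
        rc[j] = c;
      }
      if (!ok) continue;
      // canonical strand: lexicographic min of forward k-mer and rc
      const char* fwd = seq.data() + i;
      bool use_fwd = std::lexicographical_compare(
          fwd, fwd + k, rc.data(), rc.data() + k) ||
          std::equal(fwd, fwd + k, rc.data());
      const char* kmer = use_fwd ? fwd : rc.data();
      uint64_t h = 14695981039346656037ULL ^ seed64;  // FNV offset basis
      for (int j = 0; j < k; ++j) {
        h ^= static_cast<uint64_t>(kmer[j]);
        h *= 1099511628211ULL;                        // FNV prime
      }
      seen.insert(splitmix64_fin(h) >> 11);           // top 53 bits
    }
  }
  Rcpp::NumericVector out(seen.size());
  size_t idx = 0;
  for (uint64_t v : seen) out[idx++] = static_cast<double>(v);
  return out;
}
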