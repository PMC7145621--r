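#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <cstdio>
#include <string>
#include <unordered_set>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// splitmix64 finalizer: avalanche so bottom-s selection sees uniform bits
static inline uint64_t mix64(uint64_t h) {
  h ^= h >> 30; h *= 0xBF58476D1CE4E5B9ULL;
  h ^= h >> 27; h *= 0x94D049BB133111EBULL;
  h ^= h >> 31;
  return h;
}

// FNV-1a over the k-mer bytes, seeded, then avalanched
static inline uint64_t hash_bytes(const char* s, int n, uint64_t seed) {
  uint64_t h = 1469598103934665603ULL ^ mix64(seed + 0x9E3779B97F4A7C15ULL);
  for (int i = 0; i < n; ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 1099511628211ULL;
  }
  return mix64(h);
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 0;  // N or anything else: window is skipped
  }
}

static std::string hex64(uint64_t v) {
  char buf[17];
  std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)v);
  return std::string(buf);
}

// Hash every valid canonical k-mer of each sequence and return the s
// smallest distinct hash values (as fixed-width lowercase hex, so that
// lexicographic order equals numeric order) plus the total number of
// distinct k-mer hashes observed.
// [[Rcpp::export(name = ".sketch_hashes")]]
List sketch_hashes(CharacterVector seqs, int k, int s, double seed) {
  if (k < 1) stop("k must be >= 1");
  if (s < 1) stop("s must be >= 1");
  uint64_t hseed = (uint64_t)seed;
  std::unordered_set<uint64_t> seen;
  std::vector<char> fwd(k), rev(k);
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    const char* p = CHAR(STRING_ELT(seqs, r));
    int n = (int)std::strlen(p);
    if (n < k) continue;
    for (int i = 0; i + k <= n; ++i) {
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        char c = p[i + j];
        char cc = comp_base(c);
        if (!cc) { ok = false; break; }
        fwd[j] = c;
        rev[k - 1 - j] = cc;
      }
      if (!ok) continue;
      const char* use = fwd.data();
      if (std::lexicographical_compare(rev.begin(), rev.end(),
                                       fwd.begin(), fwd.end()))
        use = rev.data();
      seen.insert(hash_bytes(use, k, hseed));
    }
  }
  std::vector<uint64_t> all(seen.begin(), seen.end());
  int keep = (int)std::min<size_t>((size_t)s, all.size());
  std::partial_sort(all.begin(), all.begin() + keep, all.end());
  CharacterVector out(keep);
  for (int i = 0; i < keep; ++i) out[i] = hex64(all[i]);
  return List::create(_["hashes"] = out,
                      _["total_kmers"] = (double)seen.size());
}

// Hash arbitrary strings with the sketch hash function.  Used to
// cross-check sketch content against brute-force k-mer enumeration.
// [[Rcpp::export(name = ".hash_strings")]]
CharacterVector hash_strings(CharacterVector x, double seed) {
  uint64_t hseed = (uint64_t)seed;
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const char* p = CHAR(STRING_ELT(x, i));
    out[i] = hex64(hash_bytes(p, (int)std::strlen(p), hseed));
  }
  return out;
}
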