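#pragma once
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  }
  return -1;
}

inline char bits2base(uint64_t b) { return "ACGT"[b & 3ULL]; }
inline char comp_base(char c) {
  int b = base2bits(c);
  return (b < 0) ? 'N' : "TGCA"[b];
}

inline uint64_t rc_kmer(uint64_t km, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; i++) { rc = (rc << 2) | (3ULL - (km & 3ULL)); km >>= 2; }
  return rc;
}

inline std::string rc_seq(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

inline std::string spell_kmer(uint64_t km, int k) {
  std::string s(k, 'N');
  for (int i = k - 1; i >= 0; i--) { s[i] = bits2base(km); km >>= 2; }
  return s;
}

// Enumerate valid k-mers of a string: calls fn(pos, fwd_kmer).
template <typename F>
inline void for_each_kmer(const std::string& s, int k, F fn) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t km = 0;
  int valid = 0;
  const int n = (int)s.size();
  for (int i = 0; i < n; i++) {
    int b = base2bits(s[i]);
    if (b < 0) { valid = 0; km = 0; continue; }
    km = ((km << 2) | (uint64_t)b) & mask;
    valid++;
    if (valid >= k) fn(i - k + 1, km);
  }
}
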