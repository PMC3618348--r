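#include "common.h"
#include <set>
#include <tuple>
#include <array>
using namespace Rcpp;

// Maximal reverse-complement self-match pairs of a (possibly circular)
// sequence: pairs of intervals [s1, s1+len) and [s2, s2+len) with
// seq[s1..] == revcomp(seq[s2..]). Seeded by exact shared k-mers between
// the sequence and its reverse complement, grouped on the anti-diagonal
// (s1 + s2 is invariant under co-extension), then extended maximally.
// Coordinates are 0-based on the original sequence (mod n for circular).
// [[Rcpp::export]]
IntegerMatrix cpp_revcomp_selfmatches(std::string seq, int k, int min_len,
                                      bool circular) {
  const int n = (int)seq.size();
  if (n < k) return IntegerMatrix(0, 3);
  std::string S = circular ? seq + seq : seq;
  const int ns = (int)S.size();
  std::unordered_map<uint64_t, std::vector<int>> fwd;
  for_each_kmer(S, k, [&](int pos, uint64_t km) {
    auto& v = fwd[km];
    if ((int)v.size() <= 32) v.push_back(pos);
  });
  std::string R = rc_seq(S);
  // group seed pairs by c = s1 + s2
  std::unordered_map<int64_t, std::vector<int>> groups;
  for_each_kmer(R, k, [&](int j, uint64_t km) {
    auto it = fwd.find(km);
    if (it == fwd.end()) return;
    int p = ns - k - j; // position on S of the rc partner window
    for (int i : it->second) {
      int64_t c = (int64_t)i + p;
      groups[c].push_back(i);
    }
  });
  std::vector<std::array<int64_t, 3>> pairs;
  std::set<std::tuple<int, int, int>> seen;
  for (auto& kv : groups) {
    int64_t c = kv.first;
    std::vector<int>& is = kv.second;
    std::sort(is.begin(), is.end());
    is.erase(std::unique(is.begin(), is.end()), is.end());
    size_t gi = 0;
    while (gi < is.size()) {
      size_t gj = gi;
      while (gj + 1 < is.size() && is[gj + 1] - is[gj] <= k) gj++;
      int imin = is[gi], imax = is[gj];
      int s1 = imin;
      int len = imax + k - imin;
      int s2 = (int)(c - imax);
      // extend left of s1 (pairs with right end of partner)
      while (s1 > 0 && s2 + len < ns && S[s1 - 1] == comp_base(S[s2 + len]) &&
             base2bits(S[s1 - 1]) >= 0) {
        s1--; len++;
      }
      // extend right of s1+len (pairs with left of s2)
      while (s1 + len < ns && s2 > 0 && S[s1 + len] == comp_base(S[s2 - 1]) &&
             base2bits(S[s1 + len]) >= 0) {
        s2--; len++;
      }
      gi = gj + 1;
      if (len < min_len) continue;
      if (circular && len > n) continue; // over-extension around the circle
      int a = s1 % n, b = s2 % n;
      int lo = std::min(a, b), hi = std::max(a, b);
      auto key = std::make_tuple(lo, hi, len);
      if (seen.count(key)) continue;
      seen.insert(key);
      pairs.push_back({lo, hi, len});
    }
  }
  std::sort(pairs.begin(), pairs.end(),
            [](const std::array<int64_t, 3>& x, const std::array<int64_t, 3>& y) {
              if (x[2] != y[2]) return x[2] > y[2];
              if (x[0] != y[0]) return x[0] < y[0];
              return x[1] < y[1];
            });
  IntegerMatrix out((int)pairs.size(), 3);
  for (int i = 0; i < (int)pairs.size(); i++) {
    out(i, 0) = (int)pairs[i][0];
    out(i, 1) = (int)pairs[i][1];
    out(i, 2) = (int)pairs[i][2];
  }
  colnames(out) = CharacterVector::create("start1", "start2", "len");
  return out;
}

// Shared unique k-mer anchors between two sequences (forward strand only):
// k-mers occurring exactly once in each. Consecutive same-diagonal anchors
// are merged into maximal segments. Returns (ref_start, query_start, len),
// 0-based.
// [[Rcpp::export]]
IntegerMatrix cpp_shared_unique_anchors(std::string ref, std::string qry, int k) {
  std::unordered_map<uint64_t, int64_t> rpos; // pos or -1 if repeated
  for_each_kmer(ref, k, [&](int pos, uint64_t km) {
    auto it = rpos.find(km);
    if (it == rpos.end()) rpos[km] = pos; else it->second = -1;
  });
  std::unordered_map<uint64_t, int64_t> qpos;
  for_each_kmer(qry, k, [&](int pos, uint64_t km) {
    auto it = qpos.find(km);
    if (it == qpos.end()) qpos[km] = pos; else it->second = -1;
  });
  std::vector<std::pair<int, int>> hits;
  for (auto& kv : qpos) {
    if (kv.second < 0) continue;
    auto it = rpos.find(kv.first);
    if (it == rpos.end() || it->second < 0) continue;
    hits.push_back({(int)it->second, (int)kv.second});
  }
  std::sort(hits.begin(), hits.end());
  std::vector<std::array<int, 3>> segs;
  for (auto& h : hits) {
    if (!segs.empty()) {
      auto& s = segs.back();
      int diag_prev = s[0] - s[1];
      int diag_cur = h.first - h.second;
      if (diag_cur == diag_prev && h.first <= s[0] + s[2]) {
        s[2] = std::max(s[2], h.first + k - s[0]);
        continue;
      }
    }
    segs.push_back({h.first, h.second, k});
  }
  IntegerMatrix out((int)segs.size(), 3);
  for (int i = 0; i < (int)segs.size(); i++) {
    out(i, 0) = segs[i][0];
    out(i, 1) = segs[i][1];
    out(i, 2) = segs[i][2];
  }
  colnames(out) = CharacterVector::create("ref_start", "query_start", "len");
  return out;
}
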