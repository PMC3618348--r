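#include "common.h"
using namespace Rcpp;

// Canonical-k-mer de Bruijn graph with unitig extraction, optional
// coverage-relative pruning of short weak unitigs (sequencing-error tips
// and bubble arms). K-mers are 2-bit packed into 128-bit words so the
// assembler supports the long k values (up to 63) that plastome k sweeps
// use.

typedef unsigned __int128 kmer_t;

struct KmerHash {
  size_t operator()(const kmer_t& x) const {
    uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
    uint64_t h = lo * 0x9E3779B97F4A7C15ULL ^ (hi + 0x9E3779B97F4A7C15ULL + (lo << 6));
    h ^= h >> 31;
    return (size_t)h;
  }
};

static inline kmer_t rc_kmer128(kmer_t km, int k) {
  kmer_t rc = 0;
  for (int i = 0; i < k; i++) { rc = (rc << 2) | (kmer_t)(3 - (int)(km & 3)); km >>= 2; }
  return rc;
}

typedef std::unordered_map<kmer_t, uint32_t, KmerHash> KmerMap;

struct Walker {
  int k;
  kmer_t mask;
  const KmerMap* cnt;
  bool has(kmer_t fwd) const {
    kmer_t canon = std::min(fwd, rc_kmer128(fwd, k));
    return cnt->count(canon) > 0;
  }
  int successors(kmer_t fwd, kmer_t* out) const {
    int n = 0;
    for (int x = 0; x < 4; x++) {
      kmer_t nx = ((fwd << 2) | (kmer_t)x) & mask;
      if (has(nx)) out[n++] = nx;
    }
    return n;
  }
  int predecessors(kmer_t fwd, kmer_t* out) const {
    int n = 0;
    for (int x = 0; x < 4; x++) {
      kmer_t pv = (fwd >> 2) | ((kmer_t)x << (2 * (k - 1)));
      if (has(pv)) out[n++] = pv;
    }
    return n;
  }
};

struct Unitig {
  std::string seq;
  double cov;
  std::vector<kmer_t> canon_kmers;
};

static void build_unitigs(const KmerMap& cnt, int k, std::vector<Unitig>& out) {
  out.clear();
  Walker w;
  w.k = k;
  w.mask = (((kmer_t)1) << (2 * k)) - 1;
  w.cnt = &cnt;
  std::unordered_set<kmer_t, KmerHash> visited;
  visited.reserve(cnt.size() * 2);

  // deterministic start order: sorted canonical k-mers
  std::vector<kmer_t> keys;
  keys.reserve(cnt.size());
  for (auto& kv : cnt) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());

  kmer_t succ[4], pred[4];
  for (kmer_t start : keys) {
    if (visited.count(start)) continue;
    visited.insert(start);
    Unitig u;
    u.canon_kmers.push_back(start);
    double covsum = cnt.at(start);

    // extend in both directions from the forward spelling of `start`
    std::string right, left_rc;
    for (int dir = 0; dir < 2; dir++) {
      kmer_t cur = (dir == 0) ? start : rc_kmer128(start, k);
      std::string& acc = (dir == 0) ? right : left_rc;
      while (true) {
        int ns = w.successors(cur, succ);
        if (ns != 1) break;
        kmer_t nxt = succ[0];
        if (w.predecessors(nxt, pred) != 1) break;
        kmer_t ncanon = std::min(nxt, rc_kmer128(nxt, k));
        if (visited.count(ncanon)) break; // branch seen, circular, or palindm
        visited.insert(ncanon);
        acc.push_back(bits2base((uint64_t)(nxt & 3)));
        u.canon_kmers.push_back(ncanon);
        covsum += cnt.at(ncanon);
        cur = nxt;
      }
    }
    std::string core(k, 'N');
    { kmer_t t = start;
      for (int i = k - 1; i >= 0; i--) { core[i] = bits2base((uint64_t)(t & 3)); t >>= 2; } }
    std::string left = rc_seq(left_rc);
    u.seq = left + core + right;
    u.cov = covsum / (double)u.canon_kmers.size();
    // canonical orientation for determinism
    std::string rc = rc_seq(u.seq);
    if (rc < u.seq) u.seq = rc;
    out.push_back(std::move(u));
  }
}

// weighted median of unitig coverages (weight = length), over unitigs with
// length >= min_len; falls back to all unitigs if none qualify
static double cov_median(const std::vector<Unitig>& us, int min_len) {
  std::vector<std::pair<double, double>> cw;
  for (auto& u : us)
    if ((int)u.seq.size() >= min_len) cw.push_back({u.cov, (double)u.seq.size()});
  if (cw.empty())
    for (auto& u : us) cw.push_back({u.cov, (double)u.seq.size()});
  if (cw.empty()) return 0.0;
  std::sort(cw.begin(), cw.end());
  double tot = 0;
  for (auto& p : cw) tot += p.second;
  double acc = 0;
  for (auto& p : cw) { acc += p.second; if (acc >= tot / 2) return p.first; }
  return cw.back().first;
}

// [[Rcpp::export]]
List cpp_debruijn(CharacterVector reads, int k, int min_count, bool prune,
                  int prune_rounds) {
  if (k < 3 || k > 63 || k % 2 == 0) stop("k must be odd and in [3, 63]");
  KmerMap cnt;
  const kmer_t mask = (((kmer_t)1) << (2 * k)) - 1;
  for (int i = 0; i < reads.size(); i++) {
    std::string s = as<std::string>(reads[i]);
    kmer_t km = 0;
    int valid = 0;
    const int nn = (int)s.size();
    for (int t = 0; t < nn; t++) {
      int b = base2bits(s[t]);
      if (b < 0) { valid = 0; km = 0; continue; }
      km = ((km << 2) | (kmer_t)b) & mask;
      valid++;
      if (valid >= k) {
        kmer_t canon = std::min(km, rc_kmer128(km, k));
        cnt[canon]++;
      }
    }
  }
  if (min_count > 1) {
    for (auto it = cnt.begin(); it != cnt.end();) {
      if ((int)it->second < min_count) it = cnt.erase(it); else ++it;
    }
  }
  std::vector<Unitig> us;
  build_unitigs(cnt, k, us);
  if (prune) {
    for (int round = 0; round < prune_rounds; round++) {
      double med = cov_median(us, 3 * k);
      // absolute floor handles round 1, where error arms still dominate the
      // unitig set and drag the median down
      double thr = std::max(2.5, 0.2 * med);
      bool removed = false;
      for (auto& u : us) {
        if ((int)u.seq.size() < 3 * k && u.cov < thr) {
          for (kmer_t km : u.canon_kmers) cnt.erase(km);
          removed = true;
        }
      }
      if (!removed) break;
      build_unitigs(cnt, k, us);
    }
  }
  // sort: longest first, then lexicographic
  std::sort(us.begin(), us.end(), [](const Unitig& a, const Unitig& b) {
    if (a.seq.size() != b.seq.size()) return a.seq.size() > b.seq.size();
    return a.seq < b.seq;
  });
  CharacterVector seqs(us.size());
  NumericVector covs(us.size());
  for (int i = 0; i < (int)us.size(); i++) {
    seqs[i] = us[i].seq;
    covs[i] = us[i].cov;
  }
  return List::create(_["seq"] = seqs, _["coverage"] = covs);
}
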