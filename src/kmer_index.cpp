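#include "common.h"
using namespace Rcpp;

// A k-mer index over a panel of reference sequences, keyed by canonical
// k-mer. Each posting records the reference, the position of the k-mer on
// the reference forward strand, and whether the canonical form equals the
// forward-strand k-mer at that position.
struct Posting {
  int32_t ref;
  int32_t pos;
  uint8_t canon_is_fwd;
};

struct PanelIndex {
  int k;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<Posting>> map;
};

// [[Rcpp::export]]
SEXP cpp_panel_build(CharacterVector seqs, int k) {
  if (k < 1 || k > 32) stop("k must be in [1, 32]");
  PanelIndex* idx = new PanelIndex();
  idx->k = k;
  idx->seqs.reserve(seqs.size());
  for (int r = 0; r < seqs.size(); r++) idx->seqs.push_back(as<std::string>(seqs[r]));
  for (int r = 0; r < (int)idx->seqs.size(); r++) {
    const std::string& s = idx->seqs[r];
    for_each_kmer(s, k, [&](int pos, uint64_t fwd) {
      uint64_t rc = rc_kmer(fwd, k);
      uint64_t canon = std::min(fwd, rc);
      Posting p;
      p.ref = r; p.pos = pos; p.canon_is_fwd = (canon == fwd) ? 1 : 0;
      idx->map[canon].push_back(p);
    });
  }
  XPtr<PanelIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
LogicalVector cpp_panel_has(SEXP idx_ptr, CharacterVector kmers) {
  XPtr<PanelIndex> idx(idx_ptr);
  LogicalVector out(kmers.size());
  for (int i = 0; i < kmers.size(); i++) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() != idx->k) { out[i] = false; continue; }
    bool ok = true;
    uint64_t fwd = 0;
    for (char c : s) {
      int b = base2bits(c);
      if (b < 0) { ok = false; break; }
      fwd = (fwd << 2) | (uint64_t)b;
    }
    if (!ok) { out[i] = false; continue; }
    uint64_t canon = std::min(fwd, rc_kmer(fwd, idx->k));
    out[i] = idx->map.count(canon) > 0;
  }
  return out;
}

// [[Rcpp::export]]
int cpp_panel_n_kmers(SEXP idx_ptr) {
  XPtr<PanelIndex> idx(idx_ptr);
  return (int)idx->map.size();
}

// Banded semi-global edit distance: `query` aligned globally, `segment`
// with free leading/trailing gaps. Band of +/- band around the diagonal.
static int banded_semiglobal(const std::string& q, const std::string& s, int band) {
  const int n = (int)q.size(), m = (int)s.size();
  if (n == 0) return 0;
  const int INF = 1 << 28;
  std::vector<int> prev(m + 1, 0), cur(m + 1, INF); // row 0: free start gap in segment
  for (int i = 1; i <= n; i++) {
    std::fill(cur.begin(), cur.end(), INF);
    int lo = std::max(1, i - band), hi = std::min(m, i + band + (m - n > 0 ? m - n : 0));
    for (int j = lo; j <= hi; j++) {
      int d = prev[j - 1] + (q[i - 1] == s[j - 1] ? 0 : 1);
      int up = (prev[j] == INF) ? INF : prev[j] + 1;
      int lf = (cur[j - 1] == INF) ? INF : cur[j - 1] + 1;
      cur[j] = std::min(d, std::min(up, lf));
    }
    if (i - band - 1 >= 0 && i - band - 1 <= m) cur[i - band - 1] = INF;
    std::swap(prev, cur);
  }
  int best = INF;
  for (int j = 0; j <= m; j++) best = std::min(best, prev[j]);
  return best;
}

// [[Rcpp::export]]
int cpp_banded_edit(std::string a, std::string b, int band) {
  return banded_semiglobal(a, b, band);
}

// Classify / locate queries against the panel.
// For each query: count distinct query k-mer positions hitting each
// reference; the best reference (ties by smallest priority[ref]) is the
// candidate; its modal diagonal gives a candidate locus; optional banded
// edit-distance verification against that locus.
// Returns 0-based candidate start position `pos` and strand (0 fwd, 1 rc).
// [[Rcpp::export]]
List cpp_classify(SEXP idx_ptr, CharacterVector queries, double min_hit_fraction,
                  int max_edit, IntegerVector priority, bool verify) {
  XPtr<PanelIndex> idx(idx_ptr);
  const int k = idx->k;
  const int nref = (int)idx->seqs.size();
  const int nq = queries.size();
  IntegerVector out_ref(nq), out_hits(nq), out_nk(nq), out_edit(nq), out_pos(nq), out_strand(nq);
  IntegerVector out_pos2(nq), out_strand2(nq);

  std::vector<int> refhits(nref, 0);
  std::vector<int> touched;
  std::unordered_map<int64_t, int> diag; // key: ref, type, diagonal
  std::vector<int> kmref; // refs hit by current kmer (dedupe)

  for (int qi = 0; qi < nq; qi++) {
    std::string q = as<std::string>(queries[qi]);
    const int L = (int)q.size();
    int nk = std::max(0, L - k + 1);
    touched.clear();
    diag.clear();
    int nkv = 0;
    for_each_kmer(q, k, [&](int pos, uint64_t fwd) {
      nkv++;
      uint64_t rc = rc_kmer(fwd, k);
      uint64_t canon = std::min(fwd, rc);
      bool q_canon_is_fwd = (canon == fwd);
      auto it = idx->map.find(canon);
      if (it == idx->map.end()) return;
      const std::vector<Posting>& ps = it->second;
      if (ps.size() > 200) return; // highly repetitive k-mer, uninformative
      kmref.clear();
      for (const Posting& p : ps) {
        bool same = (p.canon_is_fwd == (uint8_t)(q_canon_is_fwd ? 1 : 0));
        // same orientation -> query matches ref forward; else reverse
        int type = same ? 0 : 1;
        int64_t dg = same ? (int64_t)p.pos - pos : (int64_t)p.pos + pos;
        int64_t key = (((int64_t)p.ref * 2 + type) << 32) ^ (dg + (1LL << 31));
        diag[key]++;
        bool seen = false;
        for (int rr : kmref) if (rr == p.ref) { seen = true; break; }
        if (!seen) {
          kmref.push_back(p.ref);
          if (refhits[p.ref] == 0) touched.push_back(p.ref);
          refhits[p.ref]++;
        }
      }
    });
    (void)nkv;
    out_nk[qi] = nk;
    // pick best reference
    int best = -1, bh = 0;
    for (int r : touched) {
      if (refhits[r] > bh || (refhits[r] == bh && best >= 0 && priority[r] < priority[best])) {
        best = r; bh = refhits[r];
      }
    }
    int need = std::max(1, (int)std::ceil(min_hit_fraction * nk));
    if (best < 0 || bh < need) {
      out_ref[qi] = 0; out_hits[qi] = bh; out_edit[qi] = NA_INTEGER;
      out_pos[qi] = NA_INTEGER; out_strand[qi] = NA_INTEGER;
      out_pos2[qi] = NA_INTEGER; out_strand2[qi] = NA_INTEGER;
      for (int r : touched) refhits[r] = 0;
      continue;
    }
    // modal diagonal for best ref
    int64_t bestkey = -1; int bestdc = -1;
    for (auto& kv : diag) {
      int ref = (int)((kv.first >> 32) / 2);
      if (ref != best) continue;
      if (kv.second > bestdc) { bestdc = kv.second; bestkey = kv.first; }
    }
    int type = (int)((bestkey >> 32) % 2);
    int64_t dg = (bestkey & 0xffffffffLL) - (1LL << 31);
    // (packing via ^ is invertible for low 32 bits given key>>32 known)
    int start;
    if (type == 0) start = (int)dg;
    else start = (int)(dg - (L - k));
    // second-best candidate locus on the same reference, away from the
    // best one (used to resolve repeat copies such as the plastome IR)
    int start2 = NA_INTEGER, type2 = NA_INTEGER, dc2 = -1;
    for (auto& kv : diag) {
      int ref = (int)((kv.first >> 32) / 2);
      if (ref != best) continue;
      int ty = (int)((kv.first >> 32) % 2);
      int64_t d2 = (kv.first & 0xffffffffLL) - (1LL << 31);
      int st = (ty == 0) ? (int)d2 : (int)(d2 - (L - k));
      if (std::abs(st - start) <= L) continue;
      if (kv.second > dc2) { dc2 = kv.second; start2 = st; type2 = ty; }
    }
    int edit = NA_INTEGER;
    bool ok = true;
    if (verify) {
      const std::string& rs = idx->seqs[best];
      int s0 = std::max(0, start - max_edit);
      int s1 = std::min((int)rs.size(), start + L + max_edit);
      if (s1 <= s0) { ok = false; }
      else {
        std::string seg = rs.substr(s0, s1 - s0);
        std::string qq = (type == 0) ? q : rc_seq(q);
        edit = banded_semiglobal(qq, seg, std::max(max_edit, 2) + 2);
        if (edit > max_edit) ok = false;
      }
    }
    if (ok) {
      out_ref[qi] = best + 1; out_hits[qi] = bh; out_edit[qi] = edit;
      out_pos[qi] = start; out_strand[qi] = type;
      out_pos2[qi] = start2; out_strand2[qi] = type2;
    } else {
      out_ref[qi] = 0; out_hits[qi] = bh; out_edit[qi] = edit;
      out_pos[qi] = NA_INTEGER; out_strand[qi] = NA_INTEGER;
      out_pos2[qi] = NA_INTEGER; out_strand2[qi] = NA_INTEGER;
    }
    for (int r : touched) refhits[r] = 0;
  }
  return List::create(_["ref"] = out_ref, _["hits"] = out_hits, _["nk"] = out_nk,
                      _["edit"] = out_edit, _["pos"] = out_pos, _["strand"] = out_strand,
                      _["pos2"] = out_pos2, _["strand2"] = out_strand2);
}
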