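#include "common.h"
using namespace Rcpp;

// Best ungapped suffix(a)-prefix(b) overlap with identity >= min_id and
// length >= min_ov. Returns the overlap maximising matches (ties: longer).
// Contig ends produced by a substitution-dominated assembler are modelled
// without indels. Early abandoning keeps the scan near-linear.
// [[Rcpp::export]]
List cpp_best_overlap(std::string a, std::string b, int min_ov, double min_id) {
  const int na = (int)a.size(), nb = (int)b.size();
  const int maxL = std::min(na, nb);
  int best_len = 0, best_match = -1;
  for (int L = min_ov; L <= maxL; L++) {
    int allowed = (int)std::floor(L * (1.0 - min_id));
    int mm = 0;
    const char* pa = a.data() + (na - L);
    const char* pb = b.data();
    bool ok = true;
    for (int i = 0; i < L; i++) {
      if (pa[i] != pb[i]) {
        if (++mm > allowed) { ok = false; break; }
      }
    }
    if (ok) {
      int match = L - mm;
      if (match > best_match || (match == best_match && L > best_len)) {
        best_match = match;
        best_len = L;
      }
    }
  }
  return List::create(_["len"] = best_len,
                      _["matches"] = best_match < 0 ? 0 : best_match,
                      _["found"] = best_match >= 0);
}

// [[Rcpp::export]]
int cpp_hamming(std::string a, std::string b) {
  if (a.size() != b.size()) stop("length mismatch");
  int d = 0;
  for (size_t i = 0; i < a.size(); i++)
    if (a[i] != b[i]) d++;
  return d;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return rc_seq(s); }

// Apply point substitutions to a vector of sequences (1-based read index
// and position).
// [[Rcpp::export]]
CharacterVector cpp_apply_subs(CharacterVector seqs, IntegerVector read_idx,
                               IntegerVector pos, CharacterVector base) {
  std::vector<std::string> ss(seqs.size());
  for (int i = 0; i < seqs.size(); i++) ss[i] = as<std::string>(seqs[i]);
  for (int e = 0; e < read_idx.size(); e++) {
    int r = read_idx[e] - 1;
    int p = pos[e] - 1;
    if (r < 0 || r >= (int)ss.size() || p < 0 || p >= (int)ss[r].size())
      stop("substitution out of bounds");
    ss[r][p] = as<std::string>(base[e])[0];
  }
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); i++) out[i] = ss[i];
  return out;
}

// PHRED+offset encode/decode
// [[Rcpp::export]]
CharacterVector cpp_encode_phred(List quals, int offset) {
  CharacterVector out(quals.size());
  for (int i = 0; i < quals.size(); i++) {
    IntegerVector q = quals[i];
    std::string s(q.size(), ' ');
    for (int j = 0; j < q.size(); j++) s[j] = (char)(q[j] + offset);
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_encode_phred_mat(IntegerMatrix quals, int offset) {
  CharacterVector out(quals.nrow());
  std::string s(quals.ncol(), ' ');
  for (int i = 0; i < quals.nrow(); i++) {
    for (int j = 0; j < quals.ncol(); j++) s[j] = (char)(quals(i, j) + offset);
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_decode_phred(CharacterVector strs, int offset) {
  List out(strs.size());
  for (int i = 0; i < strs.size(); i++) {
    std::string s = as<std::string>(strs[i]);
    IntegerVector q(s.size());
    for (size_t j = 0; j < s.size(); j++) q[j] = (int)s[j] - offset;
    out[i] = q;
  }
  return out;
}
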