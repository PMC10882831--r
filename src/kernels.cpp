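#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Unanimity consensus over read families. Reads arrive sorted by family;
// every read in a family has the same length (the R side routes
// mixed-extent families elsewhere). The consensus equals the first read
// wherever all members agree and 'N' elsewhere; identical families share
// the first read's CHARSXP without copying.
// [[Rcpp::export]]
List cpp_unanimity_consensus(CharacterVector seqs, IntegerVector fam_first,
                             IntegerVector fam_size) {
  const int nf = fam_first.size();
  CharacterVector consensus(nf);
  IntegerVector n_masked(nf);
  std::string buf;
  for (int f = 0; f < nf; ++f) {
    const int first = fam_first[f] - 1;
    const int k = fam_size[f];
    SEXP s0 = seqs[first];
    const char *r0 = CHAR(s0);
    const R_xlen_t L = LENGTH(s0);
    bool same = true;
    for (int j = 1; j < k && same; ++j) {
      same = std::memcmp(r0, CHAR(seqs[first + j]), L) == 0;
    }
    if (same) {
      consensus[f] = s0;
      n_masked[f] = 0;
      continue;
    }
    buf.assign(r0, L);
    int masked = 0;
    for (int j = 1; j < k; ++j) {
      const char *rj = CHAR(seqs[first + j]);
      for (R_xlen_t i = 0; i < L; ++i) {
        if (rj[i] != r0[i] && buf[i] != 'N') {
          buf[i] = 'N';
          ++masked;
        }
      }
    }
    consensus[f] = buf;
    n_masked[f] = masked;
  }
  return List::create(_["consensus"] = consensus,
                      _["n_masked"] = n_masked);
}

// Positions where query[i] differs from ref[i] (strings of equal length
// pairwise). Returns 1-based row and within-string position plus the two
// bases, for assembly into a mismatch tibble.
// [[Rcpp::export]]
List cpp_mismatch_scan(CharacterVector query, CharacterVector ref) {
  const R_xlen_t n = query.size();
  std::vector<int> row, pos;
  std::string qb, rb;
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP qs = query[i], rs = ref[i];
    if (qs == rs) continue;
    const char *q = CHAR(qs), *r = CHAR(rs);
    const R_xlen_t L = LENGTH(qs);
    if (LENGTH(rs) != L) stop("query/ref length mismatch at row %d", (int)(i + 1));
    if (std::memcmp(q, r, L) == 0) continue;
    for (R_xlen_t p = 0; p < L; ++p) {
      if (q[p] != r[p]) {
        row.push_back(i + 1);
        pos.push_back(p + 1);
        qb.push_back(q[p]);
        rb.push_back(r[p]);
      }
    }
  }
  const int m = row.size();
  CharacterVector ref_base(m), alt_base(m);
  for (int i = 0; i < m; ++i) {
    ref_base[i] = std::string(1, rb[i]);
    alt_base[i] = std::string(1, qb[i]);
  }
  return List::create(_["row"] = wrap(row), _["pos"] = wrap(pos),
                      _["ref_base"] = ref_base, _["alt_base"] = alt_base);
}
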