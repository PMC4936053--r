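#include <Rcpp.h>
#include <climits>
#include <vector>
using namespace Rcpp;

// Affine-gap Smith-Waterman kernels used by the genome-relatedness module.
// Sequences arrive as 0-based integer codes; `sm` is the substitution matrix
// over that alphabet. Gap convention: the first gapped position costs
// `gap_open`, each further position `gap_extend` (both negative).

static const int NEG = INT_MIN / 4;

// Score-only pass: best local alignment score and its end coordinates.
// Memory O(m); used to locate the optimum before a windowed traceback.
// [[Rcpp::export(name = ".sw_best_end")]]
IntegerVector sw_best_end(IntegerVector q, IntegerVector t, IntegerMatrix sm,
                          int gap_open, int gap_extend) {
  const int m = q.size(), n = t.size(), k = sm.nrow();
  if (m == 0 || n == 0) return IntegerVector::create(0, 0, 0);
  // query profile: prof[c][i] = sm(q[i], c), contiguous per target symbol
  std::vector<int> prof((size_t)k * m);
  for (int c = 0; c < k; ++c)
    for (int i = 0; i < m; ++i) prof[(size_t)c * m + i] = sm(q[i], c);
  std::vector<int> H(m + 1, 0), E(m + 1, NEG);
  int best = 0, bq = 0, bt = 0;
  for (int j = 1; j <= n; ++j) {
    const int* p = &prof[(size_t)t[j - 1] * m];
    int diag = H[0];  // H[i-1][j-1]
    int F = NEG;      // gap consuming query, running down the column
    for (int i = 1; i <= m; ++i) {
      int e = E[i] + gap_extend;
      int eo = H[i] + gap_open;  // H[i][j-1]
      if (eo > e) e = eo;
      E[i] = e;
      int h = diag + p[i - 1];
      diag = H[i];
      if (e > h) h = e;
      if (F > h) h = F;
      if (h < 0) h = 0;
      H[i] = h;
      int fo = h + gap_open, fe = F + gap_extend;
      F = fo > fe ? fo : fe;
      if (h > best) { best = h; bq = i; bt = j; }
    }
  }
  return IntegerVector::create(best, bq, bt);
}

// Full DP with traceback on (small) inputs: returns score, 1-based alignment
// bounds in query and target, match count and alignment length (gap columns
// included).
// [[Rcpp::export(name = ".sw_traceback")]]
List sw_traceback(IntegerVector q, IntegerVector t, IntegerMatrix sm,
                  int gap_open, int gap_extend) {
  const int m = q.size(), n = t.size();
  if (m == 0 || n == 0)
    return List::create(_["score"] = 0, _["qstart"] = 0, _["qend"] = 0,
                        _["tstart"] = 0, _["tend"] = 0, _["matches"] = 0,
                        _["aln_len"] = 0);
  // state matrices: H plus direction bytes (0 stop, 1 diag, 2 from-E, 3 from-F)
  // and gap-extension flags for E and F
  std::vector<int> H((size_t)(m + 1) * (n + 1), 0),
      E((size_t)(m + 1) * (n + 1), NEG), F((size_t)(m + 1) * (n + 1), NEG);
  std::vector<unsigned char> dir((size_t)(m + 1) * (n + 1), 0),
      eext((size_t)(m + 1) * (n + 1), 0), fext((size_t)(m + 1) * (n + 1), 0);
  const size_t W = m + 1;
  int best = 0; size_t bi = 0, bj = 0;
  for (int j = 1; j <= n; ++j) {
    for (int i = 1; i <= m; ++i) {
      const size_t c = (size_t)j * W + i, left = c - W, up = c - 1;
      int e_open = H[left] + gap_open, e_ext = E[left] + gap_extend;
      E[c] = e_open >= e_ext ? e_open : e_ext;
      eext[c] = e_open >= e_ext ? 0 : 1;
      int f_open = H[up] + gap_open, f_ext = F[up] + gap_extend;
      F[c] = f_open >= f_ext ? f_open : f_ext;
      fext[c] = f_open >= f_ext ? 0 : 1;
      int h = H[left - 1] + sm(q[i - 1], t[j - 1]);
      unsigned char d = 1;
      if (E[c] > h) { h = E[c]; d = 2; }
      if (F[c] > h) { h = F[c]; d = 3; }
      if (h <= 0) { h = 0; d = 0; }
      H[c] = h; dir[c] = d;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  int matches = 0, aln_len = 0;
  size_t i = bi, j = bj;
  int qs = bi, ts = bj;
  int state = 0;  // 0 = in H, 2 = in E, 3 = in F
  while (i > 0 && j > 0) {
    const size_t c = j * W + i;
    if (state == 0) {
      unsigned char d = dir[c];
      if (d == 0) break;
      if (d == 1) {
        ++aln_len;
        if (q[i - 1] == t[j - 1]) ++matches;
        qs = i; ts = j; --i; --j;
      } else state = d;
    } else if (state == 2) {  // gap in query, consume target
      ++aln_len; ts = j;
      state = eext[c] ? 2 : 0;
      --j;
    } else {  // gap in target, consume query
      ++aln_len; qs = i;
      state = fext[c] ? 3 : 0;
      --i;
    }
  }
  return List::create(_["score"] = best, _["qstart"] = qs, _["qend"] = (int)bi,
                      _["tstart"] = ts, _["tend"] = (int)bj,
                      _["matches"] = matches, _["aln_len"] = aln_len);
}
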