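#include <Rcpp.h>
using namespace Rcpp;

// Global Needleman-Wunsch alignment of two alignment profiles with linear gap
// penalties. Profiles are 5 x L frequency matrices over {A,C,G,T,N}; the gap
// fraction of a column is 1 - colSums. Column-pair score:
//   match * m + mismatch * (fa*fb - m),
// where m = sum_{x in ACGT} pa[x]*pb[x] is the expected match mass and
// fa, fb are the non-gap fractions (N never matches, including N vs N).
// Ties are broken deterministically: diagonal, then gap-in-B, then gap-in-A.
//
// Returns 1-based column indices into each profile along the merged
// alignment, with 0 marking an inserted gap column.

// [[Rcpp::export]]
List nw_profile_path(NumericMatrix pa, NumericMatrix pb,
                     double match, double mismatch, double gap) {
  const int la = pa.ncol(), lb = pb.ncol();
  // contiguous copies: column-major 5 x L, plus per-column non-gap fractions
  std::vector<double> A(5 * (size_t)la), B(5 * (size_t)lb), fa(la), fb(lb);
  for (int i = 0; i < la; ++i) {
    double s = 0.0;
    for (int x = 0; x < 5; ++x) { A[5 * (size_t)i + x] = pa(x, i); s += pa(x, i); }
    fa[i] = s;
  }
  for (int j = 0; j < lb; ++j) {
    double s = 0.0;
    for (int x = 0; x < 5; ++x) { B[5 * (size_t)j + x] = pb(x, j); s += pb(x, j); }
    fb[j] = s;
  }
  // DP over rows, keep one row of scores plus full traceback (bytes).
  std::vector<double> prev(lb + 1), cur(lb + 1);
  std::vector<unsigned char> tb((la + 1) * (size_t)(lb + 1));
  // codes: 0 diag, 1 up (gap in B, consume A column), 2 left (gap in A)
  prev[0] = 0.0;
  for (int j = 1; j <= lb; ++j) {
    prev[j] = prev[j - 1] + gap;
    tb[j] = 2;
  }
  for (int i = 1; i <= la; ++i) {
    cur[0] = prev[0] + gap;
    tb[(size_t)i * (lb + 1)] = 1;
    const double *ac = &A[5 * (size_t)(i - 1)];
    const double fai = fa[i - 1];
    for (int j = 1; j <= lb; ++j) {
      const double *bc = &B[5 * (size_t)(j - 1)];
      double m = ac[0] * bc[0] + ac[1] * bc[1] + ac[2] * bc[2] + ac[3] * bc[3];
      double s = match * m + mismatch * (fai * fb[j - 1] - m);
      double sd = prev[j - 1] + s;
      double su = prev[j] + gap;
      double sl = cur[j - 1] + gap;
      unsigned char code = 0;
      double best = sd;
      if (su > best) { best = su; code = 1; }
      if (sl > best) { best = sl; code = 2; }
      cur[j] = best;
      tb[(size_t)i * (lb + 1) + j] = code;
    }
    std::swap(prev, cur);
  }
  // traceback
  std::vector<int> ai, bi;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    unsigned char code = tb[(size_t)i * (lb + 1) + j];
    if (i > 0 && j > 0 && code == 0) {
      ai.push_back(i); bi.push_back(j); --i; --j;
    } else if (i > 0 && (j == 0 || code == 1)) {
      ai.push_back(i); bi.push_back(0); --i;
    } else {
      ai.push_back(0); bi.push_back(j); --j;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["a"] = wrap(ai), _["b"] = wrap(bi));
}
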