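#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global alignment with affine gaps (Gotoh three-state recursion).
// Scoring: match +1, mismatch -1; a gap of length L costs 2 + (L - 1),
// i.e. the first gap residue scores -2 (open) and each further one -1
// (extend). Traceback is deterministic: ties prefer the diagonal state,
// then the vertical (gap in b), then the horizontal (gap in a); in the
// gap states, opening from M beats extending on ties.
//
// Returns the optimal score and the number of identical aligned columns
// of the traced-back optimal alignment.

// [[Rcpp::export]]
List align_global_affine(std::string a, std::string b) {
  const double MATCH = 1.0, MISMATCH = -1.0, OPEN = -2.0, EXT = -1.0;
  const double NEG = -1e18;
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence");

  const int W = m + 1;
  const size_t sz = (size_t)(n + 1) * W;
  // state 0 = M (diagonal), 1 = X (vertical, consumes a), 2 = Y (horizontal)
  std::vector<double> Mv(sz, NEG), Xv(sz, NEG), Yv(sz, NEG);
  std::vector<unsigned char> pM(sz, 0), pX(sz, 0), pY(sz, 0);
  double *Mp = Mv.data(), *Xp = Xv.data(), *Yp = Yv.data();
  unsigned char *pMp = pM.data(), *pXp = pX.data(), *pYp = pY.data();
  const char *ac = a.c_str(), *bc = b.c_str();

  Mp[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    Xp[(size_t)i * W] = OPEN + (i - 1) * EXT;
    pXp[(size_t)i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Yp[j] = OPEN + (j - 1) * EXT;
    pYp[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    const double *Md = Mp + (size_t)(i - 1) * W;   // row i-1
    const double *Xd = Xp + (size_t)(i - 1) * W;
    const double *Yd = Yp + (size_t)(i - 1) * W;
    double *Mi = Mp + (size_t)i * W;               // row i
    double *Xi = Xp + (size_t)i * W;
    double *Yi = Yp + (size_t)i * W;
    unsigned char *pMi = pMp + (size_t)i * W;
    unsigned char *pXi = pXp + (size_t)i * W;
    unsigned char *pYi = pYp + (size_t)i * W;
    const char ai = ac[i - 1];
    for (int j = 1; j <= m; ++j) {
      const double s = (ai == bc[j - 1]) ? MATCH : MISMATCH;
      // M: ties prefer M, then X, then Y
      double best = Md[j - 1];
      unsigned char ptr = 0;
      if (Xd[j - 1] > best) { best = Xd[j - 1]; ptr = 1; }
      if (Yd[j - 1] > best) { best = Yd[j - 1]; ptr = 2; }
      Mi[j] = best + s;
      pMi[j] = ptr;
      const double xo = Md[j] + OPEN, xe = Xd[j] + EXT;
      if (xo >= xe) { Xi[j] = xo; pXi[j] = 0; }
      else          { Xi[j] = xe; pXi[j] = 1; }
      const double yo = Mi[j - 1] + OPEN, ye = Yi[j - 1] + EXT;
      if (yo >= ye) { Yi[j] = yo; pYi[j] = 0; }
      else          { Yi[j] = ye; pYi[j] = 2; }
    }
  }

  const size_t end = (size_t)n * W + m;
  int state = 0;
  double score = Mp[end];
  if (Xp[end] > score) { score = Xp[end]; state = 1; }
  if (Yp[end] > score) { score = Yp[end]; state = 2; }

  int i = n, j = m, matches = 0, aligned_cols = 0;
  while (i > 0 || j > 0) {
    const size_t at = (size_t)i * W + j;
    if (state == 0) {
      unsigned char prev = pMp[at];
      if (ac[i - 1] == bc[j - 1]) ++matches;
      ++aligned_cols;
      --i; --j;
      state = prev;
    } else if (state == 1) {
      unsigned char prev = pXp[at];
      --i;
      state = prev;
    } else {
      unsigned char prev = pYp[at];
      --j;
      state = prev;
    }
  }

  return List::create(_["score"] = score,
                      _["matches"] = matches,
                      _["aligned_columns"] = aligned_cols);
}
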