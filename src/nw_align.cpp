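#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

// 4-bit base masks: A=1, C=2, G=4, T=8; ambiguity codes are unions.
static int iupac_mask(char c) {
  switch (toupper(c)) {
  case 'A': return 1;
  case 'C': return 2;
  case 'G': return 4;
  case 'T': case 'U': return 8;
  case 'R': return 1 | 4;
  case 'Y': return 2 | 8;
  case 'S': return 2 | 4;
  case 'W': return 1 | 8;
  case 'K': return 4 | 8;
  case 'M': return 1 | 2;
  case 'B': return 2 | 4 | 8;
  case 'D': return 1 | 4 | 8;
  case 'H': return 1 | 2 | 8;
  case 'V': return 1 | 2 | 4;
  case 'N': return 1 | 2 | 4 | 8;
  default: return 0;
  }
}

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh three-state
// recursion.  A gap of length L costs gap_open + L * gap_extend (both
// negative).  Two characters score `match` when their IUPAC base sets
// intersect, `mismatch` otherwise.  Traceback ties are broken in the fixed
// order: diagonal, gap-in-reference, gap-in-specimen.
// [[Rcpp::export]]
List nw_align_cpp(std::string ref, std::string spec,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int n = (int) ref.size();
  const int m = (int) spec.size();
  if (n == 0 || m == 0) stop("empty sequence");

  std::vector<int> rmask(n), smask(m);
  for (int i = 0; i < n; ++i) {
    rmask[i] = iupac_mask(ref[i]);
    if (rmask[i] == 0) stop("non-IUPAC character '%s' in reference",
                            std::string(1, ref[i]).c_str());
  }
  for (int j = 0; j < m; ++j) {
    smask[j] = iupac_mask(spec[j]);
    if (smask[j] == 0) stop("non-IUPAC character '%s' in specimen",
                            std::string(1, spec[j]).c_str());
  }

  const double NEG = -std::numeric_limits<double>::infinity();
  // State 0 = M (diagonal), 1 = X (specimen base vs gap in reference),
  // 2 = Y (reference base vs gap in specimen).
  const size_t sz = (size_t)(n + 1) * (size_t)(m + 1);
  std::vector<double> M(sz, NEG), X(sz, NEG), Y(sz, NEG);
  // Traceback: predecessor state for each cell of each matrix.
  std::vector<signed char> bM(sz, -1), bX(sz, -1), bY(sz, -1);
  auto at = [m](int i, int j) { return (size_t) i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) {
    X[at(0, j)] = gap_open + j * gap_extend;
    bX[at(0, j)] = 1;
  }
  bX[at(0, 1)] = 0;
  for (int i = 1; i <= n; ++i) {
    Y[at(i, 0)] = gap_open + i * gap_extend;
    bY[at(i, 0)] = 2;
  }
  bY[at(1, 0)] = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = at(i, j);
      // M: consume ref[i-1] and spec[j-1]
      {
        const size_t p = at(i - 1, j - 1);
        double s = (rmask[i - 1] & smask[j - 1]) ? match : mismatch;
        double best = M[p]; signed char arg = 0;
        if (X[p] > best) { best = X[p]; arg = 1; }
        if (Y[p] > best) { best = Y[p]; arg = 2; }
        if (best > NEG) { M[c] = best + s; bM[c] = arg; }
      }
      // X: consume spec[j-1] against a gap in the reference
      {
        const size_t p = at(i, j - 1);
        double open = gap_open + gap_extend, ext = gap_extend;
        double best = M[p] + open; signed char arg = 0;
        if (X[p] + ext > best) { best = X[p] + ext; arg = 1; }
        if (Y[p] + open > best) { best = Y[p] + open; arg = 2; }
        if (best > NEG) { X[c] = best; bX[c] = arg; }
      }
      // Y: consume ref[i-1] against a gap in the specimen
      {
        const size_t p = at(i - 1, j);
        double open = gap_open + gap_extend, ext = gap_extend;
        double best = M[p] + open; signed char arg = 0;
        if (X[p] + open > best) { best = X[p] + open; arg = 1; }
        if (Y[p] + ext > best) { best = Y[p] + ext; arg = 2; }
        if (best > NEG) { Y[c] = best; bY[c] = arg; }
      }
    }
  }

  const size_t end = at(n, m);
  double score = M[end]; int state = 0;
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  // Traceback
  std::string ar, as;
  ar.reserve(n + m); as.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    signed char prev;
    if (state == 0) {
      prev = bM[at(i, j)];
      ar.push_back(ref[i - 1]); as.push_back(spec[j - 1]);
      --i; --j;
    } else if (state == 1) {
      prev = bX[at(i, j)];
      ar.push_back('-'); as.push_back(spec[j - 1]);
      --j;
    } else {
      prev = bY[at(i, j)];
      ar.push_back(ref[i - 1]); as.push_back('-');
      --i;
    }
    state = prev;
  }
  std::reverse(ar.begin(), ar.end());
  std::reverse(as.begin(), as.end());

  return List::create(_["ref"] = ar, _["spec"] = as, _["score"] = score);
}
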