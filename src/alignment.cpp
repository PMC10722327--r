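#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap alignment kernels. Gap of length k costs gap_open + k * gap_extend
// (BLAST convention), so the first gap character costs gap_open + gap_extend.

// Local (Smith-Waterman) alignment of two integer-coded sequences against a
// substitution matrix. Ties between co-optimal end cells are broken by the
// earliest subject end, then the earliest query end; the traceback prefers the
// shortest alignment (restart at score 0) and resolves interior ties
// diagonal > gap-in-subject > gap-in-query, closing gaps as early as possible.
// [[Rcpp::export]]
List cpp_sw_align(IntegerVector q, IntegerVector s, NumericMatrix sub,
                  double gap_open, double gap_extend) {
  const int m = q.size(), n = s.size();
  const double NEG = -1e18, gi = gap_open + gap_extend;
  // state matrices, (m+1) x (n+1), flattened
  std::vector<double> M((m + 1) * (n + 1), NEG), Ix(M), Iy(M);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };
  for (int j = 0; j <= n; ++j) M[at(0, j)] = 0.0;
  for (int i = 0; i <= m; ++i) M[at(i, 0)] = 0.0;

  double best = 0.0;
  int bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double diag = std::max(std::max(M[at(i - 1, j - 1)], Ix[at(i - 1, j - 1)]),
                             Iy[at(i - 1, j - 1)]);
      if (diag < 0.0) diag = 0.0;  // local restart
      double sc = diag + sub(q[i - 1], s[j - 1]);
      M[at(i, j)] = sc;
      double ixo = M[at(i - 1, j)] - gi, ixe = Ix[at(i - 1, j)] - gap_extend;
      Ix[at(i, j)] = std::max(ixo, ixe);
      double iyo = M[at(i, j - 1)] - gi, iye = Iy[at(i, j - 1)] - gap_extend;
      Iy[at(i, j)] = std::max(iyo, iye);
      // local optimum must end on a residue pair (ending on a gap only lowers
      // the score); tie-break: min subject end j, then min query end i
      if (sc > best + 1e-12 ||
          (sc > best - 1e-12 && bi >= 0 && (j < bj || (j == bj && i < bi)))) {
        best = sc; bi = i; bj = j;
      }
    }
  }
  if (best <= 1e-12 || bi < 0) {
    return List::create(_["score"] = 0.0,
                        _["pairs"] = IntegerMatrix(0, 2),
                        _["align_len"] = 0);
  }
  // traceback from (bi, bj) in state M
  std::vector<int> qp, sp;
  int i = bi, j = bj, align_len = 0;
  int state = 0;  // 0 = M, 1 = Ix (gap in subject), 2 = Iy (gap in query)
  const double eps = 1e-9;
  while (true) {
    if (state == 0) {
      qp.push_back(i); sp.push_back(j); ++align_len;
      double v = M[at(i, j)] - sub(q[i - 1], s[j - 1]);
      --i; --j;
      if (v <= eps) break;  // local start (prefer shortest alignment)
      if (std::fabs(M[at(i, j)] - v) <= eps) state = 0;
      else if (std::fabs(Ix[at(i, j)] - v) <= eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++align_len;
      double v = Ix[at(i, j)];
      // prefer closing the gap (come from M) when tied
      if (std::fabs(M[at(i - 1, j)] - gi - v) <= eps) state = 0;
      --i;
    } else {
      ++align_len;
      double v = Iy[at(i, j)];
      if (std::fabs(M[at(i, j - 1)] - gi - v) <= eps) state = 0;
      --j;
    }
  }
  const int k = qp.size();
  IntegerMatrix pairs(k, 2);
  for (int t = 0; t < k; ++t) {  // reverse into ascending order
    pairs(t, 0) = qp[k - 1 - t];
    pairs(t, 1) = sp[k - 1 - t];
  }
  return List::create(_["score"] = best, _["pairs"] = pairs,
                      _["align_len"] = align_len);
}

// Global affine alignment over a precomputed column-pair score matrix S
// (m x n), used for profile-profile merging in progressive alignment.
// Terminal gaps are penalized. Returns the aligned path as a two-column
// matrix of 1-based indices with 0 marking a gap in that profile.
// [[Rcpp::export]]
IntegerMatrix cpp_global_affine(NumericMatrix S, double gap_open,
                                double gap_extend) {
  const int m = S.nrow(), n = S.ncol();
  const double NEG = -1e18, gi = gap_open + gap_extend;
  std::vector<double> M((m + 1) * (n + 1), NEG), Ix(M), Iy(M);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= m; ++i) Ix[at(i, 0)] = -(gap_open + i * gap_extend);
  for (int j = 1; j <= n; ++j) Iy[at(0, j)] = -(gap_open + j * gap_extend);
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double diag = std::max(std::max(M[at(i - 1, j - 1)], Ix[at(i - 1, j - 1)]),
                             Iy[at(i - 1, j - 1)]);
      M[at(i, j)] = diag + S(i - 1, j - 1);
      Ix[at(i, j)] = std::max(std::max(M[at(i - 1, j)], Iy[at(i - 1, j)]) - gi,
                              Ix[at(i - 1, j)] - gap_extend);
      Iy[at(i, j)] = std::max(std::max(M[at(i, j - 1)], Ix[at(i, j - 1)]) - gi,
                              Iy[at(i, j - 1)] - gap_extend);
    }
  }
  // traceback, preferring diagonal > gap-in-col-profile > gap-in-row-profile
  const double eps = 1e-9;
  int i = m, j = n, state;
  {
    double vm = M[at(m, n)], vx = Ix[at(m, n)], vy = Iy[at(m, n)];
    if (vm >= vx - eps && vm >= vy - eps) state = 0;
    else if (vx >= vy - eps) state = 1;
    else state = 2;
  }
  std::vector<int> pi, pj;
  while (i > 0 || j > 0) {
    if (state == 0 && i > 0 && j > 0) {
      pi.push_back(i); pj.push_back(j);
      double v = M[at(i, j)] - S(i - 1, j - 1);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (std::fabs(M[at(i, j)] - v) <= eps) state = 0;
      else if (std::fabs(Ix[at(i, j)] - v) <= eps) state = 1;
      else state = 2;
    } else if (state == 1 || (j == 0 && i > 0)) {
      pi.push_back(i); pj.push_back(0);
      double v = Ix[at(i, j)];
      if (std::fabs(M[at(i - 1, j)] - gi - v) <= eps) state = 0;
      else if (std::fabs(Iy[at(i - 1, j)] - gi - v) <= eps) state = 2;
      --i;
    } else {
      pi.push_back(0); pj.push_back(j);
      double v = Iy[at(i, j)];
      if (std::fabs(M[at(i, j - 1)] - gi - v) <= eps) state = 0;
      else if (std::fabs(Ix[at(i, j - 1)] - gi - v) <= eps) state = 1;
      --j;
    }
  }
  const int k = pi.size();
  IntegerMatrix path(k, 2);
  for (int t = 0; t < k; ++t) {
    path(t, 0) = pi[k - 1 - t];
    path(t, 1) = pj[k - 1 - t];
  }
  return path;
}
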