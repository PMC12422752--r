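#include <Rcpp.h>
#include <stack>
using namespace Rcpp;

// 8-connected component labelling of a logical matrix (flood fill).
// Returns an integer matrix with 0 for background and 1..n component labels.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::stack<std::pair<int, int>> st;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      st.push({i, j});
      lab(i, j) = next;
      while (!st.empty()) {
        auto [ci, cj] = st.top();
        st.pop();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              st.push({ni, nj});
            }
          }
        }
      }
    }
  }
  return lab;
}

// Banded dynamic time warping on a precomputed local-cost matrix.
//
// Recurrence: D(i,j) = d(i,j) + min(D(i-1,j), D(i,j-1), D(i-1,j-1)) with
// D(1,1) = d(1,1). Cells with |i * ny/nx - j| > band_halfwidth (1-based
// indices) are excluded (Sakoe-Chiba band centered on the resampled
// diagonal). Returns the cumulative cost at the far corner (Inf if the band
// disconnects the corners) and the backtracked optimal path.
// [[Rcpp::export]]
List dtw_band_cpp(NumericMatrix d, double band_halfwidth) {
  int nx = d.nrow(), ny = d.ncol();
  NumericMatrix D(nx, ny);
  std::fill(D.begin(), D.end(), R_PosInf);
  double slope = (double)ny / nx;
  auto inband = [&](int i, int j) {  // 0-based
    return std::abs((i + 1.0) * slope - (j + 1.0)) <= band_halfwidth;
  };
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) {
      if (!inband(i, j)) continue;
      if (i == 0 && j == 0) {
        D(0, 0) = d(0, 0);
        continue;
      }
      double best = R_PosInf;
      if (i > 0) best = std::min(best, D(i - 1, j));
      if (j > 0) best = std::min(best, D(i, j - 1));
      if (i > 0 && j > 0) best = std::min(best, D(i - 1, j - 1));
      if (R_FINITE(best)) D(i, j) = d(i, j) + best;
    }
  }
  double cost = D(nx - 1, ny - 1);
  List out = List::create(Named("cost") = cost,
                          Named("feasible") = R_FINITE(cost) != 0);
  if (!R_FINITE(cost)) return out;

  // backtrack
  std::vector<int> pi, pj;
  int i = nx - 1, j = ny - 1;
  pi.push_back(i + 1);
  pj.push_back(j + 1);
  while (i > 0 || j > 0) {
    double diag = (i > 0 && j > 0) ? D(i - 1, j - 1) : R_PosInf;
    double up = (i > 0) ? D(i - 1, j) : R_PosInf;
    double left = (j > 0) ? D(i, j - 1) : R_PosInf;
    if (diag <= up && diag <= left) {
      --i; --j;
    } else if (up <= left) {
      --i;
    } else {
      --j;
    }
    pi.push_back(i + 1);
    pj.push_back(j + 1);
  }
  int n = pi.size();
  IntegerMatrix path(n, 2);
  for (int k = 0; k < n; ++k) {
    path(k, 0) = pi[n - 1 - k];
    path(k, 1) = pj[n - 1 - k];
  }
  out["path"] = path;
  return out;
}

// Cosine frame-distance matrix between the columns of two non-negative
// spectrogram matrices (same number of rows). All-zero columns get distance
// 1 to everything.
// [[Rcpp::export]]
NumericMatrix cosine_frame_dist_cpp(NumericMatrix x, NumericMatrix y) {
  int nb = x.nrow(), nx = x.ncol(), ny = y.ncol();
  NumericVector xn(nx), yn(ny);
  for (int i = 0; i < nx; ++i) {
    double s = 0;
    for (int b = 0; b < nb; ++b) s += x(b, i) * x(b, i);
    xn[i] = std::sqrt(s);
  }
  for (int j = 0; j < ny; ++j) {
    double s = 0;
    for (int b = 0; b < nb; ++b) s += y(b, j) * y(b, j);
    yn[j] = std::sqrt(s);
  }
  NumericMatrix d(nx, ny);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (xn[i] == 0 || yn[j] == 0) {
        d(i, j) = 1.0;
        continue;
      }
      double dot = 0;
      for (int b = 0; b < nb; ++b) dot += x(b, i) * y(b, j);
      double c = 1.0 - dot / (xn[i] * yn[j]);
      if (c < 0) c = 0;
      if (c > 2) c = 2;
      d(i, j) = c;
    }
  }
  return d;
}
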