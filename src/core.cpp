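#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pixel-wise lower median across the third dimension of an h x w x n array.
// Lower median = order statistic ceil(n/2), so output values are always drawn
// from observed intensities (no interpolation on even stacks).
// [[Rcpp::export]]
NumericMatrix cpp_stack_median(NumericVector arr) {
  IntegerVector dims = arr.attr("dim");
  const R_xlen_t h = dims[0], w = dims[1], n = dims[2];
  NumericMatrix out((int)h, (int)w);
  std::vector<double> buf((size_t)n);
  const R_xlen_t k = (n + 1) / 2 - 1; // 0-based lower median
  const R_xlen_t plane = h * w;
  for (R_xlen_t j = 0; j < w; ++j) {
    for (R_xlen_t i = 0; i < h; ++i) {
      const R_xlen_t base = i + h * j;
      for (R_xlen_t t = 0; t < n; ++t) buf[(size_t)t] = arr[base + plane * t];
      std::nth_element(buf.begin(), buf.begin() + k, buf.end());
      out(i, j) = buf[(size_t)k];
    }
  }
  return out;
}

// Sobel gradient magnitude, normalised so a unit intensity step has magnitude
// ~1. Border pixels use edge replication.
// [[Rcpp::export]]
NumericMatrix cpp_gradient_magnitude(NumericMatrix img) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix mag(h, w);
  auto at = [&](int i, int j) -> double {
    if (i < 0) i = 0; if (i >= h) i = h - 1;
    if (j < 0) j = 0; if (j >= w) j = w - 1;
    return img(i, j);
  };
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      double gx = -at(i - 1, j - 1) + at(i - 1, j + 1)
                  - 2.0 * at(i, j - 1) + 2.0 * at(i, j + 1)
                  - at(i + 1, j - 1) + at(i + 1, j + 1);
      double gy = -at(i - 1, j - 1) - 2.0 * at(i - 1, j) - at(i - 1, j + 1)
                  + at(i + 1, j - 1) + 2.0 * at(i + 1, j) + at(i + 1, j + 1);
      mag(i, j) = std::sqrt(gx * gx + gy * gy) / 4.0;
    }
  }
  return mag;
}

// Standard normal-form Hough accumulator: rho = x*cos(theta) + y*sin(theta)
// with x = column, y = row, both 0-based. rho bin = round(rho/rho_res) +
// nrho_half; theta bin t covers theta = t * theta_res.
// [[Rcpp::export]]
IntegerMatrix cpp_hough_accumulate(IntegerVector rows0, IntegerVector cols0,
                                   int nrho_half, double rho_res,
                                   int ntheta, double theta_res) {
  const int nrho = 2 * nrho_half + 1;
  IntegerMatrix acc(nrho, ntheta);
  const R_xlen_t npt = rows0.size();
  std::vector<double> ct((size_t)ntheta), st((size_t)ntheta);
  for (int t = 0; t < ntheta; ++t) {
    ct[(size_t)t] = std::cos(t * theta_res);
    st[(size_t)t] = std::sin(t * theta_res);
  }
  for (R_xlen_t p = 0; p < npt; ++p) {
    const double y = rows0[p], x = cols0[p];
    for (int t = 0; t < ntheta; ++t) {
      double rho = x * ct[(size_t)t] + y * st[(size_t)t];
      int idx = (int)std::lround(rho / rho_res) + nrho_half;
      if (idx >= 0 && idx < nrho) acc(idx, t)++;
    }
  }
  return acc;
}

// Connected-component labelling (connectivity 4 or 8), labels assigned in
// raster-scan order of each component's first pixel; deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  const int di8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int di4[4] = {-1, 0, 0, 1};
  const int dj4[4] = {0, -1, 1, 0};
  const int nn = (connectivity == 8) ? 8 : 4;
  const int *di = (connectivity == 8) ? di8 : di4;
  const int *dj = (connectivity == 8) ? dj8 : dj4;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i + h * j);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % h, cj = idx / h;
        for (int q = 0; q < nn; ++q) {
          int ni = ci + di[q], nj = cj + dj[q];
          if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + h * nj);
          }
        }
      }
    }
  }
  return lab;
}

static inline int nb_count(const std::vector<unsigned char> &m, int h, int i, int j, int w) {
  (void)w;
  int s = 0;
  for (int dj = -1; dj <= 1; ++dj)
    for (int di = -1; di <= 1; ++di)
      if (di || dj) s += m[(size_t)(i + di) + (size_t)h * (size_t)(j + dj)];
  return s;
}

// number of 0->1 transitions in the ordered ring p2,p3,...,p9,p2
static inline int transitions(const std::vector<unsigned char> &m, int h, int i, int j) {
  unsigned char p[8];
  p[0] = m[(size_t)(i - 1) + (size_t)h * (size_t)j];       // N
  p[1] = m[(size_t)(i - 1) + (size_t)h * (size_t)(j + 1)]; // NE
  p[2] = m[(size_t)i + (size_t)h * (size_t)(j + 1)];       // E
  p[3] = m[(size_t)(i + 1) + (size_t)h * (size_t)(j + 1)]; // SE
  p[4] = m[(size_t)(i + 1) + (size_t)h * (size_t)j];       // S
  p[5] = m[(size_t)(i + 1) + (size_t)h * (size_t)(j - 1)]; // SW
  p[6] = m[(size_t)i + (size_t)h * (size_t)(j - 1)];       // W
  p[7] = m[(size_t)(i - 1) + (size_t)h * (size_t)(j - 1)]; // NW
  int a = 0;
  for (int q = 0; q < 8; ++q) a += (p[q] == 0 && p[(q + 1) % 8] == 1);
  return a;
}

// Zhang-Suen topology-preserving thinning to an 8-connected medial axis,
// followed by a deterministic cleanup pass that removes redundant pixels of
// full 2x2 blocks (keeps the skeleton at most 1 px wide).
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix input) {
  const int h0 = input.nrow(), w0 = input.ncol();
  const int h = h0 + 2, w = w0 + 2; // zero padding
  std::vector<unsigned char> m((size_t)h * (size_t)w, 0);
  for (int j = 0; j < w0; ++j)
    for (int i = 0; i < h0; ++i)
      m[(size_t)(i + 1) + (size_t)h * (size_t)(j + 1)] = input(i, j) ? 1 : 0;

  std::vector<int> del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      del.clear();
      for (int j = 1; j < w - 1; ++j) {
        for (int i = 1; i < h - 1; ++i) {
          if (!m[(size_t)i + (size_t)h * (size_t)j]) continue;
          int B = nb_count(m, h, i, j, w);
          if (B < 2 || B > 6) continue;
          if (transitions(m, h, i, j) != 1) continue;
          unsigned char p2 = m[(size_t)(i - 1) + (size_t)h * (size_t)j];
          unsigned char p4 = m[(size_t)i + (size_t)h * (size_t)(j + 1)];
          unsigned char p6 = m[(size_t)(i + 1) + (size_t)h * (size_t)j];
          unsigned char p8 = m[(size_t)i + (size_t)h * (size_t)(j - 1)];
          bool ok = (sub == 0) ? (!(p2 && p4 && p6) && !(p4 && p6 && p8))
                               : (!(p2 && p4 && p8) && !(p2 && p6 && p8));
          if (ok) del.push_back(i + h * j);
        }
      }
      if (!del.empty()) {
        changed = true;
        for (size_t q = 0; q < del.size(); ++q) m[(size_t)del[q]] = 0;
      }
    }
  }

  // cleanup: iteratively remove redundant pixels (staircase corners, 2x2
  // block remnants) whose foreground neighbours form a single mutually
  // 8-connected group -- removal then provably preserves connectivity, while
  // pixels inside straight runs (two separated neighbour groups) are kept.
  // Sequential raster order keeps the result deterministic.
  bool again = true;
  while (again) {
    again = false;
    for (int j = 1; j < w - 1; ++j) {
      for (int i = 1; i < h - 1; ++i) {
        if (!m[(size_t)i + (size_t)h * (size_t)j]) continue;
        int di_[8], dj_[8], n = 0;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj) continue;
            if (m[(size_t)(i + di) + (size_t)h * (size_t)(j + dj)]) {
              di_[n] = di; dj_[n] = dj; ++n;
            }
          }
        if (n < 2 || n > 6) continue;
        // connected components of the neighbour set under 8-adjacency
        int comp[8];
        for (int q = 0; q < n; ++q) comp[q] = q;
        for (int a = 0; a < n; ++a)
          for (int b = a + 1; b < n; ++b)
            if (std::abs(di_[a] - di_[b]) <= 1 && std::abs(dj_[a] - dj_[b]) <= 1) {
              int ca = comp[a], cb = comp[b];
              if (ca != cb)
                for (int q = 0; q < n; ++q) if (comp[q] == cb) comp[q] = ca;
            }
        int ncomp = 0;
        for (int q = 0; q < n; ++q) if (comp[q] == q) ++ncomp;
        if (ncomp == 1) {
          m[(size_t)i + (size_t)h * (size_t)j] = 0;
          again = true;
        }
      }
    }
  }

  LogicalMatrix out(h0, w0);
  for (int j = 0; j < w0; ++j)
    for (int i = 0; i < h0; ++i)
      out(i, j) = m[(size_t)(i + 1) + (size_t)h * (size_t)(j + 1)] != 0;
  return out;
}

// Distance field (over an h x w grid of pixel centers, 0-based coordinates)
// to a dense sample of curve points; distances beyond rmax stay at +Inf.
// [[Rcpp::export]]
NumericMatrix cpp_dist_to_points(int h, int w, NumericVector pr, NumericVector pc,
                                 double rmax) {
  NumericMatrix dist(h, w);
  std::fill(dist.begin(), dist.end(), R_PosInf);
  const R_xlen_t n = pr.size();
  for (R_xlen_t p = 0; p < n; ++p) {
    const double y = pr[p], x = pc[p];
    const int i0 = std::max(0, (int)std::ceil(y - rmax));
    const int i1 = std::min(h - 1, (int)std::floor(y + rmax));
    const int j0 = std::max(0, (int)std::ceil(x - rmax));
    const int j1 = std::min(w - 1, (int)std::floor(x + rmax));
    for (int j = j0; j <= j1; ++j) {
      const double dx = j - x;
      for (int i = i0; i <= i1; ++i) {
        const double dy = i - y;
        const double d = std::sqrt(dx * dx + dy * dy);
        if (d < dist(i, j)) dist(i, j) = d;
      }
    }
  }
  return dist;
}
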