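#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Neighborhood rank filters (grayscale erosion, dilation, median) over an
// arbitrary offset set, for 2D matrices or 3D arrays. Out-of-image neighbors
// are resolved by symmetric reflection (edge pixel repeated), the package's
// border policy for all neighborhood operators.

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : period - 1 - i;
}

enum FilterOp { OP_MIN = 0, OP_MAX = 1, OP_MEDIAN = 2 };

// img: numeric vector in R array order; dim: c(nx, ny) or c(nx, ny, nz);
// offsets: k x 3 integer matrix of (dx, dy, dz) displacements.
// [[Rcpp::export]]
NumericVector cpp_rank_filter(NumericVector img, IntegerVector dim,
                              IntegerMatrix offsets, int op) {
  const int nx = dim[0];
  const int ny = dim[1];
  const int nz = (dim.size() > 2) ? dim[2] : 1;
  const int k = offsets.nrow();
  if (k == 0) stop("empty structuring element");

  NumericVector out(img.size());
  const double *in = REAL(img);
  double *o = REAL(out);
  std::vector<int> dx(k), dy(k), dz(k);
  std::vector<R_xlen_t> dlin(k);
  int mx = 0, my = 0, mz = 0;
  for (int j = 0; j < k; ++j) {
    dx[j] = offsets(j, 0);
    dy[j] = offsets(j, 1);
    dz[j] = (offsets.ncol() > 2) ? offsets(j, 2) : 0;
    dlin[j] = dx[j] + (R_xlen_t)nx * (dy[j] + (R_xlen_t)ny * dz[j]);
    mx = std::max(mx, std::abs(dx[j]));
    my = std::max(my, std::abs(dy[j]));
    mz = std::max(mz, std::abs(dz[j]));
  }
  std::vector<double> buf(k);

  const bool interior_exists = (2 * mx < nx) && (2 * my < ny) && (2 * mz < nz);
  for (int z = 0; z < nz; ++z) {
    const bool zi = interior_exists && z >= mz && z < nz - mz;
    for (int y = 0; y < ny; ++y) {
      const bool yi = zi && y >= my && y < ny - my;
      const R_xlen_t row = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      int x = 0;
      if (yi) {
        // interior: offsets resolve to fixed linear strides, no reflection
        for (x = mx; x < nx - mx; ++x) {
          const R_xlen_t p = x + row;
          if (op == OP_MIN) {
            double acc = R_PosInf;
            for (int j = 0; j < k; ++j) {
              const double v = in[p + dlin[j]];
              if (v < acc) acc = v;
            }
            o[p] = acc;
          } else if (op == OP_MAX) {
            double acc = R_NegInf;
            for (int j = 0; j < k; ++j) {
              const double v = in[p + dlin[j]];
              if (v > acc) acc = v;
            }
            o[p] = acc;
          } else {
            for (int j = 0; j < k; ++j) buf[j] = in[p + dlin[j]];
            std::nth_element(buf.begin(), buf.begin() + k / 2, buf.end());
            double acc = buf[k / 2];
            if (k % 2 == 0) {
              acc = 0.5 * (acc + *std::max_element(buf.begin(),
                                                   buf.begin() + k / 2));
            }
            o[p] = acc;
          }
        }
      }
      // border (and whole row when no interior): reflected indexing
      for (int xb = 0; xb < nx; ++xb) {
        if (yi && xb >= mx && xb < nx - mx) continue;
        double acc = 0.0;
        if (op == OP_MIN) acc = R_PosInf;
        if (op == OP_MAX) acc = R_NegInf;
        for (int j = 0; j < k; ++j) {
          const int xx = reflect_idx(xb + dx[j], nx);
          const int yy = reflect_idx(y + dy[j], ny);
          const int zz = reflect_idx(z + dz[j], nz);
          const double v = in[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
          if (op == OP_MIN) {
            if (v < acc) acc = v;
          } else if (op == OP_MAX) {
            if (v > acc) acc = v;
          } else {
            buf[j] = v;
          }
        }
        if (op == OP_MEDIAN) {
          std::sort(buf.begin(), buf.end());
          acc = (k % 2 == 1) ? buf[k / 2]
                             : 0.5 * (buf[k / 2 - 1] + buf[k / 2]);
        }
        o[xb + row] = acc;
      }
    }
  }
  return out;
}

// Connected-component labeling of a logical mask (2D or 3D) under the given
// neighbor offset set (e.g. 8-connectivity in 2D, 26 in 3D). Labels are
// assigned in raster-scan order of each component's first pixel, so the
// result is deterministic. No reflection: neighbors outside the image are
// ignored.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   IntegerMatrix offsets) {
  const int nx = dim[0];
  const int ny = dim[1];
  const int nz = (dim.size() > 2) ? dim[2] : 1;
  const int k = offsets.nrow();
  const R_xlen_t n = mask.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    labels[start] = next_label;
    stack.push_back(start);
    while (!stack.empty()) {
      const R_xlen_t p = stack.back();
      stack.pop_back();
      const int z = (int)(p / ((R_xlen_t)nx * ny));
      const int rem = (int)(p % ((R_xlen_t)nx * ny));
      const int y = rem / nx;
      const int x = rem % nx;
      for (int j = 0; j < k; ++j) {
        const int xx = x + offsets(j, 0);
        const int yy = y + offsets(j, 1);
        const int zz = z + ((offsets.ncol() > 2) ? offsets(j, 2) : 0);
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const R_xlen_t q = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[q] && labels[q] == 0) {
          labels[q] = next_label;
          stack.push_back(q);
        }
      }
    }
  }
  return labels;
}
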