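// 3D connected-component labelling (6-connectivity) for binary masks.

#include <Rcpp.h>
#include <vector>

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_label_components(Rcpp::LogicalVector mask,
                                         Rcpp::IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  Rcpp::IntegerVector labels(n, 0);
  int current = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s]) continue;
    ++current;
    stack.push_back(s);
    labels[s] = current;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; ++d) {
        int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] && !labels[w]) {
          labels[w] = current;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// Greyscale running min/max over a centred 1D window applied along axis
// `axis` (0/1/2); used to build separable box erosion/dilation for local
// extremum detection.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_running_extreme(Rcpp::NumericVector vol,
                                        Rcpp::IntegerVector dims,
                                        int radius, int axis, bool maximum) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  Rcpp::NumericVector out(vol.size());
  out.attr("dim") = dims;
  int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? nx : (R_xlen_t)nx * ny);
  // iterate over all lines along `axis`
  for (int z = 0; z < (axis == 2 ? 1 : nz); ++z)
    for (int y = 0; y < (axis == 1 ? 1 : ny); ++y)
      for (int x = 0; x < (axis == 0 ? 1 : nx); ++x) {
        R_xlen_t base = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        for (int i = 0; i < len; ++i) {
          int lo = std::max(0, i - radius), hi = std::min(len - 1, i + radius);
          double best = vol[base + (R_xlen_t)lo * stride];
          for (int j = lo + 1; j <= hi; ++j) {
            double v = vol[base + (R_xlen_t)j * stride];
            if (maximum ? v > best : v < best) best = v;
          }
          out[base + (R_xlen_t)i * stride] = best;
        }
      }
  return out;
}
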