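// Central-slice kernels for constrained tilt-series refinement.
//
// All spectra are centred: array index i (0-based) carries frequency
// h = i - n/2 cycles per box, so the DC term sits at index n/2.
// A projection along z of a volume rotated by R corresponds to the plane
// k3d = R^T * (kx, ky, 0) of the volume transform.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline cx_double trilinear_fetch(const cx_cube& vf, double x, double y,
                                        double z, int n) {
  // coordinates in centred frequency units
  double xi = x + n / 2, yi = y + n / 2, zi = z + n / 2;
  int x0 = (int)std::floor(xi), y0 = (int)std::floor(yi),
      z0 = (int)std::floor(zi);
  if (x0 < 0 || y0 < 0 || z0 < 0 || x0 >= n - 1 || y0 >= n - 1 || z0 >= n - 1)
    return cx_double(0.0, 0.0);
  double fx = xi - x0, fy = yi - y0, fz = zi - z0;
  cx_double v = cx_double(0.0, 0.0);
  for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx) {
        double w = (dx ? fx : 1.0 - fx) * (dy ? fy : 1.0 - fy) *
                   (dz ? fz : 1.0 - fz);
        if (w > 0.0) v += w * vf(x0 + dx, y0 + dy, z0 + dz);
      }
  return v;
}

// [[Rcpp::export]]
arma::cx_mat cpp_slice_extract(const arma::cx_cube& vf, const arma::mat& rot) {
  int n = vf.n_rows;
  cx_mat out(n, n, fill::zeros);
  mat rt = rot.t();
  for (int j = 0; j < n; ++j) {
    double ky = j - n / 2;
    for (int i = 0; i < n; ++i) {
      double kx = i - n / 2;
      double qx = rt(0, 0) * kx + rt(0, 1) * ky;
      double qy = rt(1, 0) * kx + rt(1, 1) * ky;
      double qz = rt(2, 0) * kx + rt(2, 1) * ky;
      out(i, j) = trilinear_fetch(vf, qx, qy, qz, n);
    }
  }
  return out;
}

// Normalised cross-correlation between an image spectrum and the
// CTF-filtered, shifted central slice, restricted to band indices
// (m x 2 matrix of 0-based array indices).
// [[Rcpp::export]]
double cpp_slice_score(const arma::cx_mat& imft, const arma::cx_cube& vf,
                       const arma::mat& rot, double sx, double sy,
                       const arma::mat& ctf, const arma::imat& band) {
  int n = vf.n_rows;
  mat rt = rot.t();
  double two_pi = 2.0 * M_PI;
  double num = 0.0, pim = 0.0, pref = 0.0;
  for (uword b = 0; b < band.n_rows; ++b) {
    int i = band(b, 0), j = band(b, 1);
    double kx = i - n / 2, ky = j - n / 2;
    double qx = rt(0, 0) * kx + rt(0, 1) * ky;
    double qy = rt(1, 0) * kx + rt(1, 1) * ky;
    double qz = rt(2, 0) * kx + rt(2, 1) * ky;
    cx_double s = trilinear_fetch(vf, qx, qy, qz, n) * ctf(i, j);
    double ph = -two_pi * (kx * sx + ky * sy) / n;
    s *= cx_double(std::cos(ph), std::sin(ph));
    cx_double a = imft(i, j);
    num += a.real() * s.real() + a.imag() * s.imag();  // Re <a, conj(s)>
    pim += std::norm(a);
    pref += std::norm(s);
  }
  double den = std::sqrt(pim * pref);
  if (den <= 0.0) return 0.0;
  return num / den;
}

// Gridded insertion of CTF-multiplied image spectra as central slices.
// imfts: list of centred n x n complex spectra; rots: 3 x 3 x m cube;
// shifts: m x 2 (particle centre offset inside the crop, pixels);
// ctfs, wts: lists of n x n real matrices (CTF and frequency weight);
// scal: per-image scalar weight (e.g. class occupancy).
// Returns numerator (complex cube) and denominator (real cube).
// [[Rcpp::export]]
Rcpp::List cpp_insert_slices(int n, Rcpp::List imfts, const arma::cube& rots,
                             const arma::mat& shifts, Rcpp::List ctfs,
                             Rcpp::List wts, const arma::vec& scal) {
  cx_cube num(n, n, n, fill::zeros);
  cube den(n, n, n, fill::zeros);
  double two_pi = 2.0 * M_PI;
  double rmax2 = (n / 2 - 1.0) * (n / 2 - 1.0);
  for (uword p = 0; p < rots.n_slices; ++p) {
    cx_mat imft = Rcpp::as<cx_mat>(imfts[p]);
    mat ctf = Rcpp::as<mat>(ctfs[p]);
    mat wt = Rcpp::as<mat>(wts[p]);
    mat rt = rots.slice(p).t();
    double sx = shifts(p, 0), sy = shifts(p, 1), sc = scal(p);
    if (sc == 0.0) continue;
    for (int j = 0; j < n; ++j) {
      double ky = j - n / 2;
      for (int i = 0; i < n; ++i) {
        double kx = i - n / 2;
        if (kx * kx + ky * ky > rmax2) continue;
        double c = ctf(i, j), w = wt(i, j) * sc;
        if (w == 0.0) continue;
        double ph = two_pi * (kx * sx + ky * sy) / n;  // re-centre particle
        cx_double v = imft(i, j) * cx_double(std::cos(ph), std::sin(ph)) *
                      (c * w);
        double d = c * c * w;
        double qx = rt(0, 0) * kx + rt(0, 1) * ky;
        double qy = rt(1, 0) * kx + rt(1, 1) * ky;
        double qz = rt(2, 0) * kx + rt(2, 1) * ky;
        double xi = qx + n / 2, yi = qy + n / 2, zi = qz + n / 2;
        int x0 = (int)std::floor(xi), y0 = (int)std::floor(yi),
            z0 = (int)std::floor(zi);
        if (x0 < 0 || y0 < 0 || z0 < 0 || x0 >= n - 1 || y0 >= n - 1 ||
            z0 >= n - 1)
          continue;
        double fx = xi - x0, fy = yi - y0, fz = zi - z0;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              double g = (dx ? fx : 1.0 - fx) * (dy ? fy : 1.0 - fy) *
                         (dz ? fz : 1.0 - fz);
              if (g <= 0.0) continue;
              num(x0 + dx, y0 + dy, z0 + dz) += g * v;
              den(x0 + dx, y0 + dy, z0 + dz) += g * d;
            }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("num") = num,
                            Rcpp::Named("den") = den);
}
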