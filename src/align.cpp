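// Hot loops of the Fourier-domain registration: bilinear raster rotation and
// the exhaustive rotation search with per-angle integer-pixel correlation
// peaks.  Everything subpixel (matrix-multiply DFT refinement) stays in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Sample img at (row ys, col xs) with bilinear weights; out-of-range
// neighbours contribute zero.  Coordinates are 0-based.
static inline double sample_bilinear(const mat& img, double ys, double xs) {
  const int nr = img.n_rows, nc = img.n_cols;
  if (ys <= -1.0 || xs <= -1.0 || ys >= nr || xs >= nc) return 0.0;
  const int y0 = (int)std::floor(ys), x0 = (int)std::floor(xs);
  const double fy = ys - y0, fx = xs - x0;
  double v = 0.0;
  const bool y0in = y0 >= 0 && y0 < nr, y1in = y0 + 1 >= 0 && y0 + 1 < nr;
  const bool x0in = x0 >= 0 && x0 < nc, x1in = x0 + 1 >= 0 && x0 + 1 < nc;
  if (y0in && x0in) v += img(y0, x0) * (1 - fy) * (1 - fx);
  if (y0in && x1in) v += img(y0, x0 + 1) * (1 - fy) * fx;
  if (y1in && x0in) v += img(y0 + 1, x0) * fy * (1 - fx);
  if (y1in && x1in) v += img(y0 + 1, x0 + 1) * fy * fx;
  return v;
}

// Rotate image content by +theta (radians) about the raster center
// ((nr-1)/2, (nc-1)/2), x = column, y = row: a feature at p moves to
// R(theta) (p - c) + c with R = [cos -sin; sin cos] acting on (x, y).
static mat rotate_bilinear(const mat& img, double theta) {
  const int nr = img.n_rows, nc = img.n_cols;
  if (std::fabs(theta) < 1e-15) return img;
  const double cy = (nr - 1) / 2.0, cx = (nc - 1) / 2.0;
  const double ct = std::cos(theta), st = std::sin(theta);
  mat out(nr, nc, fill::zeros);
  for (int c = 0; c < nc; ++c) {
    const double dx = c - cx;
    for (int r = 0; r < nr; ++r) {
      const double dy = r - cy;
      // inverse rotation of the output site back into the source image
      const double xs = ct * dx + st * dy + cx;
      const double ys = -st * dx + ct * dy + cy;
      out(r, c) = sample_bilinear(img, ys, xs);
    }
  }
  return out;
}

// [[Rcpp::export(name = ".rotate_bilinear_cpp")]]
arma::mat rotate_bilinear_cpp(const arma::mat& img, double theta) {
  return rotate_bilinear(img, theta);
}

// For each trial angle: rotate `moving`, mean-subtract, apply the window,
// FFT, cross-power against Fref (the FFT of the preprocessed reference) and
// locate the integer-pixel circular cross-correlation peak.
// Returns per-angle peak heights and wrapped (signed) integer shifts
// (sx = columns, sy = rows): shifting the rotated moving image by (sx, sy)
// maximizes the Eq-style cross-correlation with the reference.
// [[Rcpp::export(name = ".rot_search_cpp")]]
Rcpp::List rot_search_cpp(const arma::mat& moving, const arma::cx_mat& Fref,
                          const arma::mat& window,
                          const arma::vec& angles_rad) {
  const int nr = moving.n_rows, nc = moving.n_cols;
  const int K = angles_rad.n_elem;
  vec peaks(K);
  ivec sx(K), sy(K);
  for (int k = 0; k < K; ++k) {
    mat rot = rotate_bilinear(moving, angles_rad(k));
    rot -= accu(rot) / (nr * nc);
    rot %= window;
    cx_mat G = fft2(rot);
    mat cc = real(ifft2(Fref % conj(G)));
    uword idx = cc.index_max();
    int row = idx % nr, col = idx / nr;
    if (row > nr / 2) row -= nr;
    if (col > nc / 2) col -= nc;
    peaks(k) = cc(idx);
    sx(k) = col;
    sy(k) = row;
  }
  return Rcpp::List::create(Rcpp::Named("peak") = peaks,
                            Rcpp::Named("sx") = sx,
                            Rcpp::Named("sy") = sy);
}
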