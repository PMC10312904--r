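#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Fan-beam geometry conventions (shared by every routine in this file):
//  * image is an n x n matrix img(ix, iy); pixel centres at
//      x = (ix - (n-1)/2) * h  (to the right),
//      y = (iy - (n-1)/2) * h  (up),
//    with h the pixel size in mm and the grid centred on the rotation axis;
//  * the source sits at radius rs (mm) and view angle beta, i.e. at
//    (rs cos beta, rs sin beta); beta = 0 puts it on the +x axis and
//    angles increase counter-clockwise;
//  * detector element d (0-based) of an equiangular curved array subtends
//    the fan angle gamma_d = (d - (ndet-1)/2) * dgamma, and the ray leaves
//    the source at direction angle beta + pi + gamma_d.
//
// The projector is ray-driven Joseph style: each ray is traversed along its
// dominant axis, one pixel row/column per step, with linear interpolation
// across the transverse axis and a path-length factor h/|u_major|. The
// backprojector scatters through the *identical* weights, so forward and
// backward are an exact adjoint pair (the same sparse matrix and its
// transpose), which the fixed-point and convergence machinery relies on.

using arma::mat;
using arma::vec;

// [[Rcpp::export]]
arma::mat fan_forward_cpp(const arma::mat& img, const arma::vec& angles, int ndet,
                    double dgamma, double rs, double h) {
  const int n = img.n_rows;
  const int nv = angles.n_elem;
  const double c = (n - 1) / 2.0;
  mat sino(nv, ndet, arma::fill::zeros);
  for (int v = 0; v < nv; ++v) {
    const double beta = angles[v];
    const double sx = rs * std::cos(beta), sy = rs * std::sin(beta);
    for (int d = 0; d < ndet; ++d) {
      const double gamma = (d - (ndet - 1) / 2.0) * dgamma;
      const double phi = beta + M_PI + gamma;
      const double ux = std::cos(phi), uy = std::sin(phi);
      double acc = 0.0;
      if (std::fabs(ux) >= std::fabs(uy)) {
        const double w = h / std::fabs(ux);
        for (int ix = 0; ix < n; ++ix) {
          const double x = (ix - c) * h;
          const double t = (x - sx) / ux;
          const double g = (sy + t * uy) / h + c;
          const int i0 = (int)std::floor(g);
          const double f = g - i0;
          if (i0 >= 0 && i0 < n)         acc += (1.0 - f) * w * img(ix, i0);
          if (i0 + 1 >= 0 && i0 + 1 < n) acc += f * w * img(ix, i0 + 1);
        }
      } else {
        const double w = h / std::fabs(uy);
        for (int iy = 0; iy < n; ++iy) {
          const double y = (iy - c) * h;
          const double t = (y - sy) / uy;
          const double g = (sx + t * ux) / h + c;
          const int i0 = (int)std::floor(g);
          const double f = g - i0;
          if (i0 >= 0 && i0 < n)         acc += (1.0 - f) * w * img(i0, iy);
          if (i0 + 1 >= 0 && i0 + 1 < n) acc += f * w * img(i0 + 1, iy);
        }
      }
      sino(v, d) = acc;
    }
  }
  return sino;
}

// [[Rcpp::export]]
arma::mat fan_back_cpp(const arma::mat& sino, const arma::vec& angles, int ndet,
                 double dgamma, double rs, double h, int n) {
  const int nv = angles.n_elem;
  const double c = (n - 1) / 2.0;
  mat img(n, n, arma::fill::zeros);
  for (int v = 0; v < nv; ++v) {
    const double beta = angles[v];
    const double sx = rs * std::cos(beta), sy = rs * std::sin(beta);
    for (int d = 0; d < ndet; ++d) {
      const double val = sino(v, d);
      if (val == 0.0) continue;
      const double gamma = (d - (ndet - 1) / 2.0) * dgamma;
      const double phi = beta + M_PI + gamma;
      const double ux = std::cos(phi), uy = std::sin(phi);
      if (std::fabs(ux) >= std::fabs(uy)) {
        const double w = h / std::fabs(ux);
        for (int ix = 0; ix < n; ++ix) {
          const double x = (ix - c) * h;
          const double t = (x - sx) / ux;
          const double g = (sy + t * uy) / h + c;
          const int i0 = (int)std::floor(g);
          const double f = g - i0;
          if (i0 >= 0 && i0 < n)         img(ix, i0) += (1.0 - f) * w * val;
          if (i0 + 1 >= 0 && i0 + 1 < n) img(ix, i0 + 1) += f * w * val;
        }
      } else {
        const double w = h / std::fabs(uy);
        for (int iy = 0; iy < n; ++iy) {
          const double y = (iy - c) * h;
          const double t = (y - sy) / uy;
          const double g = (sx + t * ux) / h + c;
          const int i0 = (int)std::floor(g);
          const double f = g - i0;
          if (i0 >= 0 && i0 < n)         img(i0, iy) += (1.0 - f) * w * val;
          if (i0 + 1 >= 0 && i0 + 1 < n) img(i0 + 1, iy) += f * w * val;
        }
      }
    }
  }
  return img;
}

// Distance-weighted backprojection step of equiangular fan-beam FBP:
//   f(x, y) = dbeta * sum_v  q(v, gamma') / L^2
// where q is the filtered, cosine-weighted sinogram, L the source-to-pixel
// distance and gamma' the pixel's fan angle at view v, interpolated linearly
// between detector samples. Pixel-driven on purpose: FBP has no adjointness
// requirement and this is the standard discretisation.
// [[Rcpp::export]]
arma::mat fbp_backproject_cpp(const arma::mat& qf, const arma::vec& angles, int ndet,
                        double dgamma, double rs, double h, int n,
                        double dbeta) {
  const int nv = angles.n_elem;
  const double c = (n - 1) / 2.0;
  mat img(n, n, arma::fill::zeros);
  for (int v = 0; v < nv; ++v) {
    const double beta = angles[v];
    const double sx = rs * std::cos(beta), sy = rs * std::sin(beta);
    const double phic = beta + M_PI;
    for (int iy = 0; iy < n; ++iy) {
      const double y = (iy - c) * h;
      for (int ix = 0; ix < n; ++ix) {
        const double x = (ix - c) * h;
        const double dx = x - sx, dy = y - sy;
        const double L2 = dx * dx + dy * dy;
        double g = std::atan2(dy, dx) - phic;
        while (g > M_PI)  g -= 2.0 * M_PI;
        while (g < -M_PI) g += 2.0 * M_PI;
        const double di = g / dgamma + (ndet - 1) / 2.0;
        const int i0 = (int)std::floor(di);
        if (i0 < -1 || i0 > ndet - 1) continue;
        const double f = di - i0;
        double q = 0.0;
        if (i0 >= 0)        q += (1.0 - f) * qf(v, i0);
        if (i0 + 1 < ndet)  q += f * qf(v, i0 + 1);
        img(ix, iy) += dbeta * q / L2;
      }
    }
  }
  return img;
}
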