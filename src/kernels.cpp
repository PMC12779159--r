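// Regularized-Stokeslet kernels for half-space flow over a no-slip wall.
//
// Blob: psi_eps(r) = 15 eps^4 / (8 pi (r^2 + eps^2)^{7/2}).
// Free space (times 8 pi mu):
//   u = f H1(r) + (f.y) y H2(r),
//   H1 = (r^2 + 2 eps^2)/(r^2+eps^2)^{3/2},  H2 = (r^2+eps^2)^{-3/2}.
//
// Wall images: the no-slip plane z = 0 is enforced exactly by the image
// tensor obtained by convolving the classical singular image system for a
// point force below the source with the blob (the v3-moments of the blob
// have closed forms).  With W = x - X*, s^2 = |W|^2, w = s^2 + eps^2,
// h = source height, ftilde = (f1, f2, -f3):
//
//   8 pi mu u = S_eps(y; f) - S_eps(W; f) + 2 [ alpha ftilde
//               + beta (ftilde.W) W + gam1 (ftilde.W) e3 + gam2 ftilde_3 W ]
//   alpha = [3 e2 W3^2 - 2 h W3 (4 e2 + s^2) + h^2 (5 e2 + 2 s^2)]/(2 w^{5/2})
//   beta  = -3 [5 e2 W3^2 - 2 h W3 (6 e2 + s^2) + h^2 (7 e2 + 2 s^2)]/(2 w^{7/2})
//   gam1  = h / w^{3/2}
//   gam2  = [3 e2 W3 - h (4 e2 + s^2)] / w^{5/2}
//
// The tensor vanishes identically on z = 0 and reduces to the singular
// Blake system at separations large compared with eps.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

inline void pair_velocity(const double *p, const double *x0,
                          const double *f, double e2, bool wall,
                          double *u) {
  // free-space part
  double y0 = p[0] - x0[0], y1 = p[1] - x0[1], y2 = p[2] - x0[2];
  double r2 = y0 * y0 + y1 * y1 + y2 * y2;
  double w = r2 + e2;
  double iv = 1.0 / std::sqrt(w);
  double iw3 = iv * iv * iv;
  double H1 = (r2 + 2.0 * e2) * iw3;
  double fy = f[0] * y0 + f[1] * y1 + f[2] * y2;
  double fy3 = fy * iw3;
  u[0] += f[0] * H1 + fy3 * y0;
  u[1] += f[1] * H1 + fy3 * y1;
  u[2] += f[2] * H1 + fy3 * y2;
  if (!wall) return;

  const double h = x0[2];
  double W0 = y0, W1 = y1, W2 = p[2] + h;  // x - X*, X* = (x0, y0, -h)
  double s2 = W0 * W0 + W1 * W1 + W2 * W2;
  double ws = s2 + e2;
  double is = 1.0 / std::sqrt(ws);
  double is2 = is * is;
  double is3 = is2 * is;
  double is5 = is3 * is2;
  double is7 = is5 * is2;
  double G1 = (s2 + 2.0 * e2) * is3;
  double fW = f[0] * W0 + f[1] * W1 + f[2] * W2;
  double fW3 = fW * is3;
  u[0] -= f[0] * G1 + fW3 * W0;
  u[1] -= f[1] * G1 + fW3 * W1;
  u[2] -= f[2] * G1 + fW3 * W2;

  double ft2 = -f[2];
  double ftW = fW - 2.0 * f[2] * W2;       // f~ . W
  double alpha = (1.5 * e2 * W2 * W2 - h * W2 * (4.0 * e2 + s2)
                  + 0.5 * h * h * (5.0 * e2 + 2.0 * s2)) * is5;
  double beta = -1.5 * (5.0 * e2 * W2 * W2 - 2.0 * h * W2 * (6.0 * e2 + s2)
                        + h * h * (7.0 * e2 + 2.0 * s2)) * is7;
  double gam1 = h * is3;
  double gam2 = (3.0 * e2 * W2 - h * (4.0 * e2 + s2)) * is5;
  double cW = beta * ftW + gam2 * ft2;     // coefficient of W
  u[0] += 2.0 * (alpha * f[0] + cW * W0);
  u[1] += 2.0 * (alpha * f[1] + cW * W1);
  u[2] += 2.0 * (alpha * ft2 + cW * W2 + gam1 * ftW);
}

}  // namespace

// [[Rcpp::export(name = ".rs_velocity_cpp")]]
NumericMatrix rs_velocity_cpp(NumericMatrix points, NumericMatrix sources,
                              NumericMatrix forces, double epsilon,
                              double mu, bool wall) {
  const int K = points.nrow(), M = sources.nrow();
  if (sources.ncol() != 3 || points.ncol() != 3 || forces.ncol() != 3 ||
      forces.nrow() != M)
    stop("points, sources and forces must be 3-column matrices with matching rows");
  NumericMatrix out(K, 3);
  const double e2 = epsilon * epsilon;
  const double scale = 1.0 / (8.0 * M_PI * mu);
  // copy into row-major scratch for locality
  std::vector<double> P(3 * K), S(3 * M), F(3 * M);
  for (int k = 0; k < K; ++k)
    for (int c = 0; c < 3; ++c) P[3 * k + c] = points(k, c);
  for (int m = 0; m < M; ++m)
    for (int c = 0; c < 3; ++c) {
      S[3 * m + c] = sources(m, c);
      F[3 * m + c] = forces(m, c);
    }
  for (int k = 0; k < K; ++k) {
    double u[3] = {0.0, 0.0, 0.0};
    const double *p = &P[3 * k];
    for (int m = 0; m < M; ++m)
      pair_velocity(p, &S[3 * m], &F[3 * m], e2, wall, u);
    out(k, 0) = u[0] * scale;
    out(k, 1) = u[1] * scale;
    out(k, 2) = u[2] * scale;
  }
  return out;
}

// [[Rcpp::export(name = ".rs_matrix_cpp")]]
NumericMatrix rs_matrix_cpp(NumericMatrix points, NumericMatrix sources,
                            double epsilon, double mu, bool wall) {
  // G such that u(points) = G %*% vec(forces); 3x3 blocks, row-major by point.
  const int K = points.nrow(), M = sources.nrow();
  NumericMatrix G(3 * K, 3 * M);
  const double e2 = epsilon * epsilon;
  const double scale = 1.0 / (8.0 * M_PI * mu);
  double p[3], s[3], f[3], u[3];
  for (int k = 0; k < K; ++k) {
    for (int c = 0; c < 3; ++c) p[c] = points(k, c);
    for (int m = 0; m < M; ++m) {
      for (int c = 0; c < 3; ++c) s[c] = sources(m, c);
      for (int j = 0; j < 3; ++j) {
        f[0] = f[1] = f[2] = 0.0;
        f[j] = 1.0;
        u[0] = u[1] = u[2] = 0.0;
        pair_velocity(p, s, f, e2, wall, u);
        for (int i = 0; i < 3; ++i) G(3 * k + i, 3 * m + j) = u[i] * scale;
      }
    }
  }
  return G;
}
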