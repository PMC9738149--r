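// Rigid 2D slice registration with a normalized cross-correlation cost.
//
// Transform convention (shared with the R level): a transform (dx, dy, theta)
// maps a point p to T(p) = R_theta (p - c) + c + t, where c is the slice
// centre ((nx-1)/2, (ny-1)/2) in 0-based voxel coordinates and t = (dx, dy).
// Resampling is inverse-mapped with bilinear interpolation and zero fill
// outside the field of view.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sample_bilinear(const NumericMatrix& img, double x,
                                     double y) {
  const int nx = img.nrow(), ny = img.ncol();
  if (x < 0.0 || y < 0.0 || x > nx - 1.0 || y > ny - 1.0) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = x0 + 1 < nx ? x0 + 1 : nx - 1;
  int y1 = y0 + 1 < ny ? y0 + 1 : ny - 1;
  double fx = x - x0, fy = y - y0;
  return (1 - fx) * (1 - fy) * img(x0, y0) + fx * (1 - fy) * img(x1, y0) +
         (1 - fx) * fy * img(x0, y1) + fx * fy * img(x1, y1);
}

// [[Rcpp::export]]
NumericMatrix cpp_resample_rigid(NumericMatrix img, double dx, double dy,
                                 double theta_deg) {
  const int nx = img.nrow(), ny = img.ncol();
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double th = theta_deg * M_PI / 180.0;
  const double c = std::cos(th), s = std::sin(th);
  NumericMatrix out(nx, ny);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      // inverse map: R_{-theta}(p - c - t) + c
      double px = i - cx - dx, py = j - cy - dy;
      double xs = c * px + s * py + cx;
      double ys = -s * px + c * py + cy;
      out(i, j) = sample_bilinear(img, xs, ys);
    }
  }
  return out;
}

// Fused resample + NCC against a fixed reference; returns -2 when either
// image is constant over the frame (degenerate for correlation).
static double eval_ncc(const NumericMatrix& ref, const NumericMatrix& mov,
                       double dx, double dy, double theta_deg) {
  const int nx = ref.nrow(), ny = ref.ncol();
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double th = theta_deg * M_PI / 180.0;
  const double c = std::cos(th), s = std::sin(th);
  const double n = (double)nx * ny;
  double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double px = i - cx - dx, py = j - cy - dy;
      double xs = c * px + s * py + cx;
      double ys = -s * px + c * py + cy;
      double b = sample_bilinear(mov, xs, ys);
      double a = ref(i, j);
      sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b;
    }
  }
  double va = saa - sa * sa / n, vb = sbb - sb * sb / n;
  double cov = sab - sa * sb / n;
  if (va <= 0.0 || vb <= 0.0) return -2.0;
  return cov / std::sqrt(va * vb);
}

// [[Rcpp::export]]
double cpp_eval_ncc(NumericMatrix ref, NumericMatrix mov, double dx,
                    double dy, double theta_deg) {
  return eval_ncc(ref, mov, dx, dy, theta_deg);
}

// NCC of ref against an integer shift of a pre-rotated image (zero fill).
static double ncc_shift(const NumericMatrix& ref, const NumericMatrix& rot,
                        int tx, int ty, double sa, double saa) {
  const int nx = ref.nrow(), ny = ref.ncol();
  const double n = (double)nx * ny;
  double sb = 0, sbb = 0, sab = 0;
  int i0 = tx > 0 ? tx : 0, i1 = nx + (tx < 0 ? tx : 0);
  int j0 = ty > 0 ? ty : 0, j1 = ny + (ty < 0 ? ty : 0);
  for (int j = j0; j < j1; ++j) {
    for (int i = i0; i < i1; ++i) {
      double b = rot(i - tx, j - ty);
      sb += b; sbb += b * b; sab += ref(i, j) * b;
    }
  }
  double va = saa - sa * sa / n, vb = sbb - sb * sb / n;
  double cov = sab - sa * sb / n;
  if (va <= 0.0 || vb <= 0.0) return -2.0;
  return cov / std::sqrt(va * vb);
}

// Golden-section maximization of NCC along one parameter.
static void golden_refine(const NumericMatrix& ref, const NumericMatrix& mov,
                          double* par, int which, double halfwidth,
                          double tol, double* best_ncc) {
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double lo = par[which] - halfwidth, hi = par[which] + halfwidth;
  double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
  double p[3] = {par[0], par[1], par[2]};
  p[which] = x1;
  double f1 = eval_ncc(ref, mov, p[0], p[1], p[2]);
  p[which] = x2;
  double f2 = eval_ncc(ref, mov, p[0], p[1], p[2]);
  while (hi - lo > tol) {
    if (f1 < f2) {
      lo = x1; x1 = x2; f1 = f2;
      x2 = lo + gr * (hi - lo);
      p[which] = x2;
      f2 = eval_ncc(ref, mov, p[0], p[1], p[2]);
    } else {
      hi = x2; x2 = x1; f2 = f1;
      x1 = hi - gr * (hi - lo);
      p[which] = x1;
      f1 = eval_ncc(ref, mov, p[0], p[1], p[2]);
    }
  }
  double xb = f1 > f2 ? x1 : x2, fb = f1 > f2 ? f1 : f2;
  if (fb > *best_ncc) {
    par[which] = xb;
    *best_ncc = fb;
  }
}

// Grid search (integer translations x coarse angles) followed by
// coordinate-wise golden-section refinement.  The identity transform is part
// of the grid and the refined optimum is only accepted when it improves the
// cost, so the returned NCC never falls below the uncorrected NCC.
// Returns (dx, dy, theta, ncc_best, ncc_identity).
// [[Rcpp::export]]
NumericVector cpp_register_slice(NumericMatrix ref, NumericMatrix mov,
                                 int max_shift, double max_theta,
                                 double theta_step, double shift_tol,
                                 double theta_tol) {
  const int nx = ref.nrow(), ny = ref.ncol();
  double sa = 0, saa = 0;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      sa += ref(i, j);
      saa += ref(i, j) * ref(i, j);
    }

  int n_theta = theta_step > 0 ? (int)std::floor(max_theta / theta_step) : 0;
  double best = -3.0, bdx = 0, bdy = 0, bth = 0;
  for (int k = -n_theta; k <= n_theta; ++k) {
    double th = k * theta_step;
    NumericMatrix rot =
        (k == 0) ? mov : cpp_resample_rigid(mov, 0.0, 0.0, th);
    for (int ty = -max_shift; ty <= max_shift; ++ty) {
      for (int tx = -max_shift; tx <= max_shift; ++tx) {
        double v = ncc_shift(ref, rot, tx, ty, sa, saa);
        if (v > best) {
          best = v; bdx = tx; bdy = ty; bth = th;
        }
      }
    }
  }
  double ncc_identity = eval_ncc(ref, mov, 0.0, 0.0, 0.0);

  double par[3] = {bdx, bdy, bth};
  // re-evaluate grid optimum with the exact (interpolating) cost so the
  // refinement compares like with like
  best = eval_ncc(ref, mov, par[0], par[1], par[2]);
  for (int sweep = 0; sweep < 2; ++sweep) {
    golden_refine(ref, mov, par, 0, 1.0, shift_tol, &best);
    golden_refine(ref, mov, par, 1, 1.0, shift_tol, &best);
    if (n_theta > 0)
      golden_refine(ref, mov, par, 2, theta_step, theta_tol, &best);
  }
  if (ncc_identity >= best) {
    par[0] = 0.0; par[1] = 0.0; par[2] = 0.0;
    best = ncc_identity;
  }
  return NumericVector::create(par[0], par[1], par[2], best, ncc_identity);
}
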