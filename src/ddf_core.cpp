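// Core numerical kernels for speckle-based directional dark-field retrieval.
//
// Conventions (shared with the R layer, see ?ddf_conventions):
//   * images are matrices indexed [row, col]; x = column offset, y = row offset
//   * the blur kernel K(x, y) = A exp(-(a1 x^2 + 2 a2 x y + a3 y^2)/2) is
//     rasterised on an odd grid with weight W(iy + R, ix + R) = K(ix, iy)
//   * theta is the axial angle of the kernel's major axis, measured from +x
//     toward +y, in (-90, 90] degrees
//   * shifts u = (ux, uy) are (column, row) displacements in pixels; the model
//     samples the blurred reference at r + u with cubic (Catmull-Rom)
//     interpolation

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double DELTA_FLOOR = 0.05;   // widths below this are a delta
static const double PD_EPS = 1e-12;

// ---------------------------------------------------------------------------
// kernel rasterisation
// ---------------------------------------------------------------------------

// covariance (cxx, cxy, cyy) of the continuous kernel = inverse of alpha matrix
static bool alpha_cov(double a1, double a2, double a3,
                      double &cxx, double &cxy, double &cyy) {
  const double det = a1 * a3 - a2 * a2;
  if (!(a1 > 0.0) || !(a3 > 0.0) || !(det > PD_EPS * std::max(1.0, a1 * a3)))
    return false;
  cxx = a3 / det;
  cxy = -a2 / det;
  cyy = a1 / det;
  return true;
}

static void cov_eigen(double cxx, double cxy, double cyy,
                      double &vmax, double &vmin) {
  const double tr = cxx + cyy;
  const double disc = std::sqrt(std::max(0.0, (cxx - cyy) * (cxx - cyy) +
                                         4.0 * cxy * cxy));
  vmax = 0.5 * (tr + disc);
  vmin = 0.5 * (tr - disc);
}

// point-sample a Gaussian with covariance (cxx,cxy,cyy) on [-R,R]^2, unit sum
static void sample_gauss(double cxx, double cxy, double cyy, int R, mat &W) {
  const int m = 2 * R + 1;
  const double det = cxx * cyy - cxy * cxy;
  W.set_size(m, m);
  if (det <= 0.0) {  // degenerate: delta
    W.zeros();
    W(R, R) = 1.0;
    return;
  }
  const double b1 = cyy / det, b2 = -cxy / det, b3 = cxx / det;
  for (int j = 0; j < m; ++j) {
    const double x = j - R;
    double *wc = W.colptr(j);
    for (int i = 0; i < m; ++i) {
      const double y = i - R;
      wc[i] = std::exp(-0.5 * (b1 * x * x + 2.0 * b2 * x * y + b3 * y * y));
    }
  }
  W /= accu(W);
}

static void discrete_cov(const mat &W, double &dxx, double &dxy, double &dyy) {
  const int m = W.n_rows, R = (m - 1) / 2;
  dxx = dxy = dyy = 0.0;
  for (int j = 0; j < m; ++j) {
    const double x = j - R;
    for (int i = 0; i < m; ++i) {
      const double y = i - R;
      const double w = W(i, j);
      dxx += w * x * x;
      dxy += w * x * y;
      dyy += w * y * y;
    }
  }
}

// Rasterise the kernel so that the *discrete* second moments of the raster
// match the continuous covariance M^-1 (moment-matched sampling).  Plain
// point sampling under-estimates sub-pixel widths; cell integration adds
// ~1/12 quantisation variance.  The fixed point below fixes both.
static mat raster_kernel(double a1, double a2, double a3, int R) {
  double cxx, cxy, cyy;
  if (!alpha_cov(a1, a2, a3, cxx, cxy, cyy))
    Rcpp::stop("invalid kernel parameters in rasterisation");
  double vmax, vmin;
  cov_eigen(cxx, cxy, cyy, vmax, vmin);
  const int m = 2 * R + 1;
  if (std::sqrt(vmax) < DELTA_FLOOR) {  // whole kernel below the width floor
    mat W(m, m, fill::zeros);
    W(R, R) = 1.0;
    return W;
  }
  // clamp the minor axis at the width floor (no blur across)
  if (std::sqrt(std::max(vmin, 0.0)) < DELTA_FLOOR) {
    const double tgt = DELTA_FLOOR * DELTA_FLOOR;
    // shift both eigenvalues so min becomes tgt, preserving orientation
    const double add = tgt - vmin;
    cxx += add;
    cyy += add;
    cov_eigen(cxx, cxy, cyy, vmax, vmin);
  }
  double sxx = cxx, sxy = cxy, syy = cyy;
  mat W;
  sample_gauss(sxx, sxy, syy, R, W);
  const double tol = 1e-11 * std::max(1.0, vmax);
  for (int it = 0; it < 80; ++it) {
    double dxx, dxy, dyy;
    discrete_cov(W, dxx, dxy, dyy);
    const double exx = cxx - dxx, exy = cxy - dxy, eyy = cyy - dyy;
    if (std::max(std::fabs(exx),
                 std::max(std::fabs(exy), std::fabs(eyy))) < tol)
      break;
    sxx += 0.8 * exx;
    sxy += 0.8 * exy;
    syy += 0.8 * eyy;
    // keep the sampling covariance positive definite
    double evmax, evmin;
    cov_eigen(sxx, sxy, syy, evmax, evmin);
    if (evmin < 1e-6) {
      const double add = 1e-6 - evmin;
      sxx += add;
      syy += add;
    }
    sample_gauss(sxx, sxy, syy, R, W);
  }
  return W;
}

static int auto_radius(double a1, double a2, double a3) {
  double cxx, cxy, cyy, vmax, vmin;
  if (!alpha_cov(a1, a2, a3, cxx, cxy, cyy))
    Rcpp::stop("invalid kernel parameters");
  cov_eigen(cxx, cxy, cyy, vmax, vmin);
  const double sM = std::sqrt(std::max(vmax, 0.0));
  return std::max(1, (int)std::ceil(4.0 * sM));
}

// [[Rcpp::export]]
arma::mat cpp_rasterize_kernel(double a1, double a2, double a3, int radius) {
  const int R = radius > 0 ? radius : auto_radius(a1, a2, a3);
  return raster_kernel(a1, a2, a3, R);
}

// ---------------------------------------------------------------------------
// interpolation and convolution
// ---------------------------------------------------------------------------

static inline void cubic_weights(double f, double *w) {
  const double f2 = f * f, f3 = f2 * f;
  w[0] = 0.5 * (-f3 + 2.0 * f2 - f);
  w[1] = 0.5 * (3.0 * f3 - 5.0 * f2 + 2.0);
  w[2] = 0.5 * (-3.0 * f3 + 4.0 * f2 + f);
  w[3] = 0.5 * (f3 - f2);
}

static inline int mirror_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// out(r) = img(r + u), cubic interpolation, mirror boundary
// [[Rcpp::export]]
arma::mat cpp_shift_cubic(const arma::mat &img, double ux, double uy) {
  const int H = img.n_rows, W = img.n_cols;
  mat out(H, W);
  const int bx = (int)std::floor(ux), by = (int)std::floor(uy);
  double wx[4], wy[4];
  cubic_weights(ux - bx, wx);
  cubic_weights(uy - by, wy);
  for (int c = 0; c < W; ++c) {
    int xi[4];
    for (int k = 0; k < 4; ++k) xi[k] = mirror_idx(c + bx - 1 + k, W);
    for (int r = 0; r < H; ++r) {
      double v = 0.0;
      for (int ky = 0; ky < 4; ++ky) {
        const int rr = mirror_idx(r + by - 1 + ky, H);
        double h = 0.0;
        for (int kx = 0; kx < 4; ++kx) h += wx[kx] * img(rr, xi[kx]);
        v += wy[ky] * h;
      }
      out(r, c) = v;
    }
  }
  return out;
}

// full-image correlation with a point-symmetric kernel, mirror boundary
// [[Rcpp::export]]
arma::mat cpp_convolve(const arma::mat &img, const arma::mat &ker) {
  const int H = img.n_rows, W = img.n_cols;
  const int m = ker.n_rows, R = (m - 1) / 2;
  mat out(H, W, fill::zeros);
  for (int kj = 0; kj < m; ++kj) {
    for (int ki = 0; ki < m; ++ki) {
      const double kv = ker(ki, kj);
      if (kv == 0.0) continue;
      const int dy = ki - R, dx = kj - R;
      for (int c = 0; c < W; ++c) {
        const int cc = mirror_idx(c + dx, W);
        const double *ip = img.colptr(cc);
        double *op = out.colptr(c);
        for (int r = 0; r < H; ++r) op[r] += kv * ip[mirror_idx(r + dy, H)];
      }
    }
  }
  return out;
}

// forward model on a full frame: T * (ref (*) K)(r + u), clipped at 0
// [[Rcpp::export]]
arma::mat cpp_model_intensity(const arma::mat &ref, double T, double ux,
                              double uy, double a1, double a2, double a3,
                              int radius) {
  const int R = radius > 0 ? radius : auto_radius(a1, a2, a3);
  mat ker = raster_kernel(a1, a2, a3, R);
  mat blurred;
  if (ker(R, R) == 1.0 && accu(ker) == 1.0)  // delta: skip the convolution
    blurred = ref;
  else
    blurred = cpp_convolve(ref, ker);
  mat out = (ux == 0.0 && uy == 0.0) ? blurred : cpp_shift_cubic(blurred, ux, uy);
  out *= T;
  out.clamp(0.0, datum::inf);
  return out;
}

// ---------------------------------------------------------------------------
// windowed cost (Eq-2-style double sum) and the per-pixel solver
// ---------------------------------------------------------------------------

struct PixelWorkspace {
  mat SC;     // shifted reference crop, (w + 2R) x (w + 2R)
  mat T1;     // horizontal-pass scratch for the interpolation
  cube Mbuf;  // model values on the window for every frame
};

// Evaluate the windowed cost at one pixel.  If T_in is NA the closed-form
// optimal transmittance is used.  kcut is a relative tap cutoff (0 = exact).
// Returns false (margin violation) if any read would fall out of bounds.
static bool window_cost(const cube &sample, const cube &reference,
                        int r0y, int r0x, const mat &gamma, double T_in,
                        double ux, double uy, const mat &ker,
                        PixelWorkspace &ws, double kcut,
                        double &cost_out, double &T_out) {
  const int H = sample.n_rows, W = sample.n_cols, N = sample.n_slices;
  const int w = gamma.n_rows, wh = (w - 1) / 2;
  const int m = ker.n_rows, R = (m - 1) / 2;
  const int e = w + 2 * R;  // extended crop side
  const int bx = (int)std::floor(ux), by = (int)std::floor(uy);
  // reads span r0 - wh - R + floor(u) - 1 ... r0 + wh + R + floor(u) + 2
  const int ylo = r0y - wh - R + by - 1, yhi = r0y + wh + R + by + 2;
  const int xlo = r0x - wh - R + bx - 1, xhi = r0x + wh + R + bx + 2;
  if (ylo < 0 || xlo < 0 || yhi >= H || xhi >= W) return false;

  double wx[4], wy[4];
  cubic_weights(ux - bx, wx);
  cubic_weights(uy - by, wy);
  const bool delta = (m == 1) || (ker(R, R) == 1.0);
  const double kmax = ker.max();

  if ((int)ws.SC.n_rows != e) {
    ws.SC.set_size(e, e);
    ws.T1.set_size(e + 3, e);
  }
  if ((int)ws.Mbuf.n_rows != w || (int)ws.Mbuf.n_slices != N)
    ws.Mbuf.set_size(w, w, N);

  double Sgg = 0.0, Sgi = 0.0, Sii = 0.0;
  for (int j = 0; j < N; ++j) {
    const mat &ref = reference.slice(j);
    // horizontal cubic pass: T1(ry, c) over raw rows ylo..yhi
    const int nry = yhi - ylo + 1;
    for (int c = 0; c < e; ++c) {
      const int xb = xlo + c;  // = r0x - wh - R + c + bx - 1
      double *t1 = ws.T1.colptr(c);
      const double *p0 = ref.colptr(xb) + ylo;
      const double *p1 = ref.colptr(xb + 1) + ylo;
      const double *p2 = ref.colptr(xb + 2) + ylo;
      const double *p3 = ref.colptr(xb + 3) + ylo;
      for (int ry = 0; ry < nry; ++ry)
        t1[ry] = wx[0] * p0[ry] + wx[1] * p1[ry] + wx[2] * p2[ry] +
                 wx[3] * p3[ry];
    }
    // vertical cubic pass into the shifted crop SC
    for (int c = 0; c < e; ++c) {
      const double *t1 = ws.T1.colptr(c);
      double *sc = ws.SC.colptr(c);
      for (int r = 0; r < e; ++r)
        sc[r] = wy[0] * t1[r] + wy[1] * t1[r + 1] + wy[2] * t1[r + 2] +
                wy[3] * t1[r + 3];
    }
    // correlation with the (point-symmetric) kernel on the window
    mat &M = ws.Mbuf.slice(j);
    if (delta) {
      M = ws.SC.submat(R, R, R + w - 1, R + w - 1);
    } else {
      // per kernel column: 1-D correlation along image rows (contiguous
      // dot products vectorise; the tap cutoff trims negligible weights)
      M.zeros();
      const double thr = kcut * kmax;
      for (int kj = 0; kj < m; ++kj) {
        const double *kcol = ker.colptr(kj);
        int k0 = 0, k1 = m - 1;
        while (k0 < m && kcol[k0] <= thr && kcol[m - 1 - k0] <= thr) ++k0;
        k1 = m - 1 - k0;
        if (k0 > k1) continue;
        const int nk = k1 - k0 + 1;
        for (int c = 0; c < w; ++c) {
          const double *sc = ws.SC.colptr(c + kj) + k0;
          double *mp = M.colptr(c);
          for (int r = 0; r < w; ++r) {
            double acc = 0.0;
            const double *scp = sc + r;
            for (int k = 0; k < nk; ++k) acc += kcol[k0 + k] * scp[k];
            mp[r] += acc;
          }
        }
      }
    }
    // accumulate the window sums
    for (int c = 0; c < w; ++c) {
      const double *gp = gamma.colptr(c);
      const double *mp = M.colptr(c);
      const double *Ip = sample.slice_colptr(j, r0x - wh + c) + (r0y - wh);
      for (int r = 0; r < w; ++r) {
        Sgg += gp[r] * mp[r] * mp[r];
        Sgi += gp[r] * Ip[r] * mp[r];
        Sii += gp[r] * Ip[r] * Ip[r];
      }
    }
  }
  double T = T_in;
  if (!std::isfinite(T_in)) {
    if (Sgg <= 0.0) {  // model term vanishes: T* undefined
      T_out = datum::nan;
      cost_out = Sii;
      return true;
    }
    T = Sgi / Sgg;
  }
  // residual pass (numerically exact, no cancellation)
  double cost = 0.0;
  for (int j = 0; j < N; ++j) {
    const mat &M = ws.Mbuf.slice(j);
    for (int c = 0; c < w; ++c) {
      const double *gp = gamma.colptr(c);
      const double *mp = M.colptr(c);
      const double *Ip = sample.slice_colptr(j, r0x - wh + c) + (r0y - wh);
      for (int r = 0; r < w; ++r) {
        const double res = Ip[r] - T * mp[r];
        cost += gp[r] * res * res;
      }
    }
  }
  cost_out = cost;
  T_out = T;
  return true;
}

// [[Rcpp::export]]
Rcpp::List cpp_cost(const arma::cube &sample, const arma::cube &reference,
                    int r0y, int r0x, const arma::mat &gamma, double T,
                    double ux, double uy, double a1, double a2, double a3,
                    int radius) {
  const int R = radius > 0 ? radius : auto_radius(a1, a2, a3);
  mat ker = raster_kernel(a1, a2, a3, R);
  PixelWorkspace ws;
  double cost, Tout;
  if (!window_cost(sample, reference, r0y, r0x, gamma, T, ux, uy, ker, ws,
                   0.0, cost, Tout))
    Rcpp::stop("pixel (%d, %d) is inside the margin for this window/shift/kernel",
               r0y + 1, r0x + 1);
  return Rcpp::List::create(Rcpp::Named("cost") = cost,
                            Rcpp::Named("T") = Tout);
}

// ---------------------------------------------------------------------------
// Nelder-Mead over q = (ux, uy, log sigma_a, log sigma_b, theta[rad])
// sigma_a is the width along theta, sigma_b across; T solved in closed form.
// ---------------------------------------------------------------------------

struct SolveOpts {
  double max_shift;
  double wmin, wmax;       // width bounds (pixels)
  double reltol;
  double xtol;             // simplex-extent stop in parameter units
  int maxit;               // cost-evaluation budget for Nelder-Mead
  double kcut;             // relative kernel tap cutoff inside the search
  int radius_cap;          // kernel support cap (margin guarantee)
};

static void q_to_alpha(const double *q, double &a1, double &a2, double &a3) {
  const double sa = std::exp(q[2]), sb = std::exp(q[3]);
  const double c = std::cos(q[4]), s = std::sin(q[4]);
  const double va = sa * sa, vb = sb * sb;
  const double cxx = va * c * c + vb * s * s;
  const double cyy = va * s * s + vb * c * c;
  const double cxy = (va - vb) * s * c;
  const double det = va * vb;
  a1 = cyy / det;
  a2 = -cxy / det;
  a3 = cxx / det;
}

struct Objective {
  const cube *sample, *reference;
  int r0y, r0x;
  const mat *gamma;
  const SolveOpts *opts;
  PixelWorkspace ws;
  long nev = 0;

  double eval(const double *q, double &Tout, bool exact = false) {
    ++nev;
    const SolveOpts &o = *opts;
    double pen = 0.0;
    if (std::fabs(q[0]) > o.max_shift) pen += std::fabs(q[0]) - o.max_shift;
    if (std::fabs(q[1]) > o.max_shift) pen += std::fabs(q[1]) - o.max_shift;
    const double la = q[2], lb = q[3];
    const double llo = std::log(o.wmin), lhi = std::log(o.wmax);
    if (la < llo) pen += llo - la;
    if (la > lhi) pen += la - lhi;
    if (lb < llo) pen += llo - lb;
    if (lb > lhi) pen += lb - lhi;
    if (pen > 0.0) {
      Tout = NA_REAL;
      return 1e15 * (1.0 + pen * pen);
    }
    double a1, a2, a3;
    q_to_alpha(q, a1, a2, a3);
    int R = auto_radius(a1, a2, a3);
    if (R > o.radius_cap) R = o.radius_cap;
    mat ker = raster_kernel(a1, a2, a3, R);
    double cost;
    if (!window_cost(*sample, *reference, r0y, r0x, *gamma, NA_REAL, q[0],
                     q[1], ker, ws, exact ? 0.0 : o.kcut, cost, Tout))
      return 1e15;  // margin hit inside the search: treat as infeasible
    return cost;
  }
};

// one Nelder-Mead run; q (length 5) is updated in place, returns best cost
static double nelder_mead(Objective &obj, double *q, const SolveOpts &o,
                          bool &converged) {
  const int n = 5;
  const double step0[5] = {0.35, 0.35, 0.25, 0.25, 0.25};
  mat S(n, n + 1);       // simplex vertices in columns
  vec f(n + 1);
  double Tdum;
  for (int v = 0; v <= n; ++v) {
    for (int d = 0; d < n; ++d) S(d, v) = q[d];
    if (v > 0) S(v - 1, v) += step0[v - 1];
    f(v) = obj.eval(S.colptr(v), Tdum);
  }
  converged = false;
  while (obj.nev < o.maxit) {
    uvec ord = sort_index(f);
    S = S.cols(ord);
    f = f(ord);
    const double flo = f(0), fhi = f(n);
    if (fhi - flo <= o.reltol * (std::fabs(flo) + 1e-300)) {
      converged = true;
      break;
    }
    double ext = 0.0;  // simplex extent around the best vertex
    for (int v = 1; v <= n; ++v)
      ext = std::max(ext, abs(S.col(v) - S.col(0)).max());
    if (ext <= o.xtol) {
      converged = true;
      break;
    }
    vec cen = mean(S.cols(0, n - 1), 1);
    vec xr = cen + (cen - S.col(n));
    double fr = obj.eval(xr.memptr(), Tdum);
    if (fr < flo) {
      vec xe = cen + 2.0 * (cen - S.col(n));
      double fe = obj.eval(xe.memptr(), Tdum);
      if (fe < fr) {
        S.col(n) = xe;
        f(n) = fe;
      } else {
        S.col(n) = xr;
        f(n) = fr;
      }
    } else if (fr < f(n - 1)) {
      S.col(n) = xr;
      f(n) = fr;
    } else {
      vec xc = cen + 0.5 * (S.col(n) - cen);
      double fc = obj.eval(xc.memptr(), Tdum);
      if (fc < f(n)) {
        S.col(n) = xc;
        f(n) = fc;
      } else {  // shrink
        for (int v = 1; v <= n; ++v) {
          S.col(v) = S.col(0) + 0.5 * (S.col(v) - S.col(0));
          f(v) = obj.eval(S.colptr(v), Tdum);
        }
      }
    }
  }
  uword ib = f.index_min();
  for (int d = 0; d < n; ++d) q[d] = S(d, ib);
  return f(ib);
}

// grid initialisation: integer shifts x isotropic widths, theta = 0
static void grid_init(Objective &obj, const SolveOpts &o,
                      const std::vector<double> &widths, double *q) {
  double Tdum, best = datum::inf;
  double qb[5] = {0, 0, std::log(0.5), std::log(0.5), 0};
  const int ms = (int)std::floor(o.max_shift);
  double qt[5];
  for (int iy = -ms; iy <= ms; ++iy) {
    for (int ix = -ms; ix <= ms; ++ix) {
      for (double wdt : widths) {
        const double wcl = std::min(std::max(wdt, o.wmin), o.wmax);
        qt[0] = ix;
        qt[1] = iy;
        qt[2] = qt[3] = std::log(wcl);
        qt[4] = 0.0;
        const double c = obj.eval(qt, Tdum);
        if (c < best) {
          best = c;
          std::copy(qt, qt + 5, qb);
        }
      }
    }
  }
  std::copy(qb, qb + 5, q);
}

// alpha -> q (principal axes), used to seed the search from init maps
static bool alpha_to_q(double a1, double a2, double a3, double *q25) {
  double cxx, cxy, cyy;
  if (!alpha_cov(a1, a2, a3, cxx, cxy, cyy)) return false;
  double vmax, vmin;
  cov_eigen(cxx, cxy, cyy, vmax, vmin);
  if (!(vmin > 0.0)) return false;
  q25[0] = 0.5 * std::log(vmax);   // log sigma_major
  q25[1] = 0.5 * std::log(vmin);
  q25[2] = 0.5 * std::atan2(2.0 * cxy, cxx - cyy);  // major-axis angle
  return true;
}

struct PixelResult {
  double T, ux, uy, a1, a2, a3, cost;
  int converged, nev;
};

static PixelResult solve_one(Objective &obj, const SolveOpts &o,
                             const std::vector<double> &grid_widths,
                             const double *init_q,  // NULL -> grid init
                             bool refine) {
  double q[5];
  if (init_q) {
    std::copy(init_q, init_q + 5, q);
  } else {
    grid_init(obj, o, grid_widths, q);
  }
  double q0[5];
  std::copy(q, q + 5, q0);
  bool conv = true;
  obj.nev = 0;
  if (refine) nelder_mead(obj, q, o, conv);
  // exact re-evaluation at both the initial and final point; keep the better
  double Tb, T0, cb, c0;
  cb = obj.eval(q, Tb, true);
  c0 = obj.eval(q0, T0, true);
  if (c0 < cb) {
    std::copy(q0, q0 + 5, q);
    cb = c0;
    Tb = T0;
  }
  PixelResult r;
  r.ux = q[0];
  r.uy = q[1];
  q_to_alpha(q, r.a1, r.a2, r.a3);
  r.T = std::isfinite(Tb) ? std::max(Tb, 0.0) : 0.0;
  r.cost = cb;
  r.converged = conv ? 1 : 0;
  r.nev = (int)obj.nev;
  return r;
}

// [[Rcpp::export]]
Rcpp::List cpp_solve_pixel(const arma::cube &sample,
                           const arma::cube &reference, int r0y, int r0x,
                           const arma::mat &gamma, Rcpp::NumericVector init,
                           double max_shift, double wmin, double wmax,
                           double reltol, double xtol, int maxit, double kcut,
                           int radius_cap, Rcpp::NumericVector grid_widths,
                           bool refine) {
  SolveOpts o{max_shift, wmin, wmax, reltol, xtol, maxit, kcut, radius_cap};
  Objective obj;
  obj.sample = &sample;
  obj.reference = &reference;
  obj.r0y = r0y;
  obj.r0x = r0x;
  obj.gamma = &gamma;
  obj.opts = &o;
  PixelResult r;
  if (init.size() == 5) {
    double q[5] = {init[0], init[1], init[2], init[3], init[4]};
    r = solve_one(obj, o, {}, q, refine);
  } else {
    std::vector<double> gw(grid_widths.begin(), grid_widths.end());
    r = solve_one(obj, o, gw, nullptr, refine);
  }
  return Rcpp::List::create(
      Rcpp::Named("T") = r.T, Rcpp::Named("ux") = r.ux,
      Rcpp::Named("uy") = r.uy, Rcpp::Named("a1") = r.a1,
      Rcpp::Named("a2") = r.a2, Rcpp::Named("a3") = r.a3,
      Rcpp::Named("cost") = r.cost, Rcpp::Named("converged") = r.converged,
      Rcpp::Named("nev") = r.nev);
}

// Solve all pixels on a stride grid.  init_* are either empty matrices (grid
// initialisation at every pixel) or full-size maps of initial parameters.
// [[Rcpp::export]]
Rcpp::List cpp_solve_level(const arma::cube &sample,
                           const arma::cube &reference,
                           const arma::mat &gamma, int margin, int step,
                           const arma::mat &init_ux, const arma::mat &init_uy,
                           const arma::mat &init_a1, const arma::mat &init_a2,
                           const arma::mat &init_a3, double max_shift,
                           double wmin, double wmax, double reltol,
                           double xtol, int maxit, double kcut,
                           int radius_cap, Rcpp::NumericVector grid_widths) {
  const int H = sample.n_rows, W = sample.n_cols;
  const bool have_init = init_ux.n_rows == (uword)H;
  SolveOpts o{max_shift, wmin, wmax, reltol, xtol, maxit, kcut, radius_cap};
  Objective obj;
  obj.sample = &sample;
  obj.reference = &reference;
  obj.gamma = &gamma;
  obj.opts = &o;
  std::vector<double> gw(grid_widths.begin(), grid_widths.end());

  mat Tm(H, W), ux(H, W), uy(H, W), a1(H, W), a2(H, W), a3(H, W), cost(H, W);
  Tm.fill(datum::nan); ux.fill(datum::nan); uy.fill(datum::nan);
  a1.fill(datum::nan); a2.fill(datum::nan); a3.fill(datum::nan);
  cost.fill(datum::nan);
  imat conv(H, W, fill::zeros), mask(H, W, fill::zeros);

  for (int y = margin; y < H - margin; y += step) {
    Rcpp::checkUserInterrupt();
    for (int x = margin; x < W - margin; x += step) {
      obj.r0y = y;
      obj.r0x = x;
      PixelResult r;
      if (have_init) {
        double ax[3];
        double q[5] = {init_ux(y, x), init_uy(y, x), 0, 0, 0};
        if (alpha_to_q(init_a1(y, x), init_a2(y, x), init_a3(y, x), ax)) {
          q[2] = std::max(ax[0], std::log(wmin));
          q[3] = std::max(ax[1], std::log(wmin));
          q[4] = ax[2];
        } else {
          q[2] = q[3] = std::log(std::max(0.5, wmin));
        }
        q[0] = std::min(std::max(q[0], -max_shift), max_shift);
        q[1] = std::min(std::max(q[1], -max_shift), max_shift);
        r = solve_one(obj, o, gw, q, true);
      } else {
        r = solve_one(obj, o, gw, nullptr, true);
      }
      Tm(y, x) = r.T;
      ux(y, x) = r.ux;
      uy(y, x) = r.uy;
      a1(y, x) = r.a1;
      a2(y, x) = r.a2;
      a3(y, x) = r.a3;
      cost(y, x) = r.cost;
      conv(y, x) = r.converged;
      mask(y, x) = 1;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("T") = Tm, Rcpp::Named("ux") = ux, Rcpp::Named("uy") = uy,
      Rcpp::Named("a1") = a1, Rcpp::Named("a2") = a2,
      Rcpp::Named("a3") = a3, Rcpp::Named("residual") = cost,
      Rcpp::Named("converged") = conv, Rcpp::Named("mask") = mask);
}

// block-average binning (crops to a multiple of the factor)
// [[Rcpp::export]]
arma::mat cpp_bin2(const arma::mat &img, int b) {
  const int H = (img.n_rows / b) * b, W = (img.n_cols / b) * b;
  mat out(H / b, W / b, fill::zeros);
  for (int c = 0; c < W; ++c) {
    const double *ip = img.colptr(c);
    double *op = out.colptr(c / b);
    for (int r = 0; r < H; ++r) op[r / b] += ip[r];
  }
  out /= (double)(b * b);
  return out;
}
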