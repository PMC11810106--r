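// Sequential inner loops: two-state Markov contact dynamics and the
// overdamped Langevin / well-tempered metadynamics toy engine.
// All quantities in the package's internal units (nm, ps, kJ/mol, K).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Two-state Markov chain with fixed one-step transition probabilities.
// Uses R's RNG so set.seed() on the R side makes runs reproducible.
// [[Rcpp::export]]
IntegerVector cpp_markov_chain(int n, double p_on_given_on,
                               double p_on_given_off, int init_state) {
  IntegerVector s(n);
  int cur = init_state;
  for (int i = 0; i < n; ++i) {
    double p = cur ? p_on_given_on : p_on_given_off;
    cur = (unif_rand() < p) ? 1 : 0;
    s[i] = cur;
  }
  return s;
}

// ---------------------------------------------------------------------------
// Analytic potentials for the toy engine.
//   type 1: harmonic            par = (k1, c1[, k2, c2])
//   type 2: tilted double well  par = (a, w2, b, c) along dim 1
//           U = a*((x-c)^2 - w2)^2 + b*(x-c); dim 2 (if any) harmonic
//           with par (k2, c2) appended.
static inline void potential_grad(int type, const std::vector<double>& par,
                                  int dim, const double* x, double* g,
                                  double* u) {
  double U = 0.0;
  if (type == 1) {
    for (int d = 0; d < dim; ++d) {
      double k = par[2 * d], c = par[2 * d + 1];
      double dx = x[d] - c;
      U += 0.5 * k * dx * dx;
      g[d] = k * dx;
    }
  } else if (type == 2) {
    double a = par[0], w2 = par[1], b = par[2], c = par[3];
    double dx = x[0] - c;
    double q = dx * dx - w2;
    U += a * q * q + b * dx;
    g[0] = 4.0 * a * q * dx + b;
    if (dim == 2) {
      double k2 = par[4], c2 = par[5];
      double dy = x[1] - c2;
      U += 0.5 * k2 * dy * dy;
      g[1] = k2 * dy;
    }
  } else {
    stop("unknown potential type code %d", type);
  }
  *u = U;
}

// One-sided harmonic walls limiting the CV range.
static inline void wall_grad(int dim, const double* lo, const double* hi,
                             double k, const double* x, double* g, double* u) {
  for (int d = 0; d < dim; ++d) {
    if (x[d] < lo[d]) {
      double dx = x[d] - lo[d];
      *u += 0.5 * k * dx * dx;
      g[d] += k * dx;
    } else if (x[d] > hi[d]) {
      double dx = x[d] - hi[d];
      *u += 0.5 * k * dx * dx;
      g[d] += k * dx;
    }
  }
}

// Plain overdamped Langevin on an analytic potential (no bias).
// Returns the sampled positions every `stride` steps.
// [[Rcpp::export]]
NumericMatrix cpp_langevin(int type, NumericVector par, int dim,
                           NumericVector x0, double kT, double friction,
                           double dt, int n_steps, int stride) {
  std::vector<double> p(par.begin(), par.end());
  double x[2] = {0, 0}, g[2], u;
  for (int d = 0; d < dim; ++d) x[d] = x0[d];
  int n_out = n_steps / stride;
  NumericMatrix out(n_out, dim);
  double noise = std::sqrt(2.0 * kT * dt / friction);
  int row = 0;
  for (int i = 1; i <= n_steps; ++i) {
    potential_grad(type, p, dim, x, g, &u);
    for (int d = 0; d < dim; ++d)
      x[d] += -g[d] * dt / friction + noise * norm_rand();
    if (i % stride == 0 && row < n_out) {
      for (int d = 0; d < dim; ++d) out(row, d) = x[d];
      ++row;
    }
  }
  return out;
}

// Well-tempered metadynamics with multiple walkers sharing one bias.
// The bias potential and its gradient are accumulated on a regular grid
// (exact Gaussian values at nodes, linear interpolation in between) so a
// 1e6-step run stays cheap; every deposited hill is also recorded so the
// R-side Eq.-style reconstruction uses the hill list, not the grid.
//
// Deposition: every t_G ps one walker (round-robin) deposits a Gaussian of
// nominal height omega*t_G scaled by exp(-V(s)/(kB*dT)) evaluated at its
// own CV position; all walkers feel the shared bias immediately.
// [[Rcpp::export]]
List cpp_wt_metad(int type, NumericVector par, int dim, NumericMatrix x0,
                  double kT, double friction, double dt, int n_steps,
                  double omega, double t_G, double bias_factor, double temp,
                  NumericVector sigma, NumericVector wall_lo,
                  NumericVector wall_hi, double wall_k, NumericVector grid_lo,
                  NumericVector grid_hi, IntegerVector grid_n,
                  int out_stride) {
  const double kB = 0.008314462618;
  if (bias_factor <= 1.0) stop("bias factor must be > 1");
  if (t_G <= 0 || omega <= 0) stop("omega and t_G must be positive");
  double dT = (bias_factor - 1.0) * temp;       // CV-temperature boost, K
  double kBdT = kB * dT;                        // kJ/mol
  double h_nom = omega * t_G;                   // nominal hill height

  int n_walkers = x0.nrow();
  std::vector<double> p(par.begin(), par.end());
  std::vector<double> xs(2 * n_walkers, 0.0);
  for (int w = 0; w < n_walkers; ++w)
    for (int d = 0; d < dim; ++d) xs[2 * w + d] = x0(w, d);

  // bias grids: value + gradient per dimension
  int nx = grid_n[0], ny = (dim == 2) ? grid_n[1] : 1;
  double gx0 = grid_lo[0], gx1 = grid_hi[0];
  double gy0 = (dim == 2) ? grid_lo[1] : 0.0, gy1 = (dim == 2) ? grid_hi[1] : 1.0;
  double hx = (gx1 - gx0) / (nx - 1);
  double hy = (dim == 2) ? (gy1 - gy0) / (ny - 1) : 1.0;
  std::vector<double> V(nx * ny, 0.0), Gx(nx * ny, 0.0), Gy(nx * ny, 0.0);

  auto bias_at = [&](const double* x, double* bg) -> double {
    // clamped bilinear interpolation of V and its gradient
    double fx = (x[0] - gx0) / hx;
    if (fx < 0) fx = 0; if (fx > nx - 1.000001) fx = nx - 1.000001;
    int ix = (int)fx; double tx = fx - ix;
    if (dim == 1) {
      int i0 = ix, i1 = ix + 1;
      bg[0] = (1 - tx) * Gx[i0] + tx * Gx[i1];
      return (1 - tx) * V[i0] + tx * V[i1];
    }
    double fy = (x[1] - gy0) / hy;
    if (fy < 0) fy = 0; if (fy > ny - 1.000001) fy = ny - 1.000001;
    int iy = (int)fy; double ty = fy - iy;
    int i00 = ix * ny + iy, i01 = i00 + 1, i10 = i00 + ny, i11 = i10 + 1;
    double w00 = (1 - tx) * (1 - ty), w01 = (1 - tx) * ty,
           w10 = tx * (1 - ty), w11 = tx * ty;
    bg[0] = w00 * Gx[i00] + w01 * Gx[i01] + w10 * Gx[i10] + w11 * Gx[i11];
    bg[1] = w00 * Gy[i00] + w01 * Gy[i01] + w10 * Gy[i10] + w11 * Gy[i11];
    return w00 * V[i00] + w01 * V[i01] + w10 * V[i10] + w11 * V[i11];
  };

  auto deposit = [&](const double* c, double h) {
    double s0 = sigma[0], s1 = (dim == 2) ? sigma[1] : 1.0;
    int ix0 = std::max(0, (int)((c[0] - 6 * s0 - gx0) / hx));
    int ix1 = std::min(nx - 1, (int)((c[0] + 6 * s0 - gx0) / hx) + 1);
    if (dim == 1) {
      for (int i = ix0; i <= ix1; ++i) {
        double dx = gx0 + i * hx - c[0];
        double e = h * std::exp(-dx * dx / (2 * s0 * s0));
        V[i] += e;
        Gx[i] += e * (-dx / (s0 * s0));
      }
    } else {
      int iy0 = std::max(0, (int)((c[1] - 6 * s1 - gy0) / hy));
      int iy1 = std::min(ny - 1, (int)((c[1] + 6 * s1 - gy0) / hy) + 1);
      for (int i = ix0; i <= ix1; ++i) {
        double dx = gx0 + i * hx - c[0];
        double ex = std::exp(-dx * dx / (2 * s0 * s0));
        for (int j = iy0; j <= iy1; ++j) {
          double dy = gy0 + j * hy - c[1];
          double e = h * ex * std::exp(-dy * dy / (2 * s1 * s1));
          int id = i * ny + j;
          V[id] += e;
          Gx[id] += e * (-dx / (s0 * s0));
          Gy[id] += e * (-dy / (s1 * s1));
        }
      }
    }
  };

  int steps_per_hill = std::max(1, (int)std::round(t_G / dt));
  int n_hills_max = n_steps / steps_per_hill + 2;
  NumericVector h_time(n_hills_max);
  NumericMatrix h_center(n_hills_max, dim);
  NumericVector h_height(n_hills_max);
  int n_hills = 0, walker_turn = 0;

  int n_out = n_steps / out_stride;
  NumericMatrix cv_out(n_out * n_walkers, dim);
  NumericVector t_out(n_out);
  int row = 0;

  double noise = std::sqrt(2.0 * kT * dt / friction);
  double g[2], u, bg[2], wg[2];
  for (long i = 1; i <= n_steps; ++i) {
    for (int w = 0; w < n_walkers; ++w) {
      double* x = &xs[2 * w];
      potential_grad(type, p, dim, x, g, &u);
      double wu = 0.0;
      wg[0] = wg[1] = 0.0;
      wall_grad(dim, &wall_lo[0], &wall_hi[0], wall_k, x, wg, &wu);
      bias_at(x, bg);
      for (int d = 0; d < dim; ++d)
        x[d] += -(g[d] + wg[d] + bg[d]) * dt / friction + noise * norm_rand();
    }
    if (i % steps_per_hill == 0) {
      double* x = &xs[2 * walker_turn];
      double vb = bias_at(x, bg);
      double h = h_nom * std::exp(-vb / kBdT);
      deposit(x, h);
      if (n_hills < n_hills_max) {
        h_time[n_hills] = i * dt;
        for (int d = 0; d < dim; ++d) h_center(n_hills, d) = x[d];
        h_height[n_hills] = h;
        ++n_hills;
      }
      walker_turn = (walker_turn + 1) % n_walkers;
    }
    if (i % out_stride == 0 && row < n_out) {
      t_out[row] = i * dt;
      for (int w = 0; w < n_walkers; ++w)
        for (int d = 0; d < dim; ++d)
          cv_out(row * n_walkers + w, d) = xs[2 * w + d];
      ++row;
    }
  }

  return List::create(
    _["hill_time"] = h_time[Range(0, std::max(0, n_hills - 1))],
    _["hill_center"] = h_center(Range(0, std::max(0, n_hills - 1)), _),
    _["hill_height"] = h_height[Range(0, std::max(0, n_hills - 1))],
    _["n_hills"] = n_hills,
    _["cv"] = cv_out, _["cv_time"] = t_out);
}
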