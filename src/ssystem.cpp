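#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// S-system kinetics: dx_i/dt = alpha_i * prod_j x_j^g_ij - beta_i * prod_j x_j^h_ij.
// All integration is fixed-step classical RK4 with `substeps` internal steps per
// observed interval. States are floored at `eps` after every substep (and stage
// states before each derivative evaluation) so negative kinetic orders stay
// defined; any state above `cap` or non-finite aborts with a divergence signal.

static inline double clampf(double x, double eps) {
  return (x < eps) ? eps : x;
}

static void coupled_deriv(const NumericVector &alpha, const NumericVector &beta,
                          const NumericMatrix &g, const NumericMatrix &h,
                          const std::vector<double> &x, std::vector<double> &dx,
                          double eps) {
  int n = alpha.size();
  std::vector<double> lx(n);
  for (int j = 0; j < n; ++j) lx[j] = std::log(clampf(x[j], eps));
  for (int i = 0; i < n; ++i) {
    double sg = 0.0, sh = 0.0;
    for (int j = 0; j < n; ++j) {
      if (g(i, j) != 0.0) sg += g(i, j) * lx[j];
      if (h(i, j) != 0.0) sh += h(i, j) * lx[j];
    }
    double prod = (alpha[i] > 0.0) ? alpha[i] * std::exp(sg) : 0.0;
    double degr = (beta[i] > 0.0) ? beta[i] * std::exp(sh) : 0.0;
    dx[i] = prod - degr;
  }
}

// [[Rcpp::export]]
NumericMatrix cxx_rk4_coupled(NumericVector alpha, NumericVector beta,
                              NumericMatrix g, NumericMatrix h,
                              NumericVector x0, NumericVector times,
                              int substeps, double eps, double cap) {
  int n = alpha.size(), T = times.size();
  NumericMatrix out(T, n);
  std::vector<double> x(n), xs(n), k1(n), k2(n), k3(n), k4(n);
  for (int j = 0; j < n; ++j) {
    x[j] = clampf(x0[j], eps);
    out(0, j) = x[j];
  }
  bool diverged = false;
  for (int k = 0; k < T - 1 && !diverged; ++k) {
    double dt = (times[k + 1] - times[k]) / substeps;
    for (int s = 0; s < substeps && !diverged; ++s) {
      coupled_deriv(alpha, beta, g, h, x, k1, eps);
      for (int j = 0; j < n; ++j) xs[j] = x[j] + 0.5 * dt * k1[j];
      coupled_deriv(alpha, beta, g, h, xs, k2, eps);
      for (int j = 0; j < n; ++j) xs[j] = x[j] + 0.5 * dt * k2[j];
      coupled_deriv(alpha, beta, g, h, xs, k3, eps);
      for (int j = 0; j < n; ++j) xs[j] = x[j] + dt * k3[j];
      coupled_deriv(alpha, beta, g, h, xs, k4, eps);
      for (int j = 0; j < n; ++j) {
        x[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
        if (!std::isfinite(x[j]) || x[j] > cap) { diverged = true; break; }
        x[j] = clampf(x[j], eps);
      }
    }
    if (!diverged)
      for (int j = 0; j < n; ++j) out(k + 1, j) = x[j];
    else
      for (int kk = k + 1; kk < T; ++kk)
        for (int j = 0; j < n; ++j) out(kk, j) = NA_REAL;
  }
  out.attr("diverged") = diverged;
  return out;
}

// Stage grid shared by the decoupled integrators: interpolated log-profiles of
// every gene at the start/mid points of all RK4 substeps, so per-particle work
// reduces to one log and two exp per stage.
struct StageGrid {
  int T, n, n_grid;
  std::vector<double> logs; // n_grid x n, column-major
  std::vector<double> dt;   // per observed interval, substep width
  int substeps;
};

static StageGrid make_grid(const NumericVector &times, const NumericMatrix &obs,
                           int substeps, double eps) {
  StageGrid gr;
  gr.T = times.size();
  gr.n = obs.ncol();
  gr.substeps = substeps;
  int steps = (gr.T - 1) * substeps;
  gr.n_grid = 2 * steps + 1;
  gr.logs.assign((size_t)gr.n_grid * gr.n, 0.0);
  gr.dt.resize(gr.T - 1);
  for (int k = 0; k < gr.T - 1; ++k)
    gr.dt[k] = (times[k + 1] - times[k]) / substeps;
  // grid point m lies in interval k at fraction f of it
  for (int k = 0; k < gr.T - 1; ++k) {
    for (int s = 0; s < substeps; ++s) {
      int base = 2 * (k * substeps + s);
      for (int half = 0; half < 2; ++half) {
        double f = (s + 0.5 * half) / substeps;
        int m = base + half;
        for (int j = 0; j < gr.n; ++j) {
          double v = obs(k, j) + f * (obs(k + 1, j) - obs(k, j));
          gr.logs[(size_t)j * gr.n_grid + m] = std::log(clampf(v, eps));
        }
      }
    }
  }
  int last = gr.n_grid - 1;
  for (int j = 0; j < gr.n; ++j)
    gr.logs[(size_t)j * gr.n_grid + last] = std::log(clampf(obs(gr.T - 1, j), eps));
  return gr;
}

// Integrate one particle's decoupled gene ODE over the grid. Returns true on
// success, filling pred (length T); false on divergence.
static bool integrate_particle(const double *par, int gene0, const StageGrid &gr,
                               const NumericMatrix &obs, double eps, double cap,
                               std::vector<double> &G, std::vector<double> &H,
                               std::vector<double> &pred) {
  int n = gr.n;
  double alpha = par[0], beta = par[n + 1];
  double gii = par[1 + gene0], hii = par[n + 2 + gene0];
  double cA = (alpha > 0.0) ? std::log(alpha) : -INFINITY;
  double cB = (beta > 0.0) ? std::log(beta) : -INFINITY;
  for (int m = 0; m < gr.n_grid; ++m) { G[m] = cA; H[m] = cB; }
  for (int j = 0; j < n; ++j) {
    if (j == gene0) continue;
    double gj = par[1 + j], hj = par[n + 2 + j];
    const double *lj = &gr.logs[(size_t)j * gr.n_grid];
    if (gj != 0.0)
      for (int m = 0; m < gr.n_grid; ++m) G[m] += gj * lj[m];
    if (hj != 0.0)
      for (int m = 0; m < gr.n_grid; ++m) H[m] += hj * lj[m];
  }
  double x = clampf(obs(0, gene0), eps);
  pred[0] = x;
  for (int k = 0; k < gr.T - 1; ++k) {
    double dt = gr.dt[k];
    for (int s = 0; s < gr.substeps; ++s) {
      int base = 2 * (k * gr.substeps + s);
      double lx, xs, k1, k2, k3, k4;
      lx = std::log(x);
      k1 = std::exp(G[base] + gii * lx) - std::exp(H[base] + hii * lx);
      xs = clampf(x + 0.5 * dt * k1, eps);
      lx = std::log(xs);
      k2 = std::exp(G[base + 1] + gii * lx) - std::exp(H[base + 1] + hii * lx);
      xs = clampf(x + 0.5 * dt * k2, eps);
      lx = std::log(xs);
      k3 = std::exp(G[base + 1] + gii * lx) - std::exp(H[base + 1] + hii * lx);
      xs = clampf(x + dt * k3, eps);
      lx = std::log(xs);
      k4 = std::exp(G[base + 2] + gii * lx) - std::exp(H[base + 2] + hii * lx);
      x += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
      if (!std::isfinite(x) || x > cap) return false;
      x = clampf(x, eps);
    }
    pred[k + 1] = x;
  }
  return true;
}

// [[Rcpp::export]]
NumericVector cxx_decoupled_profile(NumericVector params, int gene0,
                                    NumericVector times, NumericMatrix obs,
                                    int substeps, double eps, double cap) {
  StageGrid gr = make_grid(times, obs, substeps, eps);
  std::vector<double> G(gr.n_grid), H(gr.n_grid), pred(gr.T);
  bool ok = integrate_particle(REAL(params), gene0, gr, obs, eps, cap, G, H, pred);
  NumericVector out(gr.T);
  for (int t = 0; t < gr.T; ++t) out[t] = ok ? pred[t] : NA_REAL;
  out.attr("diverged") = !ok;
  return out;
}

// Fitness of many candidate parameter vectors for one gene: the sum over time
// points of squared relative error against the observed profile; `penalty`
// for divergent candidates.
// [[Rcpp::export]]
NumericVector cxx_fitness_batch(NumericMatrix positions, int gene0,
                                NumericVector times, NumericMatrix obs,
                                int substeps, double eps, double cap,
                                double penalty) {
  StageGrid gr = make_grid(times, obs, substeps, eps);
  int pop = positions.nrow();
  NumericVector fit(pop);
  std::vector<double> G(gr.n_grid), H(gr.n_grid), pred(gr.T), par(positions.ncol());
  for (int p = 0; p < pop; ++p) {
    for (int d = 0; d < positions.ncol(); ++d) par[d] = positions(p, d);
    bool ok = integrate_particle(par.data(), gene0, gr, obs, eps, cap, G, H, pred);
    if (!ok) { fit[p] = penalty; continue; }
    double acc = 0.0;
    for (int t = 0; t < gr.T; ++t) {
      double rel = (pred[t] - obs(t, gene0)) / obs(t, gene0);
      acc += rel * rel;
    }
    fit[p] = std::isfinite(acc) ? acc : penalty;
  }
  return fit;
}
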