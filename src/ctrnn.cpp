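#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Numerically stable logistic function.
static inline double sig(double x) {
  if (x >= 0.0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// sigma'(x) = sigma(x) (1 - sigma(x))
static inline double dsig(double x) {
  double s = sig(x);
  return s * (1.0 - s);
}

// Linear interpolation of a per-neuron knot track at time t.
// Knots are spaced t_noise seconds apart, knot k at time k * t_noise.
static inline double knot_at(const double* kn, int nk, double t_noise, double t) {
  if (nk == 0) return 0.0;
  double pos = t / t_noise;
  int k = (int)std::floor(pos);
  if (k >= nk - 1) return kn[nk - 1];
  if (k < 0) return kn[0];
  double frac = pos - k;
  return kn[k] * (1.0 - frac) + kn[k + 1] * frac;
}

struct Net {
  int M;
  const double* W;   // column-major M x M; W(i,j) = weight from j into i
  const double* tau;
  const double* b;
};

// dx_i/dt = (-x_i + sum_j W(i,j) sig(x_j + b_j) + I_i) / tau_i
static inline void deriv(const Net& net, const double* x, const double* I, double* dx) {
  int M = net.M;
  double s[8];
  for (int j = 0; j < M; ++j) s[j] = sig(x[j] + net.b[j]);
  for (int i = 0; i < M; ++i) {
    double acc = -x[i] + I[i];
    for (int j = 0; j < M; ++j) acc += net.W[i + j * M] * s[j];
    dx[i] = acc / net.tau[i];
  }
}

// Evaluate the external input vector at time t (noise track + odor drive).
static inline void input_at(int M, const double* knots, int nk, double t_noise,
                            const double* w_odor, double u, double t, double* I) {
  for (int i = 0; i < M; ++i) {
    double n = (nk > 0) ? knot_at(knots + (size_t)i * nk, nk, t_noise, t) : 0.0;
    I[i] = n + (w_odor ? w_odor[i] * u : 0.0);
  }
}

// One RK4 step from time t with stimulus value u held constant over the step.
static inline bool rk4_step(const Net& net, double* x, double t, double dt,
                            const double* knots, int nk, double t_noise,
                            const double* w_odor, double u) {
  int M = net.M;
  double k1[8], k2[8], k3[8], k4[8], xt[8], I[8];

  input_at(M, knots, nk, t_noise, w_odor, u, t, I);
  deriv(net, x, I, k1);
  input_at(M, knots, nk, t_noise, w_odor, u, t + 0.5 * dt, I);
  for (int i = 0; i < M; ++i) xt[i] = x[i] + 0.5 * dt * k1[i];
  deriv(net, xt, I, k2);
  for (int i = 0; i < M; ++i) xt[i] = x[i] + 0.5 * dt * k2[i];
  deriv(net, xt, I, k3);
  input_at(M, knots, nk, t_noise, w_odor, u, t + dt, I);
  for (int i = 0; i < M; ++i) xt[i] = x[i] + dt * k3[i];
  deriv(net, xt, I, k4);

  for (int i = 0; i < M; ++i) {
    x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if (!std::isfinite(x[i])) return false;
  }
  return true;
}

// [[Rcpp::export]]
List cpp_ctrnn_sim(NumericMatrix W, NumericVector tau, NumericVector b,
                   NumericVector x0, double dt, int n_steps,
                   NumericMatrix knots, double t_noise,
                   NumericVector w_odor, NumericVector u,
                   bool keep_states) {
  int M = tau.size();
  if (M > 8) stop("at most 8 neurons supported");
  Net net{M, W.begin(), tau.begin(), b.begin()};
  int nk = knots.ncol();
  // knots arrive as n_neuron rows x nk cols; transpose to per-neuron contiguous
  std::vector<double> kn((size_t)M * nk);
  for (int i = 0; i < M; ++i)
    for (int k = 0; k < nk; ++k) kn[(size_t)i * nk + k] = knots(i, k);
  const double* w_od = w_odor.size() ? w_odor.begin() : nullptr;

  double x[8];
  for (int i = 0; i < M; ++i) x[i] = x0[i];

  NumericVector out(n_steps + 1);
  NumericMatrix states(keep_states ? n_steps + 1 : 0, keep_states ? M : 0);
  bool finite = true;

  out[0] = sig(x[0] + net.b[0]);
  if (keep_states) for (int i = 0; i < M; ++i) states(0, i) = x[i];

  for (int s = 0; s < n_steps; ++s) {
    double us = (u.size() > 0) ? u[s] : 0.0;
    if (!rk4_step(net, x, s * dt, dt, kn.data(), nk, t_noise, w_od, us)) {
      finite = false;
      for (int r = s + 1; r <= n_steps; ++r) out[r] = NA_REAL;
      break;
    }
    out[s + 1] = sig(x[0] + net.b[0]);
    if (keep_states) for (int i = 0; i < M; ++i) states(s + 1, i) = x[i];
  }

  NumericVector xf(M);
  for (int i = 0; i < M; ++i) xf[i] = x[i];
  return List::create(_["out"] = out, _["states"] = states,
                      _["finite"] = finite, _["x_final"] = xf);
}

// Jacobian at x: J(i,j) = W(i,j) sig'(x_j + b_j)/tau_i - delta_ij / tau_i
static inline void jac_at(const Net& net, const double* x, double* J) {
  int M = net.M;
  double d[8];
  for (int j = 0; j < M; ++j) d[j] = dsig(x[j] + net.b[j]);
  for (int j = 0; j < M; ++j)
    for (int i = 0; i < M; ++i) {
      double v = net.W[i + j * M] * d[j] / net.tau[i];
      if (i == j) v -= 1.0 / net.tau[i];
      J[i + j * M] = v;
    }
}

// [[Rcpp::export]]
List cpp_lyapunov(NumericMatrix W, NumericVector tau, NumericVector b,
                  NumericVector x0, double dt, int n_steps, int t_ortho) {
  int M = tau.size();
  if (M > 8) stop("at most 8 neurons supported");
  Net net{M, W.begin(), tau.begin(), b.begin()};
  double zeroI[8] = {0, 0, 0, 0, 0, 0, 0, 0};

  double x[8];
  for (int i = 0; i < M; ++i) x[i] = x0[i];
  // perturbation matrix, columns are perturbation vectors; start at identity
  std::vector<double> D((size_t)M * M, 0.0);
  for (int i = 0; i < M; ++i) D[i + i * M] = 1.0;

  std::vector<double> sum_log(M, 0.0);
  double trace_acc = 0.0;

  std::vector<double> J(M * M), k1(M * M), k2(M * M), k3(M * M), k4(M * M), Dt(M * M);
  double kx1[8], kx2[8], kx3[8], kx4[8], xt[8];

  auto matmul = [&](const double* A, const double* B, double* C) {
    for (int j = 0; j < M; ++j)
      for (int i = 0; i < M; ++i) {
        double acc = 0.0;
        for (int l = 0; l < M; ++l) acc += A[i + l * M] * B[l + j * M];
        C[i + j * M] = acc;
      }
  };

  for (int s = 0; s < n_steps; ++s) {
    // stage 1
    jac_at(net, x, J.data());
    for (int i = 0; i < M; ++i) trace_acc += J[i + i * M] * dt;
    deriv(net, x, zeroI, kx1);
    matmul(J.data(), D.data(), k1.data());
    // stage 2
    for (int i = 0; i < M; ++i) xt[i] = x[i] + 0.5 * dt * kx1[i];
    jac_at(net, xt, J.data());
    deriv(net, xt, zeroI, kx2);
    for (size_t i = 0; i < Dt.size(); ++i) Dt[i] = D[i] + 0.5 * dt * k1[i];
    matmul(J.data(), Dt.data(), k2.data());
    // stage 3
    for (int i = 0; i < M; ++i) xt[i] = x[i] + 0.5 * dt * kx2[i];
    jac_at(net, xt, J.data());
    deriv(net, xt, zeroI, kx3);
    for (size_t i = 0; i < Dt.size(); ++i) Dt[i] = D[i] + 0.5 * dt * k2[i];
    matmul(J.data(), Dt.data(), k3.data());
    // stage 4
    for (int i = 0; i < M; ++i) xt[i] = x[i] + dt * kx3[i];
    jac_at(net, xt, J.data());
    deriv(net, xt, zeroI, kx4);
    for (size_t i = 0; i < Dt.size(); ++i) Dt[i] = D[i] + dt * k3[i];
    matmul(J.data(), Dt.data(), k4.data());

    for (int i = 0; i < M; ++i)
      x[i] += dt / 6.0 * (kx1[i] + 2.0 * kx2[i] + 2.0 * kx3[i] + kx4[i]);
    for (size_t i = 0; i < D.size(); ++i)
      D[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);

    if ((s + 1) % t_ortho == 0 || s == n_steps - 1) {
      // modified Gram-Schmidt on the columns of D; accumulate log norms
      for (int j = 0; j < M; ++j) {
        for (int l = 0; l < j; ++l) {
          double dot = 0.0;
          for (int i = 0; i < M; ++i) dot += D[i + l * M] * D[i + j * M];
          for (int i = 0; i < M; ++i) D[i + j * M] -= dot * D[i + l * M];
        }
        double nrm = 0.0;
        for (int i = 0; i < M; ++i) nrm += D[i + j * M] * D[i + j * M];
        nrm = std::sqrt(nrm);
        sum_log[j] += std::log(nrm);
        for (int i = 0; i < M; ++i) D[i + j * M] /= nrm;
      }
    }
  }

  double total_time = n_steps * dt;
  NumericVector lam(M), xf(M);
  for (int i = 0; i < M; ++i) lam[i] = sum_log[i] / total_time;
  for (int i = 0; i < M; ++i) xf[i] = x[i];
  return List::create(_["exponents"] = lam,
                      _["trace_avg"] = trace_acc / total_time,
                      _["x_final"] = xf);
}

// Run one noisy trajectory and accumulate cell visits of its projection
// onto neuron pair (ax_i, ax_j) into `counts` (modified in place).
// [[Rcpp::export]]
int cpp_density_accumulate(NumericMatrix W, NumericVector tau, NumericVector b,
                           NumericVector x0, double dt, int n_steps,
                           NumericMatrix knots, double t_noise,
                           NumericVector w_odor, NumericVector u,
                           IntegerMatrix counts, int ax_i, int ax_j,
                           double lo, double hi) {
  int M = tau.size();
  if (M > 8) stop("at most 8 neurons supported");
  Net net{M, W.begin(), tau.begin(), b.begin()};
  int nk = knots.ncol();
  std::vector<double> kn((size_t)M * nk);
  for (int i = 0; i < M; ++i)
    for (int k = 0; k < nk; ++k) kn[(size_t)i * nk + k] = knots(i, k);
  const double* w_od = w_odor.size() ? w_odor.begin() : nullptr;

  int G = counts.nrow();
  double span = hi - lo;
  double x[8];
  for (int i = 0; i < M; ++i) x[i] = x0[i];
  int recorded = 0;

  for (int s = 0; s <= n_steps; ++s) {
    double xi = x[ax_i], xj = x[ax_j];
    int ci = (int)std::floor((xi - lo) / span * G);
    int cj = (int)std::floor((xj - lo) / span * G);
    if (ci >= 0 && ci < G && cj >= 0 && cj < G) {
      counts(ci, cj) += 1;
      ++recorded;
    }
    if (s == n_steps) break;
    double us = (u.size() > 0) ? u[s] : 0.0;
    if (!rk4_step(net, x, s * dt, dt, kn.data(), nk, t_noise, w_od, us)) break;
  }
  return recorded;
}

// Count switches between stable equilibria along one noisy trajectory.
// The label changes only when the state enters the hysteresis ball of
// radius `radius` around a different stable point.
// [[Rcpp::export]]
int cpp_switch_count(NumericMatrix W, NumericVector tau, NumericVector b,
                     NumericVector x0, double dt, int n_steps,
                     NumericMatrix knots, double t_noise,
                     NumericMatrix stable_pts, double radius) {
  int M = tau.size();
  if (M > 8) stop("at most 8 neurons supported");
  Net net{M, W.begin(), tau.begin(), b.begin()};
  int nk = knots.ncol();
  std::vector<double> kn((size_t)M * nk);
  for (int i = 0; i < M; ++i)
    for (int k = 0; k < nk; ++k) kn[(size_t)i * nk + k] = knots(i, k);

  int n_eq = stable_pts.nrow();
  double x[8];
  for (int i = 0; i < M; ++i) x[i] = x0[i];

  auto nearest = [&](const double* xx) {
    int best = 0;
    double bd = R_PosInf;
    for (int e = 0; e < n_eq; ++e) {
      double d2 = 0.0;
      for (int i = 0; i < M; ++i) {
        double diff = xx[i] - stable_pts(e, i);
        d2 += diff * diff;
      }
      if (d2 < bd) { bd = d2; best = e; }
    }
    return best;
  };

  int label = nearest(x);
  int switches = 0;
  double r2 = radius * radius;

  for (int s = 0; s < n_steps; ++s) {
    if (!rk4_step(net, x, s * dt, dt, kn.data(), nk, t_noise, nullptr, 0.0)) break;
    for (int e = 0; e < n_eq; ++e) {
      if (e == label) continue;
      double d2 = 0.0;
      for (int i = 0; i < M; ++i) {
        double diff = x[i] - stable_pts(e, i);
        d2 += diff * diff;
      }
      if (d2 < r2) { label = e; ++switches; break; }
    }
  }
  return switches;
}

// Solve A x = rhs (M x M, column-major) by Gaussian elimination with
// partial pivoting; returns false if singular.
static bool solve_lin(int M, double* A, double* rhs) {
  for (int c = 0; c < M; ++c) {
    int piv = c;
    double best = std::fabs(A[c + c * M]);
    for (int r = c + 1; r < M; ++r) {
      double v = std::fabs(A[r + c * M]);
      if (v > best) { best = v; piv = r; }
    }
    if (best < 1e-14) return false;
    if (piv != c) {
      for (int j = 0; j < M; ++j) std::swap(A[c + j * M], A[piv + j * M]);
      std::swap(rhs[c], rhs[piv]);
    }
    for (int r = c + 1; r < M; ++r) {
      double f = A[r + c * M] / A[c + c * M];
      for (int j = c; j < M; ++j) A[r + j * M] -= f * A[c + j * M];
      rhs[r] -= f * rhs[c];
    }
  }
  for (int r = M - 1; r >= 0; --r) {
    double acc = rhs[r];
    for (int j = r + 1; j < M; ++j) acc -= A[r + j * M] * rhs[j];
    rhs[r] = acc / A[r + r * M];
  }
  return true;
}

// Multi-start damped Newton iteration on the noiseless CTRNN field.
// Returns converged roots (one per row), not deduplicated.
// [[Rcpp::export]]
NumericMatrix cpp_newton_roots(NumericMatrix W, NumericVector tau,
                               NumericVector b, NumericMatrix starts,
                               double tol, int max_iter) {
  int M = tau.size();
  if (M > 8) stop("at most 8 neurons supported");
  Net net{M, W.begin(), tau.begin(), b.begin()};
  double zeroI[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  std::vector<double> found;
  double x[8], fx[8], fn[8], xn[8], step[8];
  std::vector<double> J(M * M);

  for (int s0 = 0; s0 < starts.nrow(); ++s0) {
    for (int i = 0; i < M; ++i) x[i] = starts(s0, i);
    deriv(net, x, zeroI, fx);
    double nf = 0;
    for (int i = 0; i < M; ++i) nf += fx[i] * fx[i];
    nf = std::sqrt(nf);
    bool ok = false;
    for (int it = 0; it < max_iter; ++it) {
      if (nf < tol) { ok = true; break; }
      jac_at(net, x, J.data());
      for (int i = 0; i < M; ++i) step[i] = -fx[i];
      std::vector<double> A(J);
      if (!solve_lin(M, A.data(), step)) break;
      double lambda = 1.0;
      bool moved = false;
      while (lambda > 1e-10) {
        double nn = 0;
        for (int i = 0; i < M; ++i) xn[i] = x[i] + lambda * step[i];
        deriv(net, xn, zeroI, fn);
        for (int i = 0; i < M; ++i) nn += fn[i] * fn[i];
        nn = std::sqrt(nn);
        if (std::isfinite(nn) && nn < nf) {
          for (int i = 0; i < M; ++i) { x[i] = xn[i]; fx[i] = fn[i]; }
          nf = nn;
          moved = true;
          break;
        }
        lambda *= 0.5;
      }
      if (!moved) break;
    }
    if (ok || nf < tol) for (int i = 0; i < M; ++i) found.push_back(x[i]);
  }
  int n = found.size() / M;
  NumericMatrix roots(n, M);
  for (int r = 0; r < n; ++r)
    for (int i = 0; i < M; ++i) roots(r, i) = found[(size_t)r * M + i];
  return roots;
}

// Evaluate K virtual flies with Gaussian knot noise and pool their bout
// durations. Uses R's RNG (initial conditions round-robin over `centers`
// plus unit Gaussian jitter, fresh knots per fly, random half selection),
// so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_basal_eval(NumericMatrix W, NumericVector tau, NumericVector b,
                    NumericVector w_noise, double thr, double t_noise,
                    NumericMatrix centers, int k_eval, double dt,
                    int transient_steps, int record_steps, bool split) {
  int M = tau.size();
  if (M > 8) stop("at most 8 neurons supported");
  Net net{M, W.begin(), tau.begin(), b.begin()};
  std::vector<double> walk, stat;
  bool finite = true;
  int n_centers = centers.nrow();

  for (int k = 0; k < k_eval && finite; ++k) {
    double x[8];
    int c = k % n_centers;
    for (int i = 0; i < M; ++i) x[i] = centers(c, i) + R::norm_rand();
    int offset = (split && R::unif_rand() < 0.5) ? record_steps : 0;
    int total = transient_steps + (split ? 2 : 1) * record_steps;
    int nk = (int)std::floor(total * dt / t_noise) + 2;
    std::vector<double> kn((size_t)M * nk);
    for (int i = 0; i < M; ++i)
      for (int q = 0; q < nk; ++q)
        kn[(size_t)i * nk + q] = w_noise[i] * R::norm_rand();

    int start = transient_steps + offset;
    int stop_at = start + record_steps;
    int run_len = 0;
    int cur = -1;
    for (int s = 0; s < stop_at; ++s) {
      if (s >= start) {
        int st = sig(x[0] + net.b[0]) >= thr ? 1 : 0;
        if (st == cur) {
          ++run_len;
        } else {
          if (cur >= 0) (cur ? walk : stat).push_back(run_len * dt);
          cur = st;
          run_len = 1;
        }
      }
      if (!rk4_step(net, x, s * dt, dt, kn.data(), nk, t_noise, nullptr, 0.0)) {
        finite = false;
        break;
      }
    }
    if (cur >= 0) (cur ? walk : stat).push_back(run_len * dt);
  }
  return List::create(_["walk"] = wrap(walk), _["stat"] = wrap(stat),
                      _["finite"] = finite);
}
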