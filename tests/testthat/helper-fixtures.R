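# Shared fixtures, built in code at test time.

# Small bursty synthetic target population (10 virtual flies, 5 min each).
fixture_target_population <- function(seed = 7, duration = 300, n_flies = 10) {
  spec <- synthetic_population_spec(n_flies = n_flies, duration = duration,
                                    seed = seed)
  generate_population(spec)
}

fixture_target_intervals <- function(...) {
  extract_intervals(classify_locomotion(fixture_target_population(...)))
}

# A one-neuron bistable subthreshold model: x' = -x + 8 sigma(x - 4).
# Stable states near 0.17 (down) and 7.83 (up); the up-state output
# sigma(7.83 - 4) ~ 0.979 stays below the 0.985 walking threshold, so
# walking requires fluctuations (stochastic-resonance regime).
fixture_bistable_model <- function(w_noise = 1.2, thr = 0.985, w_odor = 1) {
  ctrnn_model(w = matrix(8, 1, 1), tau = 1, b = -4, w_noise = w_noise,
              w_odor = w_odor, thr = thr, t_noise = 0.1)
}

# The steeper benchmark x' = -x + 10 sigma(x - 5), whose middle root sits
# exactly at x = 5 where sigma' = 1/4 (Jacobian 1.5 by hand).
fixture_benchmark_10 <- function() {
  ctrnn_model(w = matrix(10, 1, 1), tau = 1, b = -5)
}

# Bisection root finder for scalar fixed-point equations, used as an
# independent oracle against the Newton-based equilibrium search.
bisect_root <- function(f, lo, hi, tol = 1e-12) {
  flo <- f(lo)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol || (hi - lo) < tol) return(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid
      flo <- fm
    } else {
      hi <- mid
    }
  }
  mid
}
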