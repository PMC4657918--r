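#' Particle swarm configuration
#'
#' Standard global-best PSO settings: `c1 = c2 = 2`, 50 particles, 200
#' iterations, and a linearly decaying inertia `omega(t) = 0.9 - 0.7 t / T`
#' favouring global search early and local refinement late.
#'
#' @param n_particles Swarm size (default 50).
#' @param max_iter Iteration budget `T` (default 200); the initial
#'   evaluation counts as iteration 1.
#' @param c1,c2 Cognitive and social acceleration coefficients.
#' @param seed Master RNG seed; every objective evaluation receives a seed
#'   mixed deterministically from it, the particle id and the iteration.
#' @return A `fw_swarm_config` list.
#' @export
swarm_config <- function(n_particles = 50, max_iter = 200, c1 = 2, c2 = 2,
                         seed = 1) {
  structure(list(n_particles = n_particles, max_iter = max_iter,
                 c1 = c1, c2 = c2, seed = seed),
            class = "fw_swarm_config")
}

#' PSO inertia schedule
#'
#' `omega(t) = 0.9 - 0.7 t / T`: 0.9 at the start of the run, 0.2 at the
#' final iteration.
#'
#' @param t Iteration index (0-based).
#' @param max_iter Maximum number of iterations `T`.
#' @return Inertia weight.
#' @export
pso_inertia <- function(t, max_iter) {
  0.9 - 0.7 * t / max_iter
}

# Deterministic per-evaluation seed below 2^31.
mix_seed <- function(master, particle, iter) {
  ((master %% 100000) * 20011 + particle * 1009 + iter * 97) %% 2147483647L
}

#' Global-best particle swarm minimisation
#'
#' Positions start uniform in the box with zero velocities; each iteration
#' updates velocities with the inertia schedule and the cognitive/social
#' pulls, clips positions to the box (zeroing the clipped velocity
#' component), and re-evaluates. Non-finite objective values are treated as
#' worst-possible so divergent parameter sets are discarded rather than
#' crashing the search. Fully reproducible given the config seed.
#'
#' @param objective `function(par, seed)` returning a scalar score.
#' @param lower,upper Box constraints (equal-length numeric vectors).
#' @param config `fw_swarm_config`.
#' @return A `fw_pso` list: `par`, `value`, `trace` (per-iteration best),
#'   `n_evals`, `config`.
#' @export
pso_minimize <- function(objective, lower, upper, config = swarm_config()) {
  d <- length(lower)
  if (d == 0 || length(upper) != d || any(upper <= lower)) {
    abort("invalid box constraints.")
  }
  n <- config$n_particles
  t_max <- config$max_iter
  set.seed(config$seed)
  X <- matrix(runif(n * d), n, d)
  X <- sweep(sweep(X, 2, upper - lower, `*`), 2, lower, `+`)
  V <- matrix(0, n, d)

  eval_all <- function(X, iter) {
    vapply(seq_len(n), function(i) {
      v <- objective(X[i, ], seed = mix_seed(config$seed, i, iter))
      if (!is.finite(v)) .Machine$double.xmax else v
    }, numeric(1))
  }

  val <- eval_all(X, 1L)
  P <- X
  p_val <- val
  g_idx <- which.min(p_val)
  G <- P[g_idx, ]
  g_val <- p_val[g_idx]
  trace <- tibble(iter = 1L, best = g_val)
  n_evals <- n

  for (t in seq_len(t_max - 1L) + 1L) {
    omega <- pso_inertia(t - 1L, t_max)
    r1 <- matrix(runif(n * d), n, d)
    r2 <- matrix(runif(n * d), n, d)
    V <- omega * V + config$c1 * r1 * (P - X) +
      config$c2 * r2 * (matrix(G, n, d, byrow = TRUE) - X)
    X <- X + V
    for (j in seq_len(d)) {
      lo <- X[, j] < lower[j]
      hi <- X[, j] > upper[j]
      X[lo, j] <- lower[j]
      X[hi, j] <- upper[j]
      V[lo | hi, j] <- 0
    }
    val <- eval_all(X, t)
    n_evals <- n_evals + n
    improve <- val < p_val
    P[improve, ] <- X[improve, , drop = FALSE]
    p_val[improve] <- val[improve]
    if (min(p_val) < g_val) {
      g_idx <- which.min(p_val)
      G <- P[g_idx, ]
      g_val <- p_val[g_idx]
    }
    trace <- dplyr::bind_rows(trace, tibble(iter = t, best = g_val))
  }
  structure(list(par = G, value = g_val, trace = trace, n_evals = n_evals,
                 config = config),
            class = "fw_pso")
}

#' Parameter box for Stage-1 CTRNN optimisation
#'
#' Layout: `M^2` weights in \[-20, 20\], `M` time constants in \[0.05, 50\],
#' `M` biases in \[-10, 10\], optionally `M` noise gains in
#' \[0, `w_noise_max`\], the output threshold in \[0.01, 0.99\] and the noise
#' knot interval in \[0.01, 1\].
#'
#' @param m Network size (1-5).
#' @param with_noise Include per-neuron noise gains.
#' @param w_noise_max Upper bound of the noise gains.
#' @return List with `lower` and `upper` named vectors.
#' @export
ctrnn_param_box <- function(m, with_noise = TRUE, w_noise_max = 10) {
  nm_w <- paste0("w", rep(seq_len(m), m), rep(seq_len(m), each = m))
  lower <- c(setNames(rep(-20, m * m), nm_w),
             setNames(rep(0.05, m), paste0("tau", seq_len(m))),
             setNames(rep(-10, m), paste0("b", seq_len(m))))
  upper <- c(setNames(rep(20, m * m), nm_w),
             setNames(rep(50, m), paste0("tau", seq_len(m))),
             setNames(rep(10, m), paste0("b", seq_len(m))))
  if (with_noise) {
    lower <- c(lower, setNames(rep(0, m), paste0("w_noise", seq_len(m))))
    upper <- c(upper, setNames(rep(w_noise_max, m), paste0("w_noise", seq_len(m))))
  }
  lower <- c(lower, thr = 0.01, t_noise = 0.01)
  upper <- c(upper, thr = 0.99, t_noise = 1)
  list(lower = lower, upper = upper)
}

# Decode a Stage-1 parameter vector into a model.
decode_basal_params <- function(par, m, with_noise = TRUE) {
  w <- matrix(par[seq_len(m * m)], m, m)
  off <- m * m
  tau <- par[off + seq_len(m)]
  b <- par[off + m + seq_len(m)]
  off <- off + 2 * m
  if (with_noise) {
    w_noise <- par[off + seq_len(m)]
    off <- off + m
  } else {
    w_noise <- rep(0, m)
  }
  ctrnn_model(w = w, tau = tau, b = b, w_noise = w_noise,
              thr = par[off + 1], t_noise = par[off + 2])
}

#' Stage-1 objective: normalised cost of a parameter vector
#'
#' Builds the objective minimised during basal model discovery: decode the
#' parameter vector into a CTRNN, simulate `k_eval` virtual flies (each
#' twice the recording duration with a random half kept, after a discarded
#' transient), pool their walking and stationary bouts, and score them
#' against the target histograms. The scale factor R is the ratio of target
#' to simulated data volume (0.1 for the study's 100 trials against 10
#' flies). Divergent parameter sets receive a worst-case score.
#'
#' @param target `fw_target` from [build_target_histograms()].
#' @param m Network size.
#' @param with_noise Whether the parameter vector includes noise gains.
#' @param k_eval Virtual flies per evaluation (study setting 100).
#' @param record_duration Recorded seconds per fly (study setting 1800).
#' @param transient Discarded transient (s).
#' @param noise `fw_noise` statistics of the fluctuation source.
#' @param norm_mode Degenerate-fly normalisation convention.
#' @param split_halves Simulate twice the recording and keep a random half
#'   (the study protocol); turn off for short scaled-down runs.
#' @param dt Integration step (s).
#' @return `function(par, seed)` returning the normalised cost F; the scale
#'   factor R is attached as attribute `"scale"`.
#' @export
make_basal_objective <- function(target, m, with_noise = TRUE, k_eval = 100,
                                 record_duration = 1800, transient = 300,
                                 noise = noise_spec("gaussian"),
                                 norm_mode = "always_walking",
                                 split_halves = TRUE, dt = 0.01) {
  force(target)
  scale <- target$total_time / (k_eval * record_duration)
  obj <- function(par, seed) {
    model <- tryCatch(decode_basal_params(par, m, with_noise),
                      error = function(e) NULL)
    if (is.null(model)) return(.Machine$double.xmax)
    set.seed(seed)
    res <- tryCatch({
      eq <- find_equilibria(model, n_grid = 3, n_random = 20, seed = seed)
      m_cols <- paste0("x", seq_len(m))
      centers <- if (nrow(eq)) as.matrix(eq[, m_cols, drop = FALSE])
                 else matrix(0, 1, m)
      sims <- if (noise$kind == "gaussian") {
        ev <- cpp_basal_eval(model$w, model$tau, model$b, model$w_noise,
                             model$thr, model$t_noise, centers, k_eval, dt,
                             round(transient / dt), round(record_duration / dt),
                             split_halves)
        if (!ev$finite) return(.Machine$double.xmax)
        tibble(state = rep(c("walking", "stationary"),
                           c(length(ev$walk), length(ev$stat))),
               duration = c(ev$walk, ev$stat))
      } else {
        purrr::map_dfr(seq_len(k_eval), function(k) {
          fly <- run_virtual_fly(model, record_duration = record_duration,
                                 noise = noise, transient = transient,
                                 split_halves = split_halves,
                                 equilibria = eq, dt = dt)
          extract_intervals(fly, sample_rate = 1 / dt)
        })
      }
      cost_function(sims, target, scale = scale, k_trials = k_eval,
                    trial_duration = record_duration, norm_mode = norm_mode)$f
    }, error = function(e) NA_real_)
    if (!is.finite(res)) .Machine$double.xmax else res
  }
  attr(obj, "scale") <- scale
  obj
}

#' Discover CTRNN models matching target bout statistics
#'
#' Repeats Stage-1 PSO runs across network sizes and fluctuation conditions,
#' persisting each run's best model and score. Rerunning with the same seed
#' reproduces every score exactly.
#'
#' @param target `fw_target`.
#' @param sizes Network sizes to search (subset of 1-5).
#' @param with_noise Conditions to run (`TRUE` = fluctuation-driven).
#' @param n_runs PSO runs per size x condition (study setting 50).
#' @param config `fw_swarm_config` template; each run gets a derived seed.
#' @param ledger_path Optional JSONL path appending one record per run.
#' @param ... Passed to [make_basal_objective()] (e.g. `k_eval`,
#'   `record_duration`, `transient`).
#' @param seed Master seed.
#' @return Tibble with columns `size`, `with_noise`, `run`, `f` and a
#'   `model` list column of `fw_model` objects.
#' @export
discover_models <- function(target, sizes = 1:5, with_noise = c(FALSE, TRUE),
                            n_runs = 50, config = swarm_config(),
                            ledger_path = NULL, ..., seed = 1) {
  grid <- expand.grid(size = sizes, with_noise = with_noise, run = seq_len(n_runs))
  purrr::pmap_dfr(grid, function(size, with_noise, run) {
    box <- ctrnn_param_box(size, with_noise = with_noise)
    obj <- make_basal_objective(target, m = size, with_noise = with_noise, ...)
    cfg <- config
    cfg$seed <- mix_seed(seed, size * 2L + as.integer(with_noise), run)
    fit <- pso_minimize(obj, box$lower, box$upper, cfg)
    model <- decode_basal_params(fit$par, size, with_noise)
    if (!is.null(ledger_path)) {
      rec <- list(size = size, with_noise = with_noise, run = run,
                  f = fit$value, seed = cfg$seed,
                  model = jsonlite::fromJSON(model_to_json(model)))
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
          file = ledger_path, append = TRUE)
    }
    tibble(size = size, with_noise = with_noise, run = run, f = fit$value,
           model = list(model))
  })
}

#' Population locomotor-frequency curve of a model under the odor protocol
#'
#' Simulates `n_virtual` flies through the odor impulse protocol (basal /
#' odor-on / post-odor), averages the thresholded output across flies,
#' resamples the curve to `out_rate`, and smooths it with a centred moving
#' average.
#'
#' @param model `fw_model` (its `w_odor` and `thr` are used).
#' @param n_virtual Number of virtual flies.
#' @param protocol Named durations in seconds: `basal`, `odor`, `post`.
#' @param amplitude Odor stimulus amplitude.
#' @param noise `fw_noise` or `NULL` for the fluctuation-free condition.
#' @param transient Discarded transient (s).
#' @param equilibria Optional precomputed equilibria.
#' @param out_rate Output sample rate in Hz (default 20, the camera rate).
#' @param smooth Moving-average window (s).
#' @param seed Optional RNG seed.
#' @param dt Integration step (s).
#' @return Tibble with columns `time` and `freq`.
#' @export
odor_frequency_curve <- function(model, n_virtual = 200,
                                 protocol = c(basal = 60, odor = 30, post = 120),
                                 amplitude = 1, noise = noise_spec("gaussian"),
                                 transient = 300, equilibria = NULL,
                                 out_rate = 20, smooth = 1, seed = NULL,
                                 dt = 0.01) {
  if (!is.null(seed)) set.seed(seed)
  total <- sum(protocol)
  stim <- stimulus_schedule(protocol[["basal"]],
                            protocol[["basal"]] + protocol[["odor"]],
                            amplitude = amplitude)
  eq <- equilibria %||% find_equilibria(model, n_grid = 3, n_random = 20)
  n_steps <- round(total / dt)
  walk_sum <- numeric(n_steps + 1L)
  ics <- sample_initial_conditions(model, n_virtual, equilibria = eq)
  for (k in seq_len(n_virtual)) {
    x0 <- ics[k, ]
    pre <- sim_raw(model, transient, x0, noise, NULL, dt, keep_states = FALSE)
    if (!pre$finite) abort("virtual fly diverged during the transient.")
    res <- sim_raw(model, total, pre$x_final, noise, stim, dt, keep_states = FALSE)
    if (!res$finite) abort("virtual fly diverged during the protocol.")
    walk_sum <- walk_sum + (res$out >= model$thr)
  }
  freq <- walk_sum / n_virtual
  stride <- max(1L, round(1 / (out_rate * dt)))
  idx <- seq(1L, n_steps + 1L, by = stride)
  out <- tibble(time = (idx - 1L) * dt, freq = freq[idx])
  if (smooth > 0) out$freq <- smooth_series(out$freq, max(1L, round(smooth * out_rate)))
  out
}

#' Stage-2 fit: odor gains and threshold against an odor-response curve
#'
#' Freezes all Stage-1 parameters (weights, time constants, biases, noise
#' gains) and optimises only the per-neuron odor input gains and the output
#' threshold so that the model's population locomotor-frequency curve
#' matches a target curve in root-mean-square error. Because the frozen
#' dynamics do not depend on the free parameters, the model's equilibria are
#' computed once and reused.
#'
#' @param model `fw_model` with Stage-1 parameters fixed.
#' @param target_curve Tibble (`time`, `freq`) on the protocol grid.
#' @param config `fw_swarm_config` for the reduced search (defaults to a
#'   15-particle, 30-iteration swarm).
#' @param n_virtual Virtual flies per evaluation (study setting 200).
#' @param w_odor_box Bounds of each odor gain.
#' @param ... Passed to [odor_frequency_curve()] (e.g. `protocol`,
#'   `transient`, `noise`, `smooth`).
#' @return A `fw_odor_fit` list: `model` (with fitted `w_odor`, `thr`),
#'   `w_odor`, `thr`, `rmse`, `pso`, and the frozen Stage-1 parameters.
#' @export
fit_odor_response <- function(model, target_curve,
                              config = swarm_config(n_particles = 15,
                                                    max_iter = 30),
                              n_virtual = 200, w_odor_box = c(-20, 20), ...) {
  m <- model$m
  extra <- list(...)
  proto <- extra$protocol %||% c(basal = 60, odor = 30, post = 120)
  out_rate <- extra$out_rate %||% 20
  want <- round(sum(proto) * out_rate) + 1L
  if (nrow(target_curve) != want) {
    abort(sprintf("target curve has %d samples; the protocol implies %d.",
                  nrow(target_curve), want))
  }
  eq <- find_equilibria(model)
  frozen <- model[c("w", "tau", "b", "w_noise", "t_noise")]
  lower <- c(rep(w_odor_box[1], m), 0.01)
  upper <- c(rep(w_odor_box[2], m), 0.99)
  objective <- function(par, seed) {
    cand <- model
    cand$w_odor <- par[seq_len(m)]
    cand$thr <- par[m + 1]
    curve <- tryCatch(
      rlang::exec(odor_frequency_curve, cand, n_virtual = n_virtual,
                  equilibria = eq, seed = seed, !!!extra),
      error = function(e) NULL)
    if (is.null(curve)) return(.Machine$double.xmax)
    sqrt(mean((curve$freq - target_curve$freq)^2))
  }
  fit <- pso_minimize(objective, lower, upper, config)
  fitted <- model
  fitted$w_odor <- fit$par[seq_len(m)]
  fitted$thr <- fit$par[m + 1]
  stopifnot(identical(fitted[c("w", "tau", "b", "w_noise", "t_noise")], frozen))
  structure(list(model = fitted, w_odor = fitted$w_odor, thr = fitted$thr,
                 rmse = fit$value, pso = fit, frozen = frozen),
            class = "fw_odor_fit")
}

#' Peak locomotor frequency as a function of stimulus amplitude
#'
#' Runs the odor impulse protocol at each stimulus amplitude, with and/or
#' without fluctuations, and records the maximum of the population
#' locomotor-frequency curve; with fluctuations the response is graded from
#' zero amplitude, while a noiseless subthreshold model shows a hard
#' threshold.
#'
#' @param model `fw_model`.
#' @param amplitudes Stimulus amplitudes to sweep.
#' @param with_noise Conditions to run.
#' @param n_rep Repetitions per amplitude (study setting 5).
#' @param n_virtual Virtual flies per repetition.
#' @param noise `fw_noise` used in the with-fluctuations condition.
#' @param seed Master seed.
#' @param ... Passed to [odor_frequency_curve()].
#' @return Tibble with columns `amplitude`, `with_noise`, `rep`, `peak`.
#' @export
stimulus_response_sweep <- function(model, amplitudes,
                                    with_noise = c(TRUE, FALSE), n_rep = 5,
                                    n_virtual = 50,
                                    noise = noise_spec("gaussian"),
                                    seed = 1, ...) {
  eq <- find_equilibria(model)
  grid <- expand.grid(amplitude = amplitudes, with_noise = with_noise,
                      rep = seq_len(n_rep))
  purrr::pmap_dfr(grid, function(amplitude, with_noise, rep) {
    curve <- odor_frequency_curve(
      model, n_virtual = n_virtual, amplitude = amplitude,
      noise = if (with_noise) noise else NULL, equilibria = eq,
      seed = mix_seed(seed, round(amplitude * 1000) + with_noise, rep), ...)
    tibble(amplitude = amplitude, with_noise = with_noise, rep = rep,
           peak = max(curve$freq))
  })
}
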