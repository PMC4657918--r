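#' Continuous-time recurrent neural network model
#'
#' Defines a CTRNN with `M` neurons governed by
#' `tau_i dx_i/dt = -x_i + sum_j w_ji sigma(x_j + b_j) + I_i`,
#' where `sigma` is the logistic function and `I_i` collects the fluctuating
#' input (noise gain `w_noise_i`) and the odor drive (`w_odor_i` times the
#' stimulus). The first neuron is always the output neuron: the virtual fly
#' walks whenever `sigma(x_1 + b_1) >= thr`.
#'
#' @param w Synaptic weight matrix (M x M) with `w[i, j]` the weight from
#'   neuron `j` into neuron `i`; entries in \[-20, 20\]. A scalar is accepted
#'   for one-neuron models.
#' @param tau Per-neuron time constants in seconds, each in \[0.05, 50\].
#' @param b Per-neuron biases in \[-10, 10\].
#' @param w_noise Per-neuron noise gains (>= 0).
#' @param w_odor Per-neuron odor input gains.
#' @param thr Output threshold in (0, 1).
#' @param t_noise Noise knot interval in seconds, in \[0.01, 1\].
#' @return A validated `fw_model` object.
#' @export
ctrnn_model <- function(w, tau, b, w_noise = 0, w_odor = 0, thr = 0.5,
                        t_noise = 0.1) {
  w <- as.matrix(w)
  m <- length(tau)
  if (!all(dim(w) == c(m, m))) abort("`w` must be an M x M matrix matching `tau`.")
  b <- rep_len(b, m)
  w_noise <- rep_len(w_noise, m)
  w_odor <- rep_len(w_odor, m)
  if (m < 1 || m > 5) abort("network size must be 1-5 neurons.")
  if (any(abs(w) > 20)) abort("weights must lie in [-20, 20].")
  if (any(tau < 0.05 | tau > 50)) abort("tau must lie in [0.05, 50] s.")
  if (any(abs(b) > 10)) abort("biases must lie in [-10, 10].")
  if (any(w_noise < 0)) abort("noise gains must be >= 0.")
  if (thr <= 0 || thr >= 1) abort("`thr` must lie in (0, 1).")
  if (t_noise < 0.01 || t_noise > 1) abort("`t_noise` must lie in [0.01, 1] s.")
  structure(
    list(m = m, w = unname(w), tau = as.numeric(tau), b = as.numeric(b),
         w_noise = as.numeric(w_noise), w_odor = as.numeric(w_odor),
         thr = thr, t_noise = t_noise),
    class = "fw_model"
  )
}

#' @export
print.fw_model <- function(x, ...) {
  cat(sprintf("<fw_model> CTRNN with %d neuron(s), thr = %.3f, t_noise = %.3f s\n",
              x$m, x$thr, x$t_noise))
  invisible(x)
}

#' Logistic transfer function
#'
#' `sigma(x) = 1 / (1 + exp(-x))`, evaluated exactly and numerically stably.
#'
#' @param x Numeric.
#' @return Values in (0, 1).
#' @export
sigmoid <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  e <- exp(x[!pos])
  out[!pos] <- e / (1 + e)
  dim(out) <- dim(x)
  out
}

#' Fluctuating-input specification
#'
#' Describes the statistics of the per-neuron fluctuation source: white
#' Gaussian values, 1/f^alpha power-law noise (spectral synthesis, unit
#' sample variance before the gain), or an Ornstein-Uhlenbeck process
#' `dx = theta (mu - x) dt + sigma dW` with `mu = 0`, advanced exactly
#' between knots. Fresh values are drawn every `t_noise` seconds and
#' linearly interpolated at the integration sub-steps.
#'
#' @param kind `"gaussian"`, `"powerlaw"`, or `"ou"`.
#' @param alpha Power-law exponent (power spectrum ~ 1/f^alpha).
#' @param theta OU mean-reversion rate (1/s, > 0).
#' @param sigma OU diffusion coefficient (>= 0).
#' @param x0 OU initial value.
#' @return A `fw_noise` list.
#' @export
noise_spec <- function(kind = c("gaussian", "powerlaw", "ou"), alpha = 1,
                       theta = 1, sigma = 1, x0 = 0) {
  kind <- match.arg(kind)
  if (kind == "ou" && (theta <= 0 || sigma < 0)) {
    abort("OU noise needs theta > 0 and sigma >= 0.")
  }
  structure(list(kind = kind, alpha = alpha, theta = theta, sigma = sigma,
                 x0 = x0), class = "fw_noise")
}

# Draw one knot track of length nk for a single neuron (gain applied).
noise_knots_one <- function(spec, gain, nk, t_noise) {
  if (gain == 0) return(numeric(nk))
  switch(spec$kind,
    gaussian = gain * rnorm(nk),
    powerlaw = gain * powerlaw_sequence(nk, spec$alpha),
    ou = {
      decay <- exp(-spec$theta * t_noise)
      sd_inc <- spec$sigma * sqrt((1 - decay^2) / (2 * spec$theta))
      x <- numeric(nk)
      x[1] <- spec$x0
      eps <- rnorm(nk - 1)
      for (k in 2:nk) x[k] <- x[k - 1] * decay + sd_inc * eps[k - 1]
      gain * x
    }
  )
}

# 1/f^alpha sequence by frequency-domain amplitude shaping of white noise,
# standardized to zero mean / unit variance.
powerlaw_sequence <- function(n, alpha) {
  white <- rnorm(n)
  sp <- fft(white)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)         # two-sided frequency index
  f[1] <- 1                   # keep DC finite; mean removed below
  shaped <- Re(fft(sp * f^(-alpha / 2), inverse = TRUE)) / n
  shaped <- shaped - mean(shaped)
  s <- sd(shaped)
  if (s == 0) return(shaped)
  shaped / s
}

# Knot matrix (m x nk) for all neurons of a model.
model_noise_knots <- function(model, spec, duration) {
  if (is.null(spec) || all(model$w_noise == 0)) {
    return(matrix(0, model$m, 0))
  }
  nk <- floor(duration / model$t_noise) + 2L
  t(vapply(seq_len(model$m),
           function(i) noise_knots_one(spec, model$w_noise[i], nk, model$t_noise),
           numeric(nk)))
}

#' Interpolated fluctuation track
#'
#' Generates the knot sequence of a fluctuation source (one value every
#' `t_noise` seconds, scaled by `gain`) and linearly interpolates it onto the
#' integration grid.
#'
#' @param spec `fw_noise` from [noise_spec()].
#' @param gain Noise gain (standard deviation for Gaussian knots).
#' @param duration Track length in seconds.
#' @param t_noise Knot spacing in seconds (>= `dt`).
#' @param dt Integration step (default 0.01 s).
#' @param seed Optional RNG seed.
#' @return Tibble with columns `time` and `value`.
#' @export
noise_track <- function(spec, gain, duration, t_noise = 0.1, dt = 0.01,
                        seed = NULL) {
  if (t_noise < dt) abort("`t_noise` must be >= the integration step.")
  if (!is.null(seed)) set.seed(seed)
  nk <- floor(duration / t_noise) + 2L
  kn <- noise_knots_one(spec, gain, nk, t_noise)
  t_out <- seq(0, duration, by = dt)
  v <- approx(x = (seq_len(nk) - 1) * t_noise, y = kn, xout = t_out)$y
  tibble(time = t_out, value = v)
}

#' Stimulus schedule
#'
#' Non-overlapping odor-on intervals with a common dimensionless amplitude;
#' the stimulus input is a rectangle `u(t) = amplitude` inside the intervals
#' and 0 outside.
#'
#' @param t_on,t_off Vectors of interval start/end times in seconds.
#' @param amplitude Stimulus amplitude.
#' @return A `fw_stimulus` tibble with attribute `amplitude`.
#' @export
stimulus_schedule <- function(t_on, t_off, amplitude = 1) {
  if (length(t_on) != length(t_off) || any(t_off <= t_on)) {
    abort("need t_off > t_on for every interval.")
  }
  o <- order(t_on)
  t_on <- t_on[o]
  t_off <- t_off[o]
  if (length(t_on) > 1 && any(t_on[-1] < t_off[-length(t_off)])) {
    abort("stimulus intervals must not overlap.")
  }
  structure(tibble(t_on = t_on, t_off = t_off),
            amplitude = amplitude, class = c("fw_stimulus", class(tibble())))
}

# Per-step stimulus vector u for n_steps steps of size dt.
stimulus_steps <- function(stimulus, n_steps, dt, t0 = 0) {
  if (is.null(stimulus)) return(numeric(0))
  t_grid <- t0 + (seq_len(n_steps) - 1) * dt
  u <- numeric(n_steps)
  amp <- attr(stimulus, "amplitude") %||% 1
  for (k in seq_len(nrow(stimulus))) {
    u[t_grid >= stimulus$t_on[k] & t_grid < stimulus$t_off[k]] <- amp
  }
  u
}

# Low-level simulation; returns the C++ result list. Randomness (knots)
# is drawn from the current R RNG state.
sim_raw <- function(model, duration, x0, noise = NULL, stimulus = NULL,
                    dt = 0.01, keep_states = FALSE) {
  n_steps <- round(duration / dt)
  knots <- model_noise_knots(model, noise, duration)
  u <- stimulus_steps(stimulus, n_steps, dt)
  cpp_ctrnn_sim(model$w, model$tau, model$b, x0, dt, n_steps, knots,
                model$t_noise, model$w_odor, u, keep_states)
}

#' Integrate a CTRNN trajectory
#'
#' Classical fourth-order Runge-Kutta at a fixed 10 ms step. The fluctuation
#' track is evaluated by linear interpolation between knots at the RK4
#' sub-stage times; the odor input is a rectangle held constant over each
#' step.
#'
#' @param model `fw_model`.
#' @param duration Integration time in seconds.
#' @param x0 Initial state vector (defaults to the origin).
#' @param noise Optional `fw_noise`; effective only for neurons with a
#'   positive noise gain.
#' @param stimulus Optional `fw_stimulus`.
#' @param dt Integration step in seconds (default 0.01).
#' @param seed Optional RNG seed for the noise knots.
#' @return A `fw_trajectory` tibble: `time`, state columns `x1..xM`, and
#'   `out` = `sigma(x1 + b1)`.
#' @export
integrate_ctrnn <- function(model, duration, x0 = NULL, noise = NULL,
                            stimulus = NULL, dt = 0.01, seed = NULL) {
  stopifnot(inherits(model, "fw_model"))
  if (!is.null(seed)) set.seed(seed)
  x0 <- x0 %||% rep(0, model$m)
  res <- sim_raw(model, duration, x0, noise, stimulus, dt, keep_states = TRUE)
  if (!res$finite) {
    abort(sprintf(
      "trajectory diverged to a non-finite state (duration %.1f s); check parameters.",
      duration))
  }
  states <- res$states
  colnames(states) <- paste0("x", seq_len(model$m))
  out <- as_tibble(states)
  out <- dplyr::mutate(out,
                       time = seq(0, by = dt, length.out = nrow(states)),
                       out = res$out, .before = 1)
  structure(out, class = c("fw_trajectory", class(tibble())), model = model)
}

#' Sample initial conditions near the model's equilibria
#'
#' Draws states from identity-covariance Gaussians centred at the noiseless
#' model's equilibrium points, assigned round-robin across equilibria. If no
#' equilibrium is found the draw falls back to origin-centred sampling with a
#' warning.
#'
#' @param model `fw_model`.
#' @param n Number of initial states.
#' @param equilibria Optional precomputed [find_equilibria()] result.
#' @param seed Optional RNG seed.
#' @return An `n` x `M` matrix of initial states.
#' @export
sample_initial_conditions <- function(model, n, equilibria = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eq <- equilibria %||% find_equilibria(model)
  centers <- if (nrow(eq) == 0) {
    warn("no equilibrium found; sampling initial conditions around the origin.")
    matrix(0, 1, model$m)
  } else {
    as.matrix(eq[, paste0("x", seq_len(model$m)), drop = FALSE])
  }
  idx <- rep_len(seq_len(nrow(centers)), n)
  centers[idx, , drop = FALSE] + matrix(rnorm(n * model$m), n, model$m)
}

# One initial condition at a uniformly chosen equilibrium (plus unit
# Gaussian jitter); used by single-fly runs where round-robin would
# degenerate to always picking the first equilibrium.
draw_initial_condition <- function(model, equilibria) {
  centers <- if (nrow(equilibria) == 0) {
    matrix(0, 1, model$m)
  } else {
    as.matrix(equilibria[, paste0("x", seq_len(model$m)), drop = FALSE])
  }
  centers[sample.int(nrow(centers), 1), ] + rnorm(model$m)
}

#' Simulate one virtual fly and threshold its output into bouts
#'
#' Starts from an equilibrium-centred initial condition, discards a
#' transient (5 simulated minutes by default), then records the thresholded
#' output (walking iff `sigma(x1 + b1) >= thr`) at the integration rate.
#' For basal runs twice the recording duration is simulated and one half is
#' kept at random, which mitigates overfitting to a single trajectory.
#'
#' @param model `fw_model`.
#' @param record_duration Recorded duration in seconds (default 30 min).
#' @param noise `fw_noise` (default Gaussian knots).
#' @param stimulus Optional `fw_stimulus`; when supplied the recording
#'   follows the stimulus protocol directly (no random half).
#' @param seed Optional RNG seed.
#' @param transient Discarded transient in seconds (default 300).
#' @param split_halves Simulate two halves and keep one at random (default
#'   `TRUE` for basal runs, ignored when a stimulus is given).
#' @param equilibria Optional precomputed equilibria (skips root finding).
#' @param dt Integration step (s).
#' @return Tibble with columns `time`, `out`, `state`.
#' @export
run_virtual_fly <- function(model, record_duration = 1800,
                            noise = noise_spec("gaussian"), stimulus = NULL,
                            seed = NULL, transient = 300, split_halves = TRUE,
                            equilibria = NULL, dt = 0.01) {
  if (!is.null(seed)) set.seed(seed)
  eq <- equilibria %||% find_equilibria(model)
  x0 <- draw_initial_condition(model, eq)
  use_split <- is.null(stimulus) && split_halves
  total <- transient + record_duration * (1 + use_split)
  res <- sim_raw(model, total, x0, noise, stimulus, dt, keep_states = FALSE)
  if (!res$finite) {
    abort("virtual fly diverged to a non-finite state; check parameters.")
  }
  out <- res$out
  n_rec <- round(record_duration / dt)
  skip <- round(transient / dt)
  offset <- if (use_split && runif(1) < 0.5) n_rec else 0L
  keep <- out[(skip + offset + 1L):(skip + offset + n_rec)]
  tibble(
    time = seq(0, by = dt, length.out = n_rec),
    out = keep,
    state = as.integer(keep >= model$thr)
  )
}

#' Threshold applied directly to a fluctuation track (network-free control)
#'
#' The simplest feed-forward action-selection model: a unit-variance
#' Gaussian knot track, interpolated at the integration rate, is compared to
#' a fixed threshold; the virtual fly walks whenever the track is at or
#' above it.
#'
#' @param threshold Threshold in units of the track's standard deviation,
#'   typically in \[-4, 4\].
#' @param duration Duration in seconds.
#' @param t_noise Knot spacing (s).
#' @param dt Sample step (s).
#' @param seed Optional RNG seed.
#' @return Tibble with columns `time`, `value`, `state`.
#' @export
noise_only_baseline <- function(threshold, duration = 1800, t_noise = 0.1,
                                dt = 0.01, seed = NULL) {
  track <- noise_track(noise_spec("gaussian"), gain = 1, duration = duration,
                       t_noise = t_noise, dt = dt, seed = seed)
  dplyr::mutate(track, state = as.integer(.data$value >= threshold))
}

#' Serialize a CTRNN model to JSON
#'
#' @param model `fw_model`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
model_to_json <- function(model, path = NULL) {
  payload <- list(m = model$m, w = model$w, tau = model$tau, b = model$b,
                  w_noise = model$w_noise, w_odor = model$w_odor,
                  thr = model$thr, t_noise = model$t_noise)
  if (is.null(path)) {
    jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' Load a CTRNN model from JSON (bounds re-checked)
#'
#' @param x A file path or JSON string produced by [model_to_json()].
#' @return `fw_model`.
#' @export
model_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  ctrnn_model(w = matrix(unlist(obj$w), obj$m, obj$m), tau = obj$tau,
              b = obj$b, w_noise = obj$w_noise, w_odor = obj$w_odor,
              thr = obj$thr, t_noise = obj$t_noise)
}
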