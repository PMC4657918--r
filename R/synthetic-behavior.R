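#' Specification of a synthetic fly population
#'
#' Parameters of the virtual-fly generator used as a stand-in for recorded
#' behavior. Basal locomotion is an alternating-renewal process: walking bout
#' durations are log-normal (median 2 s), stationary durations are a mixture
#' of an exponential (mean 5 s) with a 10% Pareto tail so that multi-minute
#' stationary bouts occur, as seen in sensory-deprived flies. Walking-sample
#' speeds have support above the 1 mm/s walking threshold and stationary
#' speeds stay below the 0.5 mm/s threshold, so ground-truth labels are
#' recoverable by the hysteresis classifier.
#'
#' @param n_flies Number of flies.
#' @param duration Recording duration per fly in seconds.
#' @param sample_rate Samples per second (20 Hz camera rate).
#' @param walk_meanlog,walk_sdlog Log-normal parameters of walking-bout
#'   durations in seconds.
#' @param stat_mean Mean of the exponential component of stationary-bout
#'   durations (s).
#' @param stat_tail_weight Mixture weight of the Pareto tail.
#' @param stat_tail_xmin,stat_tail_alpha Pareto tail scale (s) and exponent
#'   (> 1 so the mean is finite).
#' @param walk_speed_shift,walk_speed_meanlog,walk_speed_sdlog Walking speed
#'   = shift + log-normal, in mm/s; shift must exceed the 1 mm/s threshold.
#' @param stat_speed_sd,stat_speed_max Stationary speed is half-normal with
#'   this scale, capped below the 0.5 mm/s threshold.
#' @param arena_length,arena_width Arena dimensions in mm.
#' @param edge_bias Drift weight toward the nearest wall while walking.
#' @param odor_bias Drift coefficient away from the odor half while odor is
#'   on.
#' @param seed RNG seed.
#' @return A validated `fw_popspec` list.
#' @export
synthetic_population_spec <- function(n_flies = 10, duration = 1800,
                                      sample_rate = 20,
                                      walk_meanlog = log(2), walk_sdlog = 0.6,
                                      stat_mean = 5, stat_tail_weight = 0.1,
                                      stat_tail_xmin = 10, stat_tail_alpha = 1.5,
                                      walk_speed_shift = 1.2,
                                      walk_speed_meanlog = log(6),
                                      walk_speed_sdlog = 0.5,
                                      stat_speed_sd = 0.12, stat_speed_max = 0.45,
                                      arena_length = 50, arena_width = 10,
                                      edge_bias = 0.3, odor_bias = 0.5,
                                      seed = 1) {
  spec <- list(
    n_flies = n_flies, duration = duration, sample_rate = sample_rate,
    walk_meanlog = walk_meanlog, walk_sdlog = walk_sdlog,
    stat_mean = stat_mean, stat_tail_weight = stat_tail_weight,
    stat_tail_xmin = stat_tail_xmin, stat_tail_alpha = stat_tail_alpha,
    walk_speed_shift = walk_speed_shift,
    walk_speed_meanlog = walk_speed_meanlog,
    walk_speed_sdlog = walk_speed_sdlog,
    stat_speed_sd = stat_speed_sd, stat_speed_max = stat_speed_max,
    arena_length = arena_length, arena_width = arena_width,
    edge_bias = edge_bias, odor_bias = odor_bias, seed = seed
  )
  with(spec, {
    if (n_flies < 1) abort("`n_flies` must be >= 1.")
    if (duration <= 0 || sample_rate <= 0) abort("duration and sample_rate must be > 0.")
    if (stat_mean <= 0 || stat_tail_xmin <= 0) abort("duration parameters must be > 0.")
    if (stat_tail_alpha <= 1) abort("`stat_tail_alpha` must exceed 1 (finite mean).")
    if (stat_tail_weight < 0 || stat_tail_weight > 1) abort("`stat_tail_weight` in [0,1].")
    if (walk_speed_shift <= 1) abort("walking speeds must have support above 1 mm/s.")
    if (stat_speed_max >= 0.5) abort("stationary speeds must stay below 0.5 mm/s.")
  })
  structure(spec, class = "fw_popspec")
}

r_walk_durations <- function(n, spec) {
  rlnorm(n, spec$walk_meanlog, spec$walk_sdlog)
}

r_stat_durations <- function(n, spec) {
  tail <- runif(n) < spec$stat_tail_weight
  d <- rexp(n, rate = 1 / spec$stat_mean)
  n_tail <- sum(tail)
  if (n_tail) {
    d[tail] <- spec$stat_tail_xmin * runif(n_tail)^(-1 / spec$stat_tail_alpha)
  }
  d
}

#' Stationary-bout duration CDF of a population spec
#'
#' Closed-form CDF of the exponential-plus-Pareto stationary duration
#' mixture, used to check generated samples against the generating law.
#'
#' @param q Quantiles in seconds.
#' @param spec `fw_popspec`.
#' @return CDF values.
#' @export
p_stat_duration <- function(q, spec) {
  p_exp <- 1 - exp(-q / spec$stat_mean)
  p_tail <- ifelse(q < spec$stat_tail_xmin, 0,
                   1 - (spec$stat_tail_xmin / q)^spec$stat_tail_alpha)
  (1 - spec$stat_tail_weight) * p_exp + spec$stat_tail_weight * p_tail
}

#' Mean walking and stationary bout durations of a population spec
#'
#' @param spec `fw_popspec`.
#' @return Named numeric vector `walk`, `stat` in seconds.
#' @export
spec_mean_durations <- function(spec) {
  mean_walk <- exp(spec$walk_meanlog + spec$walk_sdlog^2 / 2)
  mean_tail <- spec$stat_tail_alpha * spec$stat_tail_xmin /
    (spec$stat_tail_alpha - 1)
  mean_stat <- (1 - spec$stat_tail_weight) * spec$stat_mean +
    spec$stat_tail_weight * mean_tail
  c(walk = mean_walk, stat = mean_stat)
}

#' Generate a synthetic fly population
#'
#' Simulates each fly as an alternating-renewal walking/stationary process:
#' bout durations are drawn from the spec's distributions, per-sample speeds
#' from the state's speed distribution, and positions follow a reflected
#' random walk inside the arena with a mild wall-ward drift while walking.
#' The first bout's phase is randomised so flies are not synchronised.
#'
#' @param spec `fw_popspec` from [synthetic_population_spec()].
#' @param odor_schedule Optional tibble (`t_on`, `t_off`, `side`) during
#'   which positions drift away from the odor half.
#' @return Tibble with columns `fly`, `time`, `speed`, `x`, `y` and the
#'   ground-truth `state` (1 = walking); the spec is attached as attribute
#'   `spec`.
#' @export
generate_population <- function(spec, odor_schedule = NULL) {
  stopifnot(inherits(spec, "fw_popspec"))
  set.seed(spec$seed)
  dt <- 1 / spec$sample_rate
  n_samp <- round(spec$duration * spec$sample_rate)

  odor_on_left <- function(t) {
    if (is.null(odor_schedule)) return(rep(NA, length(t)))
    side <- rep(NA_character_, length(t))
    for (k in seq_len(nrow(odor_schedule))) {
      sel <- t >= odor_schedule$t_on[k] & t < odor_schedule$t_off[k]
      side[sel] <- odor_schedule$side[k]
    }
    side
  }

  one_fly <- function(id) {
    # alternating renewal sequence of states, randomized initial phase
    means <- spec_mean_durations(spec)
    start_walking <- runif(1) < means["walk"] / sum(means)
    state <- integer(0)
    cur <- as.integer(start_walking)
    first <- TRUE
    while (length(state) < n_samp) {
      d <- if (cur == 1L) r_walk_durations(1, spec) else r_stat_durations(1, spec)
      if (first) {
        d <- d * runif(1)
        first <- FALSE
      }
      state <- c(state, rep(cur, max(1L, round(d * spec$sample_rate))))
      cur <- 1L - cur
    }
    state <- state[seq_len(n_samp)]
    n_walk <- sum(state == 1L)

    speed <- numeric(n_samp)
    speed[state == 1L] <- spec$walk_speed_shift +
      rlnorm(n_walk, spec$walk_speed_meanlog, spec$walk_speed_sdlog)
    speed[state == 0L] <- pmin(abs(rnorm(n_samp - n_walk, 0, spec$stat_speed_sd)),
                               spec$stat_speed_max)

    # reflected random walk; heading diffuses while walking
    t_grid <- (seq_len(n_samp) - 1L) * dt
    side <- odor_on_left(t_grid)
    x <- numeric(n_samp)
    y <- numeric(n_samp)
    x[1] <- runif(1, 0, spec$arena_length)
    y[1] <- runif(1, 0, spec$arena_width)
    heading <- runif(1, 0, 2 * pi)
    turn <- rnorm(n_samp, 0, 0.3)
    for (i in seq_len(n_samp - 1L)) {
      if (state[i] == 1L) {
        heading <- heading + turn[i]
        step <- speed[i] * dt
        dx <- step * cos(heading)
        dy <- step * sin(heading)
        # drift toward the nearest long wall
        wall_pull <- spec$edge_bias * step *
          sign((y[i] > spec$arena_width / 2) - 0.5)
        dy <- dy + wall_pull
        if (!is.na(side[i])) {
          odor_left <- side[i] == "left"
          dx <- dx + spec$odor_bias * step * if (odor_left) 1 else -1
        }
        x[i + 1L] <- reflect(x[i] + dx, 0, spec$arena_length)
        y[i + 1L] <- reflect(y[i] + dy, 0, spec$arena_width)
      } else {
        x[i + 1L] <- x[i]
        y[i + 1L] <- y[i]
      }
    }
    tibble(fly = id, time = t_grid, speed = speed, x = x, y = y, state = state)
  }

  out <- purrr::map_dfr(seq_len(spec$n_flies), one_fly)
  attr(out, "spec") <- spec
  out
}

reflect <- function(p, lo, hi) {
  span <- hi - lo
  p <- (p - lo) %% (2 * span)
  ifelse(p > span, 2 * span - p, p) + lo
}

#' Odor-impulse response template
#'
#' Piecewise walking-probability profile of the odor impulse experiment:
#' constant basal probability, a step to the peak at odor onset, and after
#' odor offset an exponential decay toward a reduced post-odor baseline —
#' the canonical population response shape (basal, onset rise, decay,
#' reduced basal).
#'
#' @param p_basal,p_peak,p_reduced Walking probabilities in \[0, 1\] with
#'   `p_reduced <= p_basal <= p_peak`.
#' @param tau_decay Post-odor decay time constant in seconds (> 0).
#' @param t_on,t_off Odor onset/offset times (s).
#' @param t_end End of the scored protocol (s).
#' @return A validated `fw_odor_template` list.
#' @export
odor_response_template <- function(p_basal = 0.55, p_peak = 0.9,
                                   p_reduced = 0.35, tau_decay = 20,
                                   t_on = 60, t_off = 90, t_end = 210) {
  if (!(p_reduced <= p_basal && p_basal <= p_peak && p_peak <= 1 && p_reduced >= 0)) {
    abort("need 0 <= p_reduced <= p_basal <= p_peak <= 1.")
  }
  if (tau_decay <= 0) abort("`tau_decay` must be > 0.")
  if (!(t_on < t_off && t_off < t_end)) abort("need t_on < t_off < t_end.")
  structure(
    list(p_basal = p_basal, p_peak = p_peak, p_reduced = p_reduced,
         tau_decay = tau_decay, t_on = t_on, t_off = t_off, t_end = t_end),
    class = "fw_odor_template"
  )
}

#' Evaluate an odor-response template
#'
#' @param template `fw_odor_template`.
#' @param t Times in seconds.
#' @return Walking probability at each time.
#' @export
template_probability <- function(template, t) {
  with(template, ifelse(
    t < t_on, p_basal,
    ifelse(t < t_off, p_peak,
           p_reduced + (p_peak - p_reduced) * exp(-(t - t_off) / tau_decay))
  ))
}

#' Generate a virtual population following an odor-response template
#'
#' Each fly is an independent two-state process whose marginal walking
#' probability equals the template exactly at every sample: a latent
#' standard-normal AR(1) series `z_t` with persistence
#' `rho = exp(-dt / tau_switch)` is thresholded through its own CDF,
#' `state_t = 1` iff `pnorm(z_t) < p(t)`. The latent autocorrelation gives
#' walking/stationary bouts their sub-second-to-seconds granularity without
#' biasing the population frequency, even across step changes of the
#' template.
#'
#' @param template `fw_odor_template`.
#' @param n_flies Number of virtual flies (>= 1).
#' @param seed RNG seed.
#' @param sample_rate Samples per second.
#' @param tau_switch Bout time-scale in seconds.
#' @return Tibble with columns `fly`, `time`, `state`.
#' @export
generate_odor_population <- function(template, n_flies, seed = 1,
                                     sample_rate = 20, tau_switch = 0.3) {
  stopifnot(inherits(template, "fw_odor_template"))
  if (n_flies < 1) abort("`n_flies` must be >= 1.")
  set.seed(seed)
  dt <- 1 / sample_rate
  t_grid <- seq(0, template$t_end, by = dt)
  p <- template_probability(template, t_grid)
  rho <- exp(-dt / tau_switch)
  n_t <- length(t_grid)

  one_fly <- function(id) {
    eps <- rnorm(n_t)
    z <- numeric(n_t)
    z[1] <- eps[1]
    for (i in 2:n_t) z[i] <- rho * z[i - 1L] + sqrt(1 - rho^2) * eps[i]
    tibble(fly = id, time = t_grid,
           state = as.integer(stats::pnorm(z) < p))
  }
  purrr::map_dfr(seq_len(n_flies), one_fly)
}

#' Write a synthetic population to per-fly CSV files plus a JSON manifest
#'
#' @param population Tibble from [generate_population()].
#' @param dir Output directory (created if needed).
#' @param odor_schedule Optional stimulus schedule tibble, stored as JSON.
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, dir, odor_schedule = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in unique(population$fly)) {
    df <- population[population$fly == id,
                     c("time", "speed", "x", "y", "state")]
    names(df) <- c("time_s", "speed_mm_s", "x_mm", "y_mm", "state")
    utils::write.csv(df, file.path(dir, sprintf("fly_%03d.csv", id)),
                     row.names = FALSE)
  }
  spec <- attr(population, "spec")
  manifest <- list(n_flies = length(unique(population$fly)),
                   spec = unclass(spec))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(odor_schedule)) {
    jsonlite::write_json(odor_schedule, file.path(dir, "stimulus.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a population written by [write_population()]
#'
#' @param dir Directory containing `fly_*.csv` files.
#' @return Tibble with columns `fly`, `time`, `speed`, `x`, `y`, `state`.
#' @export
read_population <- function(dir) {
  files <- sort(list.files(dir, pattern = "^fly_\\d+\\.csv$", full.names = TRUE))
  if (!length(files)) abort("no fly_*.csv files found.")
  purrr::imap_dfr(files, function(f, i) {
    df <- utils::read.csv(f)
    tibble(fly = i, time = df$time_s, speed = df$speed_mm_s,
           x = df$x_mm, y = df$y_mm, state = df$state)
  })
}
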