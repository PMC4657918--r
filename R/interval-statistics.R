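#' Variable bin-width boundaries for bout-duration histograms
#'
#' Recursively bisects the single bin `[0, max(durations)]`: a bin is split at
#' its midpoint only when both children would hold at least `min_count` events
#' and span at least `min_width` seconds. The recursion is deterministic, so
#' the same target data always yields the same boundaries. Empty bins cannot
#' arise (a child with fewer than `min_count` events blocks the split), which
#' keeps rare, very long bouts in populated bins instead of a sea of zeros.
#'
#' @param durations Numeric vector of bout durations in seconds (positive).
#' @param min_width Minimum bin span in seconds (default 0.05, five
#'   integration steps of the simulator).
#' @param min_count Minimum number of events per bin (default 5).
#' @return Numeric vector of strictly increasing bin edges, first edge 0,
#'   last edge `max(durations)`.
#' @export
compute_bin_boundaries <- function(durations, min_width = 0.05, min_count = 5) {
  if (length(durations) == 0) abort("`durations` must be non-empty.")
  if (any(!is.finite(durations)) || any(durations <= 0)) {
    abort("`durations` must be finite and strictly positive.")
  }
  if (min_width <= 0) abort("`min_width` must be > 0.")
  if (min_count < 1) abort("`min_count` must be >= 1.")

  d <- sort(durations)
  d_max <- d[length(d)]
  count_in <- function(lo, hi, closed_right) {
    if (closed_right) sum(d >= lo & d <= hi) else sum(d >= lo & d < hi)
  }
  split_bin <- function(lo, hi, closed_right) {
    mid <- (lo + hi) / 2
    n_lo <- count_in(lo, mid, FALSE)
    n_hi <- count_in(mid, hi, closed_right)
    ok <- (mid - lo) >= min_width && (hi - mid) >= min_width &&
      n_lo >= min_count && n_hi >= min_count
    if (!ok) return(c(lo, hi))
    left <- split_bin(lo, mid, FALSE)
    right <- split_bin(mid, hi, closed_right)
    c(left[-length(left)], right)
  }
  edges <- split_bin(0, d_max, TRUE)
  unname(edges)
}

#' Duration-weighted histogram of bout durations
#'
#' Counts durations into the supplied bins and weights each bin's count by the
#' duration the bin represents (its lower edge), so that ten 1-s bouts and one
#' 10-s bout carry equal weight. Durations at or beyond the last edge are
#' clamped into the final bin so degenerate, very long simulated bouts remain
#' visible to the cost function.
#'
#' @param durations Numeric vector of bout durations in seconds (may be empty).
#' @param edges Strictly increasing numeric vector of bin edges (length >= 2),
#'   typically from [compute_bin_boundaries()].
#' @return A `fw_histogram` object: tibble with columns `bin`, `lower`,
#'   `upper`, `count`, `t_b` (representative duration = lower edge) and
#'   `weighted` (`count * t_b`).
#' @export
weighted_histogram <- function(durations, edges) {
  if (length(edges) < 2 || any(diff(edges) <= 0)) {
    abort("`edges` must be strictly increasing with at least two values.")
  }
  n_bin <- length(edges) - 1L
  if (length(durations)) {
    idx <- findInterval(durations, edges)
    idx[idx < 1L] <- 1L
    idx[idx > n_bin] <- n_bin
    counts <- tabulate(idx, nbins = n_bin)
  } else {
    counts <- integer(n_bin)
  }
  out <- tibble(
    bin = seq_len(n_bin),
    lower = edges[-length(edges)],
    upper = edges[-1],
    count = counts,
    t_b = edges[-length(edges)]
  )
  out$weighted <- out$count * out$t_b
  structure(out, class = c("fw_histogram", class(tibble())))
}

#' Weighted L1 distance between two bout-duration histograms
#'
#' `d = sum_i |R * h_sim(i) - h_target(i)| * t_b(i)` over shared bin
#' boundaries. `scale` (R) reconciles the simulated data volume with the
#' recorded data volume.
#'
#' @param h_target,h_sim `fw_histogram` objects on identical boundaries.
#' @param scale Scale factor R applied to the simulated counts.
#' @return Non-negative scalar distance in event-seconds.
#' @export
histogram_distance <- function(h_target, h_sim, scale = 1) {
  if (nrow(h_target) != nrow(h_sim) ||
      any(abs(h_target$lower - h_sim$lower) > 1e-12) ||
      any(abs(h_target$upper - h_sim$upper) > 1e-12)) {
    abort("histograms must share identical bin boundaries.")
  }
  sum(abs(scale * h_sim$count - h_target$count) * h_target$t_b)
}

#' Build target walking/stationary histograms from bout intervals
#'
#' Convenience wrapper: computes variable bin boundaries from the target data
#' and bins the walking and stationary durations separately. The returned
#' object carries the total recorded time, used downstream to pick the scale
#' factor R and the degenerate-fly normalisation.
#'
#' @param intervals Tibble of bout intervals with columns `state`
#'   (`"walking"`/`"stationary"`) and `duration` (seconds), e.g. from
#'   [extract_intervals()].
#' @param min_width,min_count Bin construction controls, see
#'   [compute_bin_boundaries()].
#' @return A `fw_target` list: `walking`/`stationary` `fw_histogram`s and
#'   `total_time` (sum of all durations, seconds).
#' @export
build_target_histograms <- function(intervals, min_width = 0.05, min_count = 5) {
  dw <- intervals$duration[intervals$state == "walking"]
  di <- intervals$duration[intervals$state == "stationary"]
  if (!length(dw) || !length(di)) {
    abort("target intervals must contain both walking and stationary bouts.")
  }
  structure(
    list(
      walking = weighted_histogram(dw, compute_bin_boundaries(dw, min_width, min_count)),
      stationary = weighted_histogram(di, compute_bin_boundaries(di, min_width, min_count)),
      total_time = sum(intervals$duration)
    ),
    class = "fw_target"
  )
}

degenerate_distances <- function(target, scale, k_trials, trial_duration,
                                 mode = c("always_walking", "always_stationary", "max")) {
  mode <- match.arg(mode)
  one_state <- function(active_hist, silent_hist) {
    h_deg <- weighted_histogram(
      rep(trial_duration, k_trials),
      c(active_hist$lower, active_hist$upper[nrow(active_hist)])
    )
    histogram_distance(active_hist, h_deg, scale) +
      sum(silent_hist$count * silent_hist$t_b)
  }
  walk_score <- one_state(target$walking, target$stationary)
  if (mode == "always_walking") return(walk_score)
  stat_score <- one_state(target$stationary, target$walking)
  if (mode == "always_stationary") stat_score else max(walk_score, stat_score)
}

#' Normalised cost of simulated bout statistics against a target
#'
#' Scores a set of simulated walking/stationary bout durations against target
#' histograms: `F = (d_W + d_I) / F_norm`, where `d_W`, `d_I` are weighted L1
#' histogram distances and `F_norm` is the score of the degenerate virtual fly
#' that walks for the entirety of every trial. `F = 0` is a perfect match
#' after scaling; `F = 1` is the degenerate fly's score.
#'
#' @param sim_intervals Tibble with columns `state` and `duration`, the pooled
#'   bouts of all simulated trials.
#' @param target `fw_target` from [build_target_histograms()].
#' @param scale Scale factor R (recorded volume / simulated volume); the
#'   study's setting of 100 simulated trials against 10 recorded flies of
#'   equal trial length gives R = 0.1.
#' @param k_trials Number of simulated trials behind `sim_intervals`
#'   (default 100), used for the degenerate-fly normalisation.
#' @param trial_duration Duration of one trial in seconds (default 1800).
#' @param norm_mode Degenerate-fly convention for `F_norm`; the default uses
#'   the always-walking fly.
#' @return One-row tibble: `d_w`, `d_i`, `scale`, `f_norm`, `f`.
#' @export
cost_function <- function(sim_intervals, target, scale = 0.1, k_trials = 100,
                          trial_duration = 1800,
                          norm_mode = c("always_walking", "always_stationary", "max")) {
  norm_mode <- match.arg(norm_mode)
  sim_w <- sim_intervals$duration[sim_intervals$state == "walking"]
  sim_i <- sim_intervals$duration[sim_intervals$state == "stationary"]
  hw <- target$walking
  hi <- target$stationary
  h_sw <- weighted_histogram(sim_w, c(hw$lower, hw$upper[nrow(hw)]))
  h_si <- weighted_histogram(sim_i, c(hi$lower, hi$upper[nrow(hi)]))
  d_w <- histogram_distance(hw, h_sw, scale)
  d_i <- histogram_distance(hi, h_si, scale)
  f_norm <- degenerate_distances(target, scale, k_trials, trial_duration, norm_mode)
  tibble(
    d_w = d_w, d_i = d_i, scale = scale,
    f_norm = f_norm, f = (d_w + d_i) / f_norm
  )
}

#' Cost-value floor from subsets of the target data
#'
#' Calibrates the scale of the cost function by scoring time-normalised
#' subsets of the target dataset against the full dataset: `n_subset` flies
#' are drawn at random, each selected fly's bouts are replicated
#' `ceiling(n_total / n_subset)` times, and bouts are then dropped at random
#' until the subset's total recorded time no longer exceeds the full
#' dataset's. The distribution of resulting cost values over `n_datasets`
#' draws gives the best score any model could plausibly reach.
#'
#' @param intervals Tibble with columns `fly`, `state`, `duration` covering
#'   the full target dataset.
#' @param n_subset Number of flies per subset (may be a vector).
#' @param n_datasets Number of random subsets per subset size.
#' @param min_width,min_count Histogram construction controls.
#' @param seed RNG seed.
#' @return Tibble with columns `n_subset`, `dataset`, `f`.
#' @export
subset_calibration <- function(intervals, n_subset, n_datasets = 1000,
                               min_width = 0.05, min_count = 5, seed = 1) {
  flies <- unique(intervals$fly)
  n_total <- length(flies)
  if (any(n_subset < 1 | n_subset > n_total)) {
    abort("`n_subset` must lie in [1, number of flies].")
  }
  target <- build_target_histograms(intervals, min_width, min_count)
  full_time <- target$total_time
  trial_duration <- full_time / n_total
  set.seed(seed)
  purrr::map_dfr(n_subset, function(ns) {
    reps <- ceiling(n_total / ns)
    purrr::map_dfr(seq_len(n_datasets), function(ds) {
      chosen <- sample(flies, ns)
      sub <- intervals[intervals$fly %in% chosen, c("state", "duration")]
      sub <- sub[rep(seq_len(nrow(sub)), reps), ]
      # trim random bouts until the time volume matches the full dataset
      ord <- sample.int(nrow(sub))
      sub <- sub[ord, ]
      cum_rev <- cumsum(sub$duration)
      keep <- cum_rev <= full_time + 1e-9
      if (!any(keep)) keep[1] <- TRUE
      sub <- sub[keep, ]
      scale <- full_time / sum(sub$duration)
      cost <- cost_function(sub, target, scale = scale, k_trials = n_total,
                            trial_duration = trial_duration)
      tibble(n_subset = ns, dataset = ds, f = cost$f)
    })
  })
}
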