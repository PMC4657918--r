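#' Hysteresis classification of walking versus stationary samples
#'
#' A fly is considered to have begun walking when its speed exceeds
#' `high_thr` (1 mm/s) and to have stopped when speed drops below `low_thr`
#' (0.5 mm/s); inside the band the ongoing state persists, which suppresses
#' chatter from tracking noise near a single cutoff. A trace that starts
#' inside the band starts stationary: walking requires an explicit upward
#' crossing.
#'
#' @param trace Tibble with columns `time` (s) and `speed` (mm/s); an
#'   optional `fly` column is handled per fly.
#' @param high_thr,low_thr Hysteresis thresholds in mm/s,
#'   `high_thr > low_thr >= 0`.
#' @return The input tibble with an integer `state` column
#'   (1 = walking, 0 = stationary).
#' @export
classify_locomotion <- function(trace, high_thr = 1.0, low_thr = 0.5) {
  if (!nrow(trace)) abort("`trace` is empty.")
  if (!(high_thr > low_thr) || low_thr < 0) {
    abort("need `high_thr` > `low_thr` >= 0.")
  }
  one <- function(v) {
    ev <- rep(NA_integer_, length(v))
    ev[v > high_thr] <- 1L
    ev[v < low_thr] <- 0L
    if (is.na(ev[1])) ev[1] <- 0L
    filled <- ev[!is.na(ev)]
    filled[cumsum(!is.na(ev))]
  }
  if ("fly" %in% names(trace)) {
    trace |>
      dplyr::group_by(.data$fly) |>
      dplyr::arrange(.data$time, .by_group = TRUE) |>
      dplyr::mutate(state = one(.data$speed)) |>
      dplyr::ungroup()
  } else {
    dplyr::mutate(trace, state = one(.data$speed))
  }
}

#' Extract walking and stationary bout intervals from a binary series
#'
#' Converts maximal runs of each state into durations in seconds
#' (run length divided by the sample rate). Runs cut off by the start or end
#' of the recording are flagged `truncated`; they are included by default
#' downstream because the rare, very long stationary bouts the cost function
#' must see are disproportionately likely to touch a boundary.
#'
#' @param bouts Tibble with columns `time` and `state` (0/1), optionally
#'   `fly`, `x`, `y`.
#' @param sample_rate Samples per second; inferred from `time` when `NULL`.
#' @return Tibble with columns `fly` (if present), `state`
#'   (`"walking"`/`"stationary"`), `duration` (s), `t_start`, `truncated`,
#'   and start/end positions when `x`/`y` are available.
#' @export
extract_intervals <- function(bouts, sample_rate = NULL) {
  if (!nrow(bouts)) abort("`bouts` is empty.")
  one <- function(df) {
    rate <- sample_rate %||% (1 / median(diff(df$time)))
    r <- rle(df$state)
    n <- length(r$lengths)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    out <- tibble(
      state = ifelse(r$values == 1L, "walking", "stationary"),
      duration = r$lengths / rate,
      t_start = df$time[starts],
      truncated = seq_len(n) == 1L | seq_len(n) == n
    )
    if (all(c("x", "y") %in% names(df))) {
      out$x_start <- df$x[starts]
      out$y_start <- df$y[starts]
      out$x_end <- df$x[ends]
      out$y_end <- df$y[ends]
    }
    out
  }
  if ("fly" %in% names(bouts)) {
    bouts |>
      dplyr::group_by(.data$fly) |>
      dplyr::arrange(.data$time, .by_group = TRUE) |>
      dplyr::group_modify(~ one(.x)) |>
      dplyr::ungroup()
  } else {
    one(dplyr::arrange(bouts, .data$time))
  }
}

#' Population locomotor frequency
#'
#' The proportion of flies walking at each time point: 0 when none walk,
#' 1 when all do. Optionally smoothed with a centred moving average.
#'
#' @param bouts Tibble with columns `fly`, `time`, `state` on aligned grids.
#' @param smooth Width of a centred moving-average window in seconds
#'   (0 = none).
#' @return Tibble with columns `time` and `freq`.
#' @export
locomotor_frequency <- function(bouts, smooth = 0) {
  out <- bouts |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(freq = mean(.data$state), .groups = "drop") |>
    dplyr::arrange(.data$time)
  if (smooth > 0) {
    rate <- 1 / median(diff(out$time))
    out$freq <- smooth_series(out$freq, max(1L, round(smooth * rate)))
  }
  out
}

# centred moving average with shrinking windows at the edges
smooth_series <- function(x, width) {
  if (width <= 1L) return(x)
  half <- width %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Odor-aversion score of an arena trajectory
#'
#' `(time in air zone - time in odor zone) / total scored time`, ranging from
#' -1 (always in the odor) to 1 (never in the odor). The odor zone is the
#' arena half named by each scheduled interval's `side` (`"left"` = x below
#' the arena midline).
#'
#' @param trace Tibble with columns `time` and `x` (mm), optionally `fly`.
#' @param schedule Tibble with columns `t_on`, `t_off`, `side`
#'   (`"left"`/`"right"`).
#' @param arena_length Long-axis length in mm (default 50).
#' @return Tibble with columns `fly` (if present) and `aversion`.
#' @export
odor_aversion <- function(trace, schedule, arena_length = 50) {
  if (!all(c("t_on", "t_off", "side") %in% names(schedule))) {
    abort("`schedule` needs columns t_on, t_off, side.")
  }
  mid <- arena_length / 2
  one <- function(df) {
    in_air <- 0
    in_odor <- 0
    total <- 0
    for (k in seq_len(nrow(schedule))) {
      sel <- df$time >= schedule$t_on[k] & df$time < schedule$t_off[k]
      if (!any(sel)) next
      odor_side_left <- schedule$side[k] == "left"
      in_left <- df$x[sel] < mid
      odor_samples <- if (odor_side_left) in_left else !in_left
      in_odor <- in_odor + sum(odor_samples)
      in_air <- in_air + sum(!odor_samples)
      total <- total + sum(sel)
    }
    if (total == 0) abort("odor schedule does not overlap the trace.")
    tibble(aversion = (in_air - in_odor) / total)
  }
  if ("fly" %in% names(trace)) {
    trace |>
      dplyr::group_by(.data$fly) |>
      dplyr::group_modify(~ one(.x)) |>
      dplyr::ungroup()
  } else {
    one(trace)
  }
}

#' Fold arena positions into one quadrant
#'
#' Reflects positions along the arena midlines, `x' = min(x, L - x)` and
#' `y' = min(y, W - y)`, so points near any of the four corners aggregate
#' near the origin corner. Folding is idempotent.
#'
#' @param positions Tibble with columns `x`, `y` in mm.
#' @param arena_length,arena_width Arena dimensions in mm (50 x 10).
#' @return The tibble with `x`, `y` replaced by folded coordinates.
#' @export
fold_to_quadrant <- function(positions, arena_length = 50, arena_width = 10) {
  dplyr::mutate(
    positions,
    x = pmin(.data$x, arena_length - .data$x),
    y = pmin(.data$y, arena_width - .data$y)
  )
}

#' Distance correlation between two samples
#'
#' Szekely's distance correlation from the double-centred pairwise distance
#' matrices: zero iff the samples are independent (in the population), 1 for
#' exact linear dependence, and sensitive to arbitrary nonlinear association.
#' Both arguments may be vectors or matrices with observations in rows.
#'
#' @param a,b Numeric vectors or matrices with the same number of rows.
#' @return Scalar in \[0, 1\].
#' @export
distance_correlation <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (nrow(a) != nrow(b)) abort("`a` and `b` must have the same number of observations.")
  A <- dc_center(a)
  B <- dc_center(b)
  dcov2 <- mean(A * B)
  dvar_a <- mean(A * A)
  dvar_b <- mean(B * B)
  if (dvar_a <= 0 || dvar_b <= 0) return(0)
  sqrt(max(dcov2, 0) / sqrt(dvar_a * dvar_b))
}

dc_center <- function(m) {
  d <- as.matrix(stats::dist(m))
  rm <- rowMeans(d)
  d - outer(rm, rep(1, length(rm))) - outer(rep(1, length(rm)), rm) + mean(d)
}

#' Permutation null distribution for the distance correlation
#'
#' Re-computes the distance correlation after shuffling the rows of one
#' variable, breaking any pairing; repeated `n_shuffles` times this gives the
#' reference distribution expected for uncorrelated data.
#'
#' @inheritParams distance_correlation
#' @param n_shuffles Number of permutations (default 100).
#' @param seed RNG seed.
#' @return Tibble with columns `shuffle` and `dc`.
#' @export
distance_correlation_null <- function(a, b, n_shuffles = 100, seed = 1) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  set.seed(seed)
  purrr::map_dfr(seq_len(n_shuffles), function(s) {
    tibble(shuffle = s, dc = distance_correlation(a, b[sample.int(nrow(b)), , drop = FALSE]))
  })
}

#' Distance correlation after re-pairing increasing fractions of shuffled data
#'
#' Starts from a fully shuffled pairing of `a` and `b` and restores the true
#' pairing for an incrementally larger random subset, tracing how the
#' distance correlation rises from the shuffle null towards its paired value.
#'
#' @inheritParams distance_correlation
#' @param fractions Fractions of points to re-pair (default 10%..100%).
#' @param n_rep Replicates per fraction.
#' @param seed RNG seed.
#' @return Tibble with columns `fraction`, `rep`, `dc`.
#' @export
injected_correlation_curve <- function(a, b, fractions = seq(0.1, 1, by = 0.1),
                                       n_rep = 100, seed = 1) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  n <- nrow(a)
  set.seed(seed)
  purrr::map_dfr(fractions, function(f) {
    purrr::map_dfr(seq_len(n_rep), function(r) {
      perm <- sample.int(n)
      fixed <- sample.int(n, round(f * n))
      perm[fixed] <- fixed
      tibble(fraction = f, rep = r, dc = distance_correlation(a, b[perm, , drop = FALSE]))
    })
  })
}

#' Consistency of locomotor patterns within and between strains
#'
#' For every ordered pair of strains, repeatedly draws two non-overlapping
#' groups of `group_size` flies (both from the same strain for within-strain
#' comparisons), averages each group's walking state into a locomotor
#' frequency trace, normalises the trace to \[0, 1\] over the scored window,
#' and records the squared Pearson correlation between the two group traces
#' plus each group's mean basal frequency.
#'
#' @param bouts Tibble with columns `strain`, `fly`, `time`, `state`.
#' @param group_size Flies per group (default 65).
#' @param n_rep Resampling repetitions per comparison (default 100).
#' @param window Scored window in seconds (default 58-200 of the odor
#'   impulse experiment).
#' @param basal_window Window for the basal-frequency summary (default the
#'   pre-odor minute).
#' @param seed RNG seed.
#' @return Tibble with columns `strain_a`, `strain_b`, `rep`, `r_squared`,
#'   `basal_a`, `basal_b`.
#' @export
group_consistency <- function(bouts, group_size = 65, n_rep = 100,
                              window = c(58, 200), basal_window = c(0, 58),
                              seed = 1) {
  strains <- unique(bouts$strain)
  by_strain <- split(bouts, bouts$strain)
  fly_ids <- purrr::map(by_strain, ~ unique(.x$fly))
  set.seed(seed)

  group_trace <- function(strain, flies) {
    df <- by_strain[[strain]]
    df <- df[df$fly %in% flies, ]
    locomotor_frequency(df)
  }
  norm01 <- function(x) {
    r <- range(x)
    if (diff(r) == 0) return(rep(0, length(x)))
    (x - r[1]) / diff(r)
  }
  pairs <- expand.grid(strain_a = strains, strain_b = strains,
                       stringsAsFactors = FALSE)
  pairs <- pairs[as.character(pairs$strain_a) <= as.character(pairs$strain_b), ]

  purrr::pmap_dfr(pairs, function(strain_a, strain_b) {
    same <- strain_a == strain_b
    n_a <- length(fly_ids[[strain_a]])
    n_b <- length(fly_ids[[strain_b]])
    need_a <- if (same) 2 * group_size else group_size
    if (n_a < need_a || n_b < group_size) {
      abort("`group_size` too large for strain population.")
    }
    purrr::map_dfr(seq_len(n_rep), function(r) {
      if (same) {
        picked <- sample(fly_ids[[strain_a]], 2 * group_size)
        fa <- picked[seq_len(group_size)]
        fb <- picked[group_size + seq_len(group_size)]
      } else {
        fa <- sample(fly_ids[[strain_a]], group_size)
        fb <- sample(fly_ids[[strain_b]], group_size)
      }
      ta <- group_trace(strain_a, fa)
      tb <- group_trace(strain_b, fb)
      in_win <- ta$time >= window[1] & ta$time <= window[2]
      in_basal <- ta$time >= basal_window[1] & ta$time < basal_window[2]
      tibble(
        strain_a = strain_a, strain_b = strain_b, rep = r,
        r_squared = cor(norm01(ta$freq[in_win]), norm01(tb$freq[in_win]))^2,
        basal_a = mean(ta$freq[in_basal]),
        basal_b = mean(tb$freq[in_basal])
      )
    })
  })
}

#' Single-linkage dendrogram of strain odor-response traces
#'
#' Agglomerative single-linkage clustering of strain-averaged odor-impulse
#' locomotor frequency traces, with distance `1 - Pearson correlation`
#' between traces.
#'
#' @param traces Tibble with columns `strain`, `time`, `freq`.
#' @return An [stats::hclust] merge tree.
#' @export
strain_dendrogram <- function(traces) {
  wide <- tidyr::pivot_wider(traces, names_from = "strain",
                             values_from = "freq")
  m <- as.matrix(wide[, setdiff(names(wide), "time")])
  d <- as.dist(1 - cor(m))
  hclust(d, method = "single")
}
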