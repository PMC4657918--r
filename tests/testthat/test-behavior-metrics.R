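trace_of <- function(v, rate = 20) {
  tibble::tibble(time = (seq_along(v) - 1) / rate, speed = v)
}

test_that("hysteresis classifier enters above 1 mm/s and exits below 0.5 mm/s", {
  expect_equal(classify_locomotion(trace_of(c(0, 1.2, 0.7, 0.4, 0.3)))$state,
               c(0L, 1L, 1L, 0L, 0L))
  expect_equal(classify_locomotion(trace_of(rep(0, 10)))$state, rep(0L, 10))
  expect_equal(classify_locomotion(trace_of(rep(2, 10)))$state, rep(1L, 10))
  # mid-band start is stationary until an explicit upward crossing
  expect_equal(classify_locomotion(trace_of(c(0.7, 0.8, 1.3)))$state,
               c(0L, 0L, 1L))
  expect_error(classify_locomotion(trace_of(numeric(0))), "empty")
  expect_error(classify_locomotion(trace_of(1), high_thr = 0.4, low_thr = 0.5))
})

test_that("classifier output ignores jitter strictly inside the band", {
  set.seed(11)
  for (i in 1:5) {
    base <- c(rep(0.2, 5), rep(1.5, 10), rep(0.2, 5))
    jit <- base
    idx <- 7:14  # inside the ongoing walking state
    jit[idx] <- runif(length(idx), 0.51, 0.99)
    expect_equal(classify_locomotion(trace_of(jit))$state,
                 classify_locomotion(trace_of(base))$state)
  }
})

test_that("interval extraction converts runs to durations and flags truncation", {
  b <- tibble::tibble(time = (0:5) / 20, state = c(1L, 1L, 0L, 0L, 0L, 1L))
  iv <- extract_intervals(b, sample_rate = 20)
  expect_equal(iv$duration[iv$state == "walking"], c(0.10, 0.05))
  expect_equal(iv$duration[iv$state == "stationary"], 0.15)
  expect_equal(iv$truncated, c(TRUE, FALSE, TRUE))

  ones <- tibble::tibble(time = (0:19) / 20, state = rep(1L, 20))
  iv1 <- extract_intervals(ones, sample_rate = 20)
  expect_equal(nrow(iv1), 1)
  expect_equal(iv1$duration, 1)
  expect_true(iv1$truncated)

  alt <- tibble::tibble(time = (0:9) / 20, state = rep(c(1L, 0L), 5))
  expect_true(all(extract_intervals(alt, sample_rate = 20)$duration == 0.05))

  # walking + stationary durations partition the trace exactly
  set.seed(4)
  st <- rbinom(400, 1, 0.4)
  ivr <- extract_intervals(tibble::tibble(time = (seq_along(st) - 1) / 20,
                                          state = st), sample_rate = 20)
  expect_equal(sum(ivr$duration), length(st) / 20)
})

test_that("locomotor frequency is the per-sample proportion of walking flies", {
  b <- dplyr::bind_rows(
    tibble::tibble(fly = 1, time = c(0, 0.05), state = c(1L, 1L)),
    tibble::tibble(fly = 2, time = c(0, 0.05), state = c(0L, 1L))
  )
  expect_equal(locomotor_frequency(b)$freq, c(0.5, 1))
})

test_that("aversion score is bounded and antisymmetric under zone swap", {
  sched <- tibble::tibble(t_on = 0, t_off = 10, side = "left")
  t <- seq(0, 9.95, by = 0.05)
  always_air <- tibble::tibble(time = t, x = rep(40, length(t)))
  always_odor <- tibble::tibble(time = t, x = rep(10, length(t)))
  expect_equal(odor_aversion(always_air, sched)$aversion, 1)
  expect_equal(odor_aversion(always_odor, sched)$aversion, -1)
  half <- tibble::tibble(time = t, x = rep(c(10, 40), length(t) / 2))
  expect_equal(odor_aversion(half, sched)$aversion, 0)

  set.seed(9)
  wander <- tibble::tibble(time = t, x = runif(length(t), 0, 50))
  swapped <- tibble::tibble(t_on = 0, t_off = 10, side = "right")
  expect_equal(odor_aversion(wander, sched)$aversion,
               -odor_aversion(wander, swapped)$aversion)
})

test_that("quadrant folding reflects along both midlines and is idempotent", {
  p <- tibble::tibble(x = c(49, 25, 1), y = c(9, 5, 1))
  f1 <- fold_to_quadrant(p)
  expect_equal(f1$x, c(1, 25, 1))
  expect_equal(f1$y, c(1, 5, 1))
  expect_equal(fold_to_quadrant(f1), f1)
})

test_that("distance correlation detects dependence and permutation breaks it", {
  set.seed(21)
  x <- rnorm(60)
  expect_equal(distance_correlation(x, 2 * x), 1, tolerance = 1e-10)
  y <- rnorm(60)
  expect_equal(distance_correlation(x, y), distance_correlation(y, x))

  # for independent samples the observed DC sits inside the shuffle null
  dc_obs <- distance_correlation(x, y)
  null <- distance_correlation_null(x, y, n_shuffles = 60, seed = 2)
  expect_gt(dc_obs, quantile(null$dc, 0.01))
  expect_lt(dc_obs, quantile(null$dc, 0.99))

  # nonlinear dependence is detected above the null
  z <- x^2
  expect_gt(distance_correlation(x, z),
            quantile(distance_correlation_null(x, z, 60, seed = 3)$dc, 0.99))
})

test_that("re-pairing larger fractions raises the distance correlation", {
  set.seed(31)
  x <- rnorm(80)
  y <- 2 * x
  curve <- injected_correlation_curve(x, y, fractions = c(0.1, 0.5, 1),
                                      n_rep = 30, seed = 4)
  med <- tapply(curve$dc, curve$fraction, median)
  expect_true(all(diff(med) > 0))
  expect_gt(med[["1"]], 0.999)
})

test_that("group consistency separates strains that differ in their template", {
  t_a <- odor_response_template(p_basal = 0.6, p_peak = 0.9, p_reduced = 0.3,
                                tau_decay = 10)
  t_b <- odor_response_template(p_basal = 0.3, p_peak = 0.85, p_reduced = 0.25,
                                tau_decay = 60)
  pop <- dplyr::bind_rows(
    dplyr::mutate(generate_odor_population(t_a, 40, seed = 1), strain = "A"),
    dplyr::mutate(generate_odor_population(t_b, 40, seed = 2),
                  strain = "B", fly = fly + 100)
  )
  gc <- group_consistency(pop, group_size = 15, n_rep = 10, seed = 5)
  same <- mean(gc$r_squared[gc$strain_a == gc$strain_b])
  diff_ <- mean(gc$r_squared[gc$strain_a != gc$strain_b])
  expect_gt(same, diff_)
  expect_error(group_consistency(pop, group_size = 500, n_rep = 2),
               "too large")
})

test_that("strain dendrogram is single linkage on 1 - correlation", {
  t_grid <- seq(0, 10, by = 0.5)
  base <- sin(t_grid) + 2
  traces <- dplyr::bind_rows(
    tibble::tibble(strain = "s1", time = t_grid, freq = base),
    tibble::tibble(strain = "s2", time = t_grid, freq = base),       # duplicate
    tibble::tibble(strain = "s3", time = t_grid, freq = -base + 5),  # anti
    tibble::tibble(strain = "s4", time = t_grid, freq = cos(t_grid))
  )
  hc <- strain_dendrogram(traces)
  expect_equal(nrow(hc$merge), 3)           # n - 1 merges
  expect_equal(hc$height[1], 0)             # duplicated traces merge first
  d <- 1 - cor(cbind(base, -base + 5))
  expect_equal(max(d), 2)                   # anti-correlated pair at the bound
})
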