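test_that("sigmoid is the exact logistic function", {
  expect_equal(sigmoid(0), 0.5)
  x <- seq(-30, 30, by = 0.7)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, length(x)))
  expect_lt(abs(sigmoid(10) - 1), 5e-5)
  expect_true(all(sigmoid(c(-750, 750)) >= 0 & sigmoid(c(-750, 750)) <= 1))
})

test_that("model constructor enforces the parameter boxes", {
  expect_error(ctrnn_model(matrix(30, 1, 1), 1, 0), "-20, 20")
  expect_error(ctrnn_model(matrix(0, 1, 1), 0.01, 0), "0.05, 50")
  expect_error(ctrnn_model(matrix(0, 1, 1), 1, 15), "-10, 10")
  expect_error(ctrnn_model(matrix(0, 1, 1), 1, 0, thr = 1.2), "0, 1")
  m <- ctrnn_model(matrix(0, 2, 2), c(1, 2), 0)
  expect_s3_class(m, "fw_model")
  expect_equal(m$m, 2)
})

test_that("noise tracks have the requested statistics", {
  # zero gain: identically zero
  tr0 <- noise_track(noise_spec("gaussian"), gain = 0, duration = 10, seed = 1)
  expect_true(all(tr0$value == 0))

  # Gaussian knots: sample SD within 3 standard errors of the gain
  set.seed(2)
  kn <- flywalk:::noise_knots_one(noise_spec("gaussian"), gain = 2.5,
                                  nk = 4000, t_noise = 0.1)
  se <- 2.5 / sqrt(2 * (4000 - 1))
  expect_lt(abs(sd(kn) - 2.5), 3 * se)

  # OU long-run variance ~ sigma^2 / (2 theta)
  th <- 2
  sg <- 1.5
  set.seed(3)
  kn <- flywalk:::noise_knots_one(noise_spec("ou", theta = th, sigma = sg),
                                  gain = 1, nk = 20000, t_noise = 0.1)
  v_theory <- sg^2 / (2 * th)
  rho <- exp(-th * 0.1)
  n_eff <- length(kn) * (1 - rho) / (1 + rho)
  se_v <- v_theory * sqrt(2 / n_eff)
  expect_lt(abs(var(kn) - v_theory), 3 * se_v)

  # power-law noise: fitted periodogram slope within 0.2 of -alpha
  alpha <- 1
  set.seed(4)
  kn <- flywalk:::powerlaw_sequence(8192, alpha)
  spec_p <- Mod(fft(kn)[2:2048])^2
  f <- (1:2047)
  fit <- lm(log(spec_p) ~ log(f))
  expect_lt(abs(unname(coef(fit)[2]) + alpha), 0.2)
  expect_equal(sd(kn), 1, tolerance = 1e-8)

  expect_error(noise_track(noise_spec("gaussian"), 1, 10, t_noise = 0.001),
               ">=")
})

test_that("RK4 integration matches the closed-form linear solution", {
  m <- ctrnn_model(w = matrix(0, 1, 1), tau = 1, b = 0)
  tr <- integrate_ctrnn(m, 1, x0 = 1)
  expect_lt(abs(tr$x1[nrow(tr)] - exp(-1)), 1e-6)
  expect_equal(tr$out, sigmoid(tr$x1))
})

test_that("RK4 exhibits fourth-order convergence on a nonlinear network", {
  m <- ctrnn_model(w = matrix(5, 1, 1), tau = 0.5, b = -2)
  sol_at <- function(dt) {
    res <- flywalk:::cpp_ctrnn_sim(m$w, m$tau, m$b, 1.5, dt, round(2 / dt),
                                   matrix(0, 1, 0), m$t_noise, numeric(0),
                                   numeric(0), TRUE)
    res$states[nrow(res$states), 1]
  }
  ref <- sol_at(0.000625)
  e1 <- abs(sol_at(0.01) - ref)
  e2 <- abs(sol_at(0.005) - ref)
  expect_gt(e1 / e2, 8)   # ~16 for a 4th-order scheme
  expect_lt(e1 / e2, 40)
})

test_that("trajectories are reproducible and bounded for bounded input", {
  m <- ctrnn_model(w = matrix(c(5, -3, 4, 1), 2, 2), tau = c(0.5, 2),
                   b = c(-2, 1), w_noise = c(1, 1))
  t1 <- integrate_ctrnn(m, 5, noise = noise_spec("gaussian"), seed = 99)
  t2 <- integrate_ctrnn(m, 5, noise = noise_spec("gaussian"), seed = 99)
  expect_identical(t1, t2)

  # |x_i| bounded by max input + sum of incoming |w| (+ margin)
  set.seed(5)
  for (i in 1:3) {
    w <- matrix(runif(4, -20, 20), 2, 2)
    mm <- ctrnn_model(w, tau = c(0.2, 1), b = runif(2, -10, 10),
                      w_noise = c(2, 2))
    tr <- integrate_ctrnn(mm, 20, noise = noise_spec("gaussian"), seed = i)
    bound <- 8 * 2 + max(rowSums(abs(w))) + 5
    expect_true(all(abs(tr$x1) < bound & abs(tr$x2) < bound))
  }
})

test_that("initial conditions sample around equilibria with origin fallback", {
  mb <- fixture_bistable_model(w_noise = 0)
  set.seed(6)
  ics <- sample_initial_conditions(mb, 600)
  eq <- find_equilibria(mb)
  centers <- eq$x1
  # round-robin across the three equilibria: cluster means close to centers
  assigned <- sapply(ics[, 1], function(x) which.min(abs(x - centers)))
  cl_means <- tapply(ics[, 1], assigned, mean)
  expect_true(all(abs(cl_means - centers[as.integer(names(cl_means))]) < 0.5))

  m0 <- ctrnn_model(matrix(0, 1, 1), tau = 1, b = 0)
  set.seed(7)
  ic0 <- sample_initial_conditions(m0, 2000)
  expect_lt(abs(mean(ic0)), 3 / sqrt(2000) * 1.5)
})

test_that("thresholding the output produces walking/stationary bout series", {
  m_lo <- fixture_bistable_model(w_noise = 0.5, thr = 0.001)
  fly <- run_virtual_fly(m_lo, record_duration = 10, transient = 5, seed = 1)
  expect_true(all(fly$state == 1L))

  m_hi <- fixture_bistable_model(w_noise = 0.5, thr = 0.9999999)
  fly <- run_virtual_fly(m_hi, record_duration = 10, transient = 5, seed = 1)
  expect_true(all(fly$state == 0L))

  # zero-noise model at a stable subthreshold equilibrium stays stationary
  m_q <- fixture_bistable_model(w_noise = 0)
  fly <- run_virtual_fly(m_q, record_duration = 30, transient = 60, seed = 2,
                         noise = NULL)
  expect_true(all(fly$state == 0L))
})

test_that("noise-only baseline walking fraction follows the Gaussian law", {
  b_lo <- noise_only_baseline(-4, duration = 300, seed = 1)
  expect_gt(mean(b_lo$state), 0.999)
  b_mid <- noise_only_baseline(0, duration = 600, seed = 2)
  expect_lt(abs(mean(b_mid$state) - 0.5), 0.05)
  b_hi <- noise_only_baseline(4, duration = 300, seed = 3)
  expect_lt(mean(b_hi$state), 0.001)
})

test_that("models round-trip through JSON with bounds re-checked", {
  m <- ctrnn_model(w = matrix(c(5, -3, 4, 1), 2, 2), tau = c(0.5, 2),
                   b = c(-2, 1), w_noise = c(1, 0.5), w_odor = c(2, 0),
                   thr = 0.7, t_noise = 0.25)
  back <- model_from_json(model_to_json(m))
  expect_equal(back, m)
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(m, path)
  expect_equal(model_from_json(path), m)
})
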