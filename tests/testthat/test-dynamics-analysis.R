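test_that("equilibria of benchmark networks match independent oracles", {
  # trivial linear cases
  m0 <- ctrnn_model(matrix(0, 1, 1), tau = 1, b = 0)
  eq0 <- find_equilibria(m0)
  expect_equal(nrow(eq0), 1)
  expect_lt(abs(eq0$x1), 1e-9)

  # bistable benchmark vs bisection oracle on x = 10 sigma(x - 5)
  mb <- fixture_benchmark_10()
  eq <- find_equilibria(mb)
  expect_equal(nrow(eq), 3)
  f <- function(x) -x + 10 * sigmoid(x - 5)
  oracle <- c(bisect_root(f, -1, 2), bisect_root(f, 2, 8),
              bisect_root(f, 8, 12))
  expect_equal(sort(eq$x1), sort(oracle), tolerance = 1e-7)
  expect_equal(eq$stability, c("stable node", "unstable node", "stable node"))
  expect_true(all(eq$residual < 1e-9))
})

test_that("stability labels agree with long-run noiseless simulation", {
  mb <- fixture_benchmark_10()
  eq <- find_equilibria(mb)
  stable <- eq$x1[grepl("stable node", eq$stability) &
                  !grepl("^un", eq$stability)]
  for (xs in stable) {
    tr <- integrate_ctrnn(mb, 20, x0 = xs + 1e-3)
    expect_lt(abs(tr$x1[nrow(tr)] - xs), 1e-2)
  }
  # near the unstable point trajectories diverge toward a stable one
  xu <- eq$x1[eq$stability == "unstable node"]
  tr <- integrate_ctrnn(mb, 60, x0 = xu + 1e-3)
  expect_gt(abs(tr$x1[nrow(tr)] - xu), 1)
})

test_that("analytic Jacobian matches finite differences and hand values", {
  mb <- fixture_benchmark_10()
  # sigma'(0) = 1/4, so J = -1 + 10/4 = 1.5 at the unstable point x = 5
  expect_equal(ctrnn_jacobian(mb, 5)[1, 1], 1.5)

  m <- ctrnn_model(w = matrix(c(5, -3, 4, 1), 2, 2), tau = c(0.5, 2),
                   b = c(-2, 1))
  expect_equal(ctrnn_jacobian(m, c(0, 0)), -diag(1 / m$tau) +
                 sweep(m$w, 2, sigmoid(m$b) * (1 - sigmoid(m$b)), `*`) / m$tau)

  set.seed(12)
  for (i in 1:5) {
    x <- runif(2, -5, 5)
    J <- ctrnn_jacobian(m, x)
    h <- 1e-5
    J_fd <- matrix(0, 2, 2)
    for (j in 1:2) {
      e <- numeric(2)
      e[j] <- h
      J_fd[, j] <- (flywalk:::ctrnn_field(m, x + e) -
                    flywalk:::ctrnn_field(m, x - e)) / (2 * h)
    }
    expect_lt(max(abs(J - J_fd)), 1e-6)
  }

  # w = 0 gives J = -diag(1/tau)
  m0 <- ctrnn_model(matrix(0, 2, 2), tau = c(1, 4), b = c(0, 0))
  expect_equal(ctrnn_jacobian(m0, c(3, -2)), -diag(c(1, 0.25)))
})

test_that("eigenvalue sign patterns map to the stability taxonomy", {
  expect_equal(classify_stability(c(-1, -2)), "stable node")
  expect_equal(classify_stability(c(-1, 0.5)), "saddle")
  expect_equal(classify_stability(complex(real = c(-0.5, -0.5),
                                          imaginary = c(2, -2))),
               "stable spiral")
  expect_equal(classify_stability(c(1, 2)), "unstable node")
  expect_equal(classify_stability(c(0, -1)), "marginal")
})

test_that("trajectory density conserves counts and concentrates on attractors", {
  m <- ctrnn_model(w = matrix(0, 2, 2), tau = c(0.3, 0.3), b = c(0, 0))
  den <- trajectory_density(m, n_init = 40, duration = 10, n_grid = 100,
                            range = c(-50, 50), seed = 3)
  expect_equal(den$recorded, den$total)    # nothing leaves the range
  expect_equal(sum(den$counts), den$recorded)

  # zero-noise monostable model: late-time mass collapses onto x = 0
  den2 <- trajectory_density(m, n_init = 40, duration = 60, n_grid = 100,
                             range = c(-50, 50), seed = 4)
  g <- 100
  cell <- 100 / g
  centers <- -50 + (seq_len(g) - 0.5) * cell
  near <- abs(centers) <= 1
  late_mass <- sum(den2$counts[near, near]) / sum(den2$counts)
  expect_gt(late_mass, 0.8)  # includes the approach transits

  den3 <- trajectory_density(m, n_init = 40, duration = 10, n_grid = 100,
                             seed = 3)
  expect_equal(den3$counts, den$counts)    # seeded determinism
})

test_that("switching classification separates trapped and diffusive regimes", {
  # zero noise: deterministic trapping, never switches
  m_q <- fixture_bistable_model(w_noise = 0)
  cls_q <- classify_switching(m_q, noise = noise_spec("gaussian"),
                              n_init = 5, duration = 30, seed = 1)
  expect_equal(cls_q$class, 3L)

  # large noise gain: frequent switching (Class 1)
  m_n <- fixture_bistable_model(w_noise = 6)
  cls_n <- classify_switching(m_n, n_init = 10, duration = 120, seed = 2)
  expect_equal(cls_n$class, 1L)
  expect_gt(median(cls_n$switches$n_switches), 0)

  # monostable model: Class 3 by convention
  m_m <- ctrnn_model(matrix(0, 1, 1), tau = 1, b = 0, w_noise = 2)
  expect_equal(classify_switching(m_m, n_init = 3, duration = 10,
                                  seed = 3)$class, 3L)
})

test_that("Lyapunov spectra reproduce closed-form linear and fixed-point values", {
  # decoupled linear neurons: exponents are exactly -1/tau
  m <- ctrnn_model(matrix(0, 3, 3), tau = c(0.5, 1, 4), b = rep(0, 3))
  ly <- lyapunov_spectrum(m, total_steps = 2e4, transient = 0,
                          x0 = c(1, 1, 1))
  expect_equal(ly$exponents, -1 / c(4, 1, 0.5), tolerance = 1e-3)
  expect_lt(abs(sum(ly$exponents) - ly$trace_avg), 1e-3)
  expect_equal(ly$d_ky, 0)

  # at a hyperbolic stable equilibrium the spectrum equals Re(eigen(J))
  mb <- fixture_benchmark_10()
  eq <- find_equilibria(mb)
  x_up <- max(eq$x1)
  lam_oracle <- Re(eigen(ctrnn_jacobian(mb, x_up))$values)
  ly2 <- lyapunov_spectrum(mb, total_steps = 2e4, transient = 10, x0 = x_up)
  expect_equal(ly2$exponents, sort(lam_oracle, decreasing = TRUE),
               tolerance = 1e-3)

  # spectrum stable under doubling the step budget once converged
  ly3 <- lyapunov_spectrum(m, total_steps = 4e4, transient = 0,
                           x0 = c(1, 1, 1))
  expect_equal(ly3$exponents, ly$exponents, tolerance = 1e-3)
})

test_that("Kaplan-Yorke dimension follows the cumulative-sum formula", {
  expect_equal(kaplan_yorke(c(0.5, -1)), 1.5)
  expect_equal(kaplan_yorke(c(-0.1, -2)), 0)
  d <- kaplan_yorke(c(0.011, -0.5, -3))
  expect_gt(d, 1)
  expect_lt(d, 2)
  expect_equal(kaplan_yorke(c(1, 0.5)), 2)  # saturation at M
})

test_that("dynamics reports bundle the analyses and serialize to JSON", {
  mb <- fixture_bistable_model(w_noise = 3)
  rep <- dynamics_report(mb, lyapunov_steps = 5e3, switching_init = 3,
                         switching_duration = 20, seed = 1)
  expect_s3_class(rep$equilibria, "fw_equilibria")
  expect_true(rep$switching$class %in% 1:3)
  path <- withr::local_tempfile(fileext = ".json")
  dynamics_to_json(rep, path)
  parsed <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_length(parsed$equilibria, 3)
  expect_equal(parsed$switching_class, rep$switching$class)
})
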