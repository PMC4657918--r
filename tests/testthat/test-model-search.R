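test_that("inertia schedule runs from 0.9 down to 0.2", {
  expect_equal(pso_inertia(0, 200), 0.9)
  expect_equal(pso_inertia(200, 200), 0.2)
  expect_true(all(diff(pso_inertia(0:200, 200)) < 0))
})

test_that("PSO minimises a smooth benchmark inside the box", {
  sphere <- function(par, seed) sum(par^2)
  cfg <- swarm_config(n_particles = 20, max_iter = 60, seed = 11)
  fit <- pso_minimize(sphere, rep(-5, 5), rep(5, 5), cfg)
  expect_lt(fit$value, 1e-2)
  expect_true(all(fit$par >= -5 & fit$par <= 5))
  expect_equal(fit$n_evals, 20 * 60)
  expect_true(all(diff(fit$trace$best) <= 0))

  # deterministic per seed
  fit2 <- pso_minimize(sphere, rep(-5, 5), rep(5, 5), cfg)
  expect_equal(fit$par, fit2$par)

  # non-finite objective values are tolerated
  spiky <- function(par, seed) if (abs(par[1]) < 0.5) NaN else sum(par^2)
  fit3 <- pso_minimize(spiky, -5, 5, swarm_config(10, 20, seed = 2))
  expect_true(is.finite(fit3$value))
  expect_error(pso_minimize(sphere, numeric(0), numeric(0)), "box")
})

test_that("parameter vectors decode into models respecting the boxes", {
  box <- ctrnn_param_box(3)
  expect_length(box$lower, 9 + 3 + 3 + 3 + 2)
  set.seed(13)
  for (i in 1:10) {
    par <- runif(length(box$lower), box$lower, box$upper)
    m <- flywalk:::decode_basal_params(par, 3, TRUE)
    expect_s3_class(m, "fw_model")
    expect_equal(as.vector(m$w), unname(par[1:9]))
  }
  box0 <- ctrnn_param_box(2, with_noise = FALSE)
  m0 <- flywalk:::decode_basal_params((box0$lower + box0$upper) / 2, 2, FALSE)
  expect_equal(m0$w_noise, c(0, 0))
})

test_that("basal objective anchors degenerate dynamics at F = 1 and is seeded", {
  iv <- fixture_target_intervals()
  target <- build_target_histograms(iv, min_count = 1)
  obj <- make_basal_objective(target, m = 1, k_eval = 10,
                              record_duration = 50, transient = 10,
                              split_halves = FALSE)
  # huge positive bias with threshold near 0: the output is always walking
  par_deg <- c(0, 1, 10, 0, 0.01, 0.1)  # w, tau, b, w_noise, thr, t_noise
  expect_equal(obj(par_deg, seed = 1), 1, tolerance = 1e-12)
  # repeatable given the seed
  box <- ctrnn_param_box(1)
  set.seed(1)
  par <- runif(length(box$lower), box$lower, box$upper)
  expect_identical(obj(par, seed = 42), obj(par, seed = 42))
})

test_that("model discovery persists one scored model per run and condition", {
  iv <- fixture_target_intervals()
  target <- build_target_histograms(iv, min_count = 1)
  ledger <- withr::local_tempfile(fileext = ".jsonl")
  res <- discover_models(target, sizes = 1, with_noise = c(FALSE, TRUE),
                         n_runs = 2, config = swarm_config(4, 3),
                         ledger_path = ledger, k_eval = 3,
                         record_duration = 20, transient = 5,
                         split_halves = FALSE, seed = 5)
  expect_equal(nrow(res), 4)
  expect_true(all(is.finite(res$f)))
  expect_equal(sum(res$with_noise), 2)
  # every persisted model round-trips through JSON unchanged
  for (m in res$model) {
    expect_equal(model_from_json(model_to_json(m)), m)
  }
  expect_equal(length(readLines(ledger)), 4)
})

test_that("stage-2 fitting keeps the frozen dynamics untouched", {
  mb <- fixture_bistable_model()
  curve <- odor_frequency_curve(mb, n_virtual = 5, transient = 10, seed = 3)
  fit <- fit_odor_response(mb, curve,
                           config = swarm_config(4, 3, seed = 2),
                           n_virtual = 3, transient = 10)
  expect_identical(fit$model$w, mb$w)
  expect_identical(fit$model$tau, mb$tau)
  expect_identical(fit$model$b, mb$b)
  expect_identical(fit$model$w_noise, mb$w_noise)
  expect_gt(fit$model$thr, 0)
  expect_lt(fit$model$thr, 1)
  expect_gte(fit$rmse, 0)

  # protocol / target length mismatch is an error
  expect_error(fit_odor_response(mb, curve[-(1:10), ],
                                 config = swarm_config(2, 2)),
               "samples")
})

test_that("constant-zero output scores the RMS of the target curve", {
  mb <- fixture_bistable_model()
  tmpl_curve <- odor_frequency_curve(mb, n_virtual = 5, transient = 10,
                                     seed = 4)
  # a fly that never walks: threshold ~1 cannot be exceeded
  frozen <- mb
  frozen$w_odor <- 0
  frozen$thr <- 0.9999999
  curve0 <- odor_frequency_curve(frozen, n_virtual = 5, transient = 10,
                                 seed = 5)
  expect_true(all(curve0$freq == 0))
  rmse0 <- sqrt(mean((curve0$freq - tmpl_curve$freq)^2))
  expect_equal(rmse0, sqrt(mean(tmpl_curve$freq^2)))
})

test_that("objective evaluation seeds are deterministic mixtures", {
  s1 <- flywalk:::mix_seed(1, 3, 7)
  expect_identical(s1, flywalk:::mix_seed(1, 3, 7))
  expect_false(s1 == flywalk:::mix_seed(1, 4, 7))
  expect_true(s1 >= 0 && s1 < 2^31)
})
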