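# Noiseless vector field F(x) of a CTRNN (odor input off).
ctrnn_field <- function(model, x) {
  s <- sigmoid(x + model$b)
  (-x + as.vector(model$w %*% s)) / model$tau
}

#' Analytic Jacobian of a CTRNN
#'
#' `J[i, j] = w_ji sigma'(x_j + b_j) / tau_i` off the diagonal and
#' `-1/tau_i + w_ii sigma'(x_i + b_i) / tau_i` on it, with
#' `sigma'(z) = sigma(z)(1 - sigma(z))`.
#'
#' @param model `fw_model`.
#' @param x State vector.
#' @return M x M Jacobian matrix.
#' @export
ctrnn_jacobian <- function(model, x) {
  s <- sigmoid(x + model$b)
  dphi <- s * (1 - s)
  J <- sweep(model$w, 2, dphi, `*`) / model$tau
  diag(J) <- diag(J) - 1 / model$tau
  J
}

#' Stability label from Jacobian eigenvalues
#'
#' All real parts below `-tol` gives a stable node (spiral when any
#' eigenvalue is complex); any real part above `tol` gives an unstable point
#' (a saddle when signs are mixed); real parts within `tol` of zero are
#' marginal.
#'
#' @param eigenvalues Complex (or numeric) eigenvalues.
#' @param tol Tolerance on the real part (default 1e-8).
#' @return One of `"stable node"`, `"stable spiral"`, `"saddle"`,
#'   `"unstable node"`, `"unstable spiral"`, `"marginal"`.
#' @export
classify_stability <- function(eigenvalues, tol = 1e-8) {
  re <- Re(eigenvalues)
  im <- Im(eigenvalues)
  spiral <- any(abs(im) > tol)
  if (any(abs(re) <= tol)) return("marginal")
  if (all(re < 0)) return(if (spiral) "stable spiral" else "stable node")
  if (all(re > 0)) return(if (spiral) "unstable spiral" else "unstable node")
  "saddle"
}

#' Find the equilibria of a noiseless CTRNN
#'
#' Multi-start damped Newton iteration on `F(x) = 0` using the analytic
#' Jacobian, started from a regular grid over the state box plus random
#' starts. Converged solutions are deduplicated and re-verified; every
#' returned point satisfies `||F(x)|| < tol`. Each equilibrium is labelled
#' by the eigenvalues of the Jacobian evaluated there.
#'
#' @param model `fw_model` (noise gains are ignored).
#' @param box Search interval per state dimension (default \[-60, 60\]).
#' @param n_grid Grid points per dimension (default 5; total grid starts
#'   capped at 2000).
#' @param n_random Additional uniform random starts (default 500).
#' @param tol Residual tolerance (default 1e-9).
#' @param dedup_tol Distance below which two roots are considered identical.
#' @param seed RNG seed for the random starts.
#' @return A `fw_equilibria` tibble: state columns `x1..xM`, `residual`,
#'   `stability`, and an `eigenvalues` list column.
#' @export
find_equilibria <- function(model, box = c(-60, 60), n_grid = 5,
                            n_random = 500, tol = 1e-9, dedup_tol = 1e-6,
                            seed = 1) {
  m <- model$m
  grid_1d <- seq(box[1], box[2], length.out = n_grid)
  grid <- as.matrix(expand.grid(rep(list(grid_1d), m)))
  # draw the random starts from a private RNG stream so that calling this
  # inside a seeded simulation does not disturb the caller's reproducibility
  old_rng <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  if (nrow(grid) > 2000) grid <- grid[sample.int(nrow(grid), 2000), , drop = FALSE]
  rand <- matrix(runif(n_random * m, box[1], box[2]), n_random, m)
  if (is.null(old_rng)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_rng, envir = globalenv())
  }
  starts <- rbind(grid, rand)

  raw <- cpp_newton_roots(model$w, model$tau, model$b, starts, tol, 100L)
  roots <- list()
  for (k in seq_len(nrow(raw))) {
    x <- raw[k, ]
    dup <- FALSE
    for (r in roots) {
      if (sqrt(sum((r - x)^2)) < dedup_tol) {
        dup <- TRUE
        break
      }
    }
    if (!dup) roots[[length(roots) + 1L]] <- x
  }

  if (!length(roots)) {
    warn("no equilibrium found within the search box.")
    out <- tibble(residual = numeric(0), stability = character(0),
                  eigenvalues = list())
    for (i in seq_len(m)) out[[paste0("x", i)]] <- numeric(0)
    return(structure(out[, c(paste0("x", seq_len(m)),
                             "residual", "stability", "eigenvalues")],
                     class = c("fw_equilibria", class(tibble())), model = model))
  }

  rows <- purrr::map_dfr(roots, function(x) {
    ev <- eigen(ctrnn_jacobian(model, x), only.values = TRUE)$values
    row <- as.list(setNames(x, paste0("x", seq_len(m))))
    row$residual <- sqrt(sum(ctrnn_field(model, x)^2))
    row$stability <- classify_stability(ev)
    row$eigenvalues <- list(ev)
    as_tibble(row)
  })
  rows <- dplyr::arrange(rows, .data$x1)
  structure(rows, class = c("fw_equilibria", class(tibble())), model = model)
}

#' Trajectory density map of a (possibly noisy) CTRNN
#'
#' Simulates trajectories from random initial conditions and counts how
#' often the projection onto a chosen pair of neuron states visits each cell
#' of a square grid over \[-50, 50\] per axis; the map reveals the most
#' common activity levels.
#'
#' @param model `fw_model`.
#' @param axes Indices of the two projected neurons (default `c(1, 2)`).
#' @param n_init Number of initial conditions (study setting 1e4).
#' @param duration Simulated duration per trajectory (s).
#' @param noise Optional `fw_noise`.
#' @param stimulus Optional `fw_stimulus`.
#' @param n_grid Cells per axis (study setting 1000).
#' @param range State range covered per axis.
#' @param init `"uniform"` draws starts uniformly over `range`;
#'   `"equilibria"` draws them around the noiseless equilibria.
#' @param seed RNG seed.
#' @param dt Integration step (s).
#' @return A `fw_density` object: `counts` (n_grid x n_grid, row = first
#'   axis), `axes`, `range`, `n_init`, `recorded` (points inside the range),
#'   `total` (all simulated points).
#' @export
trajectory_density <- function(model, axes = c(1, 2), n_init = 1e4,
                               duration = 60, noise = NULL, stimulus = NULL,
                               n_grid = 1000, range = c(-50, 50),
                               init = c("uniform", "equilibria"), seed = 1,
                               dt = 0.01) {
  init <- match.arg(init)
  if (model$m == 1) axes <- c(1, 1)
  set.seed(seed)
  n_steps <- round(duration / dt)
  counts <- matrix(0L, n_grid, n_grid)
  u <- stimulus_steps(stimulus, n_steps, dt)
  starts <- if (init == "uniform") {
    matrix(runif(n_init * model$m, range[1], range[2]), n_init, model$m)
  } else {
    sample_initial_conditions(model, n_init)
  }
  recorded <- 0
  for (k in seq_len(n_init)) {
    knots <- model_noise_knots(model, noise, duration)
    recorded <- recorded + cpp_density_accumulate(
      model$w, model$tau, model$b, starts[k, ], dt, n_steps, knots,
      model$t_noise, model$w_odor, u, counts, axes[1] - 1L, axes[2] - 1L,
      range[1], range[2])
  }
  structure(
    list(counts = counts, axes = axes, range = range, n_init = n_init,
         recorded = recorded, total = n_init * (n_steps + 1)),
    class = "fw_density"
  )
}

#' Classify a model by how often noisy trajectories switch equilibria
#'
#' Starts trajectories around each stable equilibrium, assigns every state
#' to its nearest stable point with a hysteresis radius (25% of the smallest
#' inter-equilibrium distance) to suppress chatter, and counts transitions.
#' Class 1 models switch many times per 30-minute trajectory, Class 2 switch
#' rarely, Class 3 never switch; models with fewer than two stable points
#' are Class 3 by convention.
#'
#' @param model `fw_model`.
#' @param noise `fw_noise` (default Gaussian).
#' @param n_init Trajectories per stable point (study setting 1000).
#' @param duration Trajectory duration in seconds (study setting 1800).
#' @param class1_threshold Median switch count separating Class 1 from
#'   Class 2 (default 10 per 30 min, rescaled to `duration`).
#' @param equilibria Optional precomputed [find_equilibria()] result.
#' @param seed RNG seed.
#' @param dt Integration step (s).
#' @return A `fw_switching` list: `class` (1, 2 or 3), `switches` tibble
#'   (`start_point`, `trajectory`, `n_switches`), `stable_points`.
#' @export
classify_switching <- function(model, noise = noise_spec("gaussian"),
                               n_init = 1000, duration = 1800,
                               class1_threshold = 10, equilibria = NULL,
                               seed = 1, dt = 0.01) {
  eq <- equilibria %||% find_equilibria(model)
  stable <- eq[grepl("^stable", eq$stability), , drop = FALSE]
  pts <- as.matrix(stable[, paste0("x", seq_len(model$m)), drop = FALSE])
  if (nrow(pts) < 2) {
    return(structure(list(class = 3L,
                          switches = tibble(start_point = integer(0),
                                            trajectory = integer(0),
                                            n_switches = integer(0)),
                          stable_points = pts),
                     class = "fw_switching"))
  }
  dists <- as.matrix(stats::dist(pts))
  radius <- 0.25 * min(dists[dists > 0])
  set.seed(seed)
  n_steps <- round(duration / dt)
  res <- purrr::map_dfr(seq_len(nrow(pts)), function(e) {
    purrr::map_dfr(seq_len(n_init), function(tr) {
      x0 <- pts[e, ] + rnorm(model$m)
      knots <- model_noise_knots(model, noise, duration)
      tibble(start_point = e, trajectory = tr,
             n_switches = cpp_switch_count(model$w, model$tau, model$b, x0,
                                           dt, n_steps, knots, model$t_noise,
                                           pts, radius))
    })
  })
  thr <- class1_threshold * duration / 1800
  cls <- if (all(res$n_switches == 0)) 3L
         else if (median(res$n_switches) > thr) 1L else 2L
  structure(list(class = cls, switches = res, stable_points = pts),
            class = "fw_switching")
}

#' Lyapunov spectrum of a noiseless CTRNN
#'
#' Co-integrates the variational equations `d(delta)/dt = J(x) delta` with
#' the state using RK4, re-orthonormalising the perturbation vectors by
#' Gram-Schmidt every `t_ortho` steps and accumulating the log norms; the
#' exponents are the time-averaged log growth rates, sorted descending.
#'
#' @param model `fw_model` (noise ignored).
#' @param total_steps Number of integration steps after the transient
#'   (default 1e6).
#' @param t_ortho Re-orthonormalisation interval in steps (default 1000).
#' @param transient Discarded transient in seconds (default 300).
#' @param x0 Initial state (defaults to a small random perturbation of the
#'   origin).
#' @param seed RNG seed for the default initial state.
#' @param dt Integration step (s).
#' @return A `fw_lyapunov` list: `exponents` (1/s, descending), `d_ky`
#'   (Kaplan-Yorke dimension), `trace_avg` (time-averaged trace of the
#'   Jacobian), `total_steps`.
#' @export
lyapunov_spectrum <- function(model, total_steps = 1e6, t_ortho = 1000,
                              transient = 300, x0 = NULL, seed = 1,
                              dt = 0.01) {
  set.seed(seed)
  x0 <- x0 %||% rnorm(model$m, 0, 0.1)
  if (transient > 0) {
    res <- sim_raw(model, transient, x0, noise = NULL, stimulus = NULL,
                   dt = dt, keep_states = FALSE)
    if (!res$finite) abort("transient diverged; cannot compute the spectrum.")
    x0 <- res$x_final
  }
  ly <- cpp_lyapunov(model$w, model$tau, model$b, x0, dt, as.integer(total_steps),
                     as.integer(t_ortho))
  exponents <- sort(ly$exponents, decreasing = TRUE)
  structure(
    list(exponents = exponents, d_ky = kaplan_yorke(exponents),
         trace_avg = ly$trace_avg, total_steps = total_steps,
         t_ortho = t_ortho),
    class = "fw_lyapunov"
  )
}

#' Kaplan-Yorke dimension from a Lyapunov spectrum
#'
#' `D_KY = k + sum(lambda_1..lambda_k) / |lambda_(k+1)|`, with `k` the
#' largest index whose partial sum is non-negative. If even the largest
#' exponent is negative, `D_KY = 0`; if the full sum is non-negative the
#' dimension saturates at the number of exponents.
#'
#' @param exponents Lyapunov exponents, sorted descending.
#' @return Kaplan-Yorke dimension in \[0, M\].
#' @export
kaplan_yorke <- function(exponents) {
  lam <- sort(exponents, decreasing = TRUE)
  cum <- cumsum(lam)
  nonneg <- which(cum >= 0)
  if (!length(nonneg)) return(0)
  k <- max(nonneg)
  if (k == length(lam)) return(length(lam))
  k + cum[k] / abs(lam[k + 1])
}

#' Full dynamical-systems report for a model
#'
#' Bundles equilibria and stability, switching class, Lyapunov spectrum and
#' Kaplan-Yorke dimension, and (optionally) a trajectory density map.
#'
#' @param model `fw_model`.
#' @param noise `fw_noise` used for switching classification.
#' @param lyapunov_steps Steps for the Lyapunov spectrum.
#' @param switching_init,switching_duration Switching-classification load.
#' @param density Logical: also compute a density map (off by default; it
#'   dominates run time).
#' @param ... Passed to [trajectory_density()] when `density = TRUE`.
#' @param seed RNG seed.
#' @return A `fw_dynamics` list with elements `equilibria`, `switching`,
#'   `lyapunov`, and optionally `density`.
#' @export
dynamics_report <- function(model, noise = noise_spec("gaussian"),
                            lyapunov_steps = 1e6, switching_init = 1000,
                            switching_duration = 1800, density = FALSE,
                            ..., seed = 1) {
  eq <- find_equilibria(model, seed = seed)
  rep <- list(
    equilibria = eq,
    switching = classify_switching(model, noise, n_init = switching_init,
                                   duration = switching_duration,
                                   equilibria = eq, seed = seed),
    lyapunov = lyapunov_spectrum(model, total_steps = lyapunov_steps,
                                 seed = seed)
  )
  if (density) rep$density <- trajectory_density(model, seed = seed, ...)
  structure(rep, class = "fw_dynamics", model = model)
}

#' Serialize a dynamics report to JSON
#'
#' @param report `fw_dynamics`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
dynamics_to_json <- function(report, path) {
  eq <- report$equilibria
  payload <- list(
    equilibria = lapply(seq_len(nrow(eq)), function(i) {
      m <- sum(grepl("^x\\d+$", names(eq)))
      list(state = as.numeric(eq[i, paste0("x", seq_len(m))]),
           residual = eq$residual[i],
           stability = eq$stability[i],
           eigenvalues_re = Re(eq$eigenvalues[[i]]),
           eigenvalues_im = Im(eq$eigenvalues[[i]]))
    }),
    switching_class = report$switching$class,
    lyapunov = report$lyapunov$exponents,
    d_ky = report$lyapunov$d_ky
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
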