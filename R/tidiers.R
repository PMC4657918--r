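#' @export
tidy.fw_histogram <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
tidy.fw_model <- function(x, ...) {
  m <- x$m
  dplyr::bind_rows(
    tibble(term = paste0("w", rep(seq_len(m), m), rep(seq_len(m), each = m)),
           estimate = as.vector(x$w)),
    tibble(term = paste0("tau", seq_len(m)), estimate = x$tau),
    tibble(term = paste0("b", seq_len(m)), estimate = x$b),
    tibble(term = paste0("w_noise", seq_len(m)), estimate = x$w_noise),
    tibble(term = paste0("w_odor", seq_len(m)), estimate = x$w_odor),
    tibble(term = c("thr", "t_noise"), estimate = c(x$thr, x$t_noise))
  )
}

#' @export
glance.fw_model <- function(x, ...) {
  tibble(m = x$m, thr = x$thr, t_noise = x$t_noise,
         max_abs_weight = max(abs(x$w)), min_tau = min(x$tau))
}

#' @export
tidy.fw_pso <- function(x, ...) {
  x$trace
}

#' @export
glance.fw_pso <- function(x, ...) {
  tibble(best = x$value, n_evals = x$n_evals,
         n_particles = x$config$n_particles, max_iter = x$config$max_iter)
}

#' @export
tidy.fw_lyapunov <- function(x, ...) {
  tibble(order = seq_along(x$exponents), exponent = x$exponents)
}

#' @export
glance.fw_lyapunov <- function(x, ...) {
  tibble(largest = x$exponents[1], sum = sum(x$exponents),
         d_ky = x$d_ky, trace_avg = x$trace_avg,
         total_steps = x$total_steps)
}

#' @export
tidy.fw_equilibria <- function(x, ...) {
  out <- as_tibble(unclass(x))
  out$eigenvalues <- NULL
  out
}

#' @export
tidy.fw_switching <- function(x, ...) {
  x$switches
}

#' @export
glance.fw_switching <- function(x, ...) {
  tibble(class = x$class,
         n_stable = nrow(x$stable_points),
         median_switches = if (nrow(x$switches)) median(x$switches$n_switches) else 0)
}

#' @export
tidy.fw_density <- function(x, ...) {
  g <- nrow(x$counts)
  cell <- diff(x$range) / g
  centers <- x$range[1] + (seq_len(g) - 0.5) * cell
  tidyr::expand_grid(xi = centers, xj = centers) |>
    dplyr::mutate(count = as.vector(t(x$counts)),
                  log_prob = ifelse(.data$count > 0,
                                    log10(.data$count / x$recorded), NA_real_))
}

#' @export
glance.fw_odor_fit <- function(x, ...) {
  tibble(rmse = x$rmse, thr = x$thr,
         w_odor = paste(signif(x$w_odor, 4), collapse = ", "))
}

#' Plot a weighted bout-duration histogram
#'
#' @param object `fw_histogram`.
#' @param ... Unused.
#' @return A ggplot showing the duration-weighted bin heights on log-scaled
#'   duration bins.
#' @export
autoplot.fw_histogram <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(xmin = .data$lower, xmax = .data$upper,
                                   ymin = 0, ymax = .data$weighted)) +
    ggplot2::geom_rect(fill = "grey35", colour = "white", linewidth = 0.2) +
    ggplot2::labs(x = "bout duration (s)",
                  y = "weighted height (count x duration, s)") +
    ggplot2::theme_minimal()
}

#' Plot a trajectory density map
#'
#' @param object `fw_density`.
#' @param ... Unused.
#' @return A ggplot raster of log10 visit probability per cell.
#' @export
autoplot.fw_density <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$xi, .data$xj, fill = .data$log_prob)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white",
                                  name = "log10 P(visit)") +
    ggplot2::labs(x = sprintf("x%d", object$axes[1]),
                  y = sprintf("x%d", object$axes[2])) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot a simulated CTRNN trajectory
#'
#' @param object `fw_trajectory`.
#' @param ... Unused.
#' @return A ggplot of each neuron state plus the sigmoidal output over
#'   time.
#' @export
autoplot.fw_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"time",
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a population locomotor-frequency time-course
#'
#' @param bouts Tibble with columns `fly`, `time`, `state`, or a
#'   precomputed frequency tibble (`time`, `freq`).
#' @param smooth Moving-average window in seconds.
#' @return A ggplot of the locomotor frequency over time.
#' @export
plot_locomotor_frequency <- function(bouts, smooth = 1) {
  freq <- if (all(c("time", "freq") %in% names(bouts))) bouts
          else locomotor_frequency(bouts, smooth = smooth)
  ggplot2::ggplot(freq, ggplot2::aes(.data$time, .data$freq)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time (s)", y = "locomotor frequency") +
    ggplot2::theme_minimal()
}
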