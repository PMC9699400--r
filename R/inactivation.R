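#' Fit a first-order inactivation rate constant
#'
#' Prolonged exposure to an inactivating inhibitor often drives enzyme
#' activity down as a first-order, single-phase decay, `A(t) = exp(-k t)`,
#' which is linear on a semilog plot. The rate constant is the negative
#' slope of OLS of `ln(rel_activity)` on time, restricted to the decaying
#' phase: activity typically plateaus late in the time course, which a pure
#' exponential to zero cannot represent, so the default window is 0-1800 s
#' and user-overridable.
#'
#' @param series An [inactivation_series()] (time in s, activity as fraction
#'   of initial).
#' @param window Length-2 numeric, time bounds (s) of the fit window.
#' @param temperature Absolute temperature (K) used for the transition
#'   free-energy change.
#' @return An `inhib_fit` of subclass `inact_fit` with terms `k` (1/s) and
#'   `ddg` (kJ/mol, `NA` when no decay); fields `semilog_r`, `fit_window`,
#'   `no_inactivation`.
#' @examples
#' s <- gen_inactivation(k = 5e-4, t_grid = seq(0, 1800, by = 180),
#'                       inhibitor_conc = 1.5, noise_sigma = 0, seed = 1)
#' param_of(fit_inactivation(s), "k")
#' @export
fit_inactivation <- function(series, window = c(0, 1800),
                             temperature = 298.15) {
  series <- as_tibble(series)
  require_columns(series, c("time", "rel_activity"), "inactivation")
  stopifnot(length(window) == 2, window[1] < window[2])
  d <- dplyr::filter(series, .data$time >= window[1], .data$time <= window[2])
  if (nrow(d) < 5) abort("need at least 5 time points inside the fit window")
  if (any(d$rel_activity <= 0)) abort("activities must be positive for the semilog fit")
  la <- log(d$rel_activity)
  m <- lm(la ~ time, data = tibble(la = la, time = d$time))
  cf <- summary(m)$coefficients
  k <- -cf["time", "Estimate"]
  k_se <- cf["time", "Std. Error"]
  no_inact <- k <= 0
  if (no_inact) {
    warn("activity does not decay over the fit window: no inactivation (k <= 0)")
    k <- max(k, 0)
  }
  ddg <- if (k > 0) transition_free_energy(k, temperature) else NA_real_
  params <- tibble(
    term = c("k", "ddg"),
    estimate = c(k, ddg),
    std.error = c(k_se, NA),
    units = c("1/s", "kJ/mol")
  )
  new_inhib_fit(params, "inact_fit",
                r = stats::cor(d$time, la),
                residuals = stats::residuals(m),
                n_obs = nrow(d),
                method = "first-order semilog inactivation fit",
                semilog_r = stats::cor(d$time, la),
                fit_window = window, temperature = temperature,
                no_inactivation = no_inact, data = series)
}

#' Transition free-energy change of inactivation
#'
#' `ddG = -R T ln(k)`, in kJ/mol, with R = 8.314 J/(mol K) and natural log:
#' the free-energy change associated with the activated inactivation step.
#' A faster inactivation (larger k) gives a smaller barrier.
#'
#' @param k First-order inactivation rate constant, 1/s; must be positive.
#' @param temperature Absolute temperature, K.
#' @return Free-energy change, kJ/mol.
#' @examples
#' transition_free_energy(4.18e-4, 298.15)  # ~19.28 kJ/mol
#' @export
transition_free_energy <- function(k, temperature = 298.15) {
  if (any(k <= 0)) abort("k must be strictly positive")
  stopifnot(all(temperature > 0))
  -R_GAS * temperature * log(k) / 1000
}

#' @exportS3Method ggplot2::autoplot
autoplot.inact_fit <- function(object, ...) {
  d <- object$data
  d$in_window <- d$time >= object$fit_window[1] & d$time <= object$fit_window[2]
  k <- param_of(object, "k")
  line <- tibble(time = seq(object$fit_window[1], object$fit_window[2],
                            length.out = 50))
  line$log_a <- -k * line$time
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = log(.data$rel_activity))) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$in_window)) +
    ggplot2::geom_line(data = line, ggplot2::aes(y = .data$log_a),
                       colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "ln(relative activity)",
                  shape = "in fit window",
                  title = "Semilog inactivation time course")
}
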