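#' Mixed-inhibition parameter set
#'
#' Bundles the mixed-type reversible inhibition parameters: Km (mM), Vm (rate
#' units), Ki (uM, binding to free enzyme), alpha-Ki (uM, binding to the
#' enzyme-substrate complex). `alpha = alpha_ki / ki`; alpha near 1 means
#' noncompetitive, large alpha approaches pure competitive, anything else is
#' mixed.
#'
#' @param km Michaelis constant, mM.
#' @param vm Maximal rate.
#' @param ki Inhibition constant for the free enzyme, uM.
#' @param alpha_ki Inhibition constant for the ES complex, uM.
#' @return A list of class `inhibition_params` with `alpha` and a `mechanism`
#'   label attached.
#' @export
inhibition_params <- function(km, vm, ki, alpha_ki) {
  stopifnot(km > 0, vm > 0, ki > 0, alpha_ki > 0)
  alpha <- alpha_ki / ki
  structure(
    list(km = km, vm = vm, ki = ki, alpha_ki = alpha_ki, alpha = alpha,
         mechanism = classify_mechanism(alpha)),
    class = "inhibition_params"
  )
}

#' Classify a reversible-inhibition mechanism from alpha
#'
#' Operational windows: `alpha` within \[0.8, 1.25\] is labelled
#' `"noncompetitive"` (Ki ~ alpha-Ki), `alpha > 20` `"competitive-like"`
#' (negligible binding to the ES complex), everything else `"mixed"`.
#'
#' @param alpha Ratio alpha-Ki / Ki.
#' @return A mechanism label.
#' @export
classify_mechanism <- function(alpha) {
  stopifnot(is.finite(alpha) || alpha == Inf, alpha > 0)
  if (alpha >= 0.8 && alpha <= 1.25) return("noncompetitive")
  if (alpha > 20) return("competitive-like")
  "mixed"
}

#' Mixed-inhibition rate law
#'
#' \deqn{v = \frac{V_m [S]}{K_m (1 + [I]/K_i) + [S](1 + [I]/\alpha K_i)}}
#' At `i = 0` this is the Michaelis-Menten law; as `alpha_ki` grows the pure
#' competitive limit is approached; at saturating substrate the rate tends to
#' `vm / (1 + i/alpha_ki)`.
#'
#' @param s Substrate concentration, mM (vectorized).
#' @param i Inhibitor concentration, uM (vectorized).
#' @param params An [inhibition_params()] (or list with `km`, `vm`, `ki`,
#'   `alpha_ki`).
#' @return Reaction rate(s), same units as `vm`.
#' @export
mixed_rate <- function(s, i, params) {
  stopifnot(all(s >= 0), all(i >= 0))
  with(params, vm * s / (km * (1 + i / ki) + s * (1 + i / alpha_ki)))
}

#' Assess inhibition reversibility from rate vs. enzyme-concentration lines
#'
#' For a reversible inhibitor, plots of initial rate against enzyme
#' concentration at several fixed inhibitor concentrations are straight lines
#' through the origin whose slopes fall as \[I\] rises: the inhibitor lowers
#' the catalytic efficiency without consuming active enzyme. An irreversible
#' (titrating) inhibitor instead shifts the lines right, producing positive
#' x-intercepts that grow with \[I\].
#'
#' The verdict is `"reversible"` iff every per-level intercept's CI covers 0
#' and the slopes strictly decrease with inhibitor concentration;
#' `"irreversible-pattern"` iff the x-intercepts are positive and increase
#' with \[I\]; otherwise `"inconclusive"`. The origin test is family-wise:
#' the per-line CIs are Bonferroni-widened so that the joint "all lines pass
#' through the origin" statement holds at `conf_level`.
#'
#' @param data A [kinetic_dataset()] with >= 3 enzyme concentrations per
#'   inhibitor level and >= 2 inhibitor levels.
#' @param conf_level Family-wise confidence level for the intercept test.
#' @return A list of class `reversibility_result`: `lines` (per-level tibble
#'   of slope, intercept, SEs, x-intercept) and `verdict`.
#' @export
assess_reversibility <- function(data, conf_level = 0.95) {
  data <- as_tibble(data)
  require_columns(data, c("inhibitor_conc", "enzyme_conc", "rate"), "kinetics")
  levels <- sort(unique(data$inhibitor_conc))
  if (length(levels) < 2) {
    abort("need at least two inhibitor levels to test a slope trend")
  }
  # Bonferroni: joint origin test across all lines at conf_level
  line_level <- 1 - (1 - conf_level) / length(levels)
  lines <- purrr::map_dfr(levels, function(ic) {
    d <- dplyr::filter(data, .data$inhibitor_conc == ic)
    if (nrow(d) < 3) abort("need >= 3 enzyme concentrations per inhibitor level")
    m <- lm(rate ~ enzyme_conc, data = d)
    cf <- summary(m)$coefficients
    ci <- suppressMessages(confint(m, level = line_level))
    tibble(
      inhibitor_conc = ic,
      slope = cf["enzyme_conc", "Estimate"],
      slope_se = cf["enzyme_conc", "Std. Error"],
      intercept = cf["(Intercept)", "Estimate"],
      intercept_se = cf["(Intercept)", "Std. Error"],
      intercept_lo = ci["(Intercept)", 1],
      intercept_hi = ci["(Intercept)", 2],
      x_intercept = -cf["(Intercept)", "Estimate"] / cf["enzyme_conc", "Estimate"]
    )
  })
  tol <- 1e-8 * max(abs(data$rate))
  through_origin <- all(lines$intercept_lo <= tol & lines$intercept_hi >= -tol)
  slopes_decreasing <- slopes_decrease(lines, conf_level)
  x_pos <- lines$x_intercept > tol
  x_growing <- length(levels) >= 2 &&
    all(x_pos[lines$inhibitor_conc > 0]) &&
    all(diff(lines$x_intercept[lines$inhibitor_conc > 0]) > 0)
  verdict <- if (through_origin && slopes_decreasing) {
    "reversible"
  } else if (x_growing) {
    "irreversible-pattern"
  } else {
    "inconclusive"
  }
  structure(list(lines = lines, verdict = verdict, conf_level = conf_level),
            class = "reversibility_result")
}

# "Slopes decrease with [I]": a significantly negative trend of the fitted
# line slopes on inhibitor concentration (one-sided t), with no adjacent pair
# showing a significant increase. Point estimates of near-equal slopes swap
# order under noise, so raw strict ordering would be an unreliable criterion.
slopes_decrease <- function(lines, conf_level) {
  alpha <- 1 - conf_level
  d <- diff(lines$slope)
  se_d <- sqrt(lines$slope_se[-nrow(lines)]^2 + lines$slope_se[-1]^2)
  no_sig_increase <- all(d <= stats::qnorm(1 - alpha / 2) * se_d)
  if (nrow(lines) < 3) return(no_sig_increase && all(d < 0))
  m <- lm(slope ~ inhibitor_conc, data = lines)
  cf <- summary(m)$coefficients
  tval <- cf["inhibitor_conc", "Estimate"] / cf["inhibitor_conc", "Std. Error"]
  p_decreasing <- stats::pt(tval, df = nrow(lines) - 2)
  if (is.nan(tval)) {  # zero-residual degenerate fit
    p_decreasing <- if (cf["inhibitor_conc", "Estimate"] < 0) 0 else 1
  }
  no_sig_increase && p_decreasing < alpha
}

#' @export
print.reversibility_result <- function(x, ...) {
  cat("Reversibility assessment:", x$verdict, "\n")
  print(x$lines)
  invisible(x)
}

#' Per-level Lineweaver-Burk fits
#'
#' Ordinary least squares of `1/v` on `1/[S]` within each inhibitor level.
#' Under mixed inhibition the double-reciprocal line at inhibitor
#' concentration \[I\] has slope `(Km/Vm)(1 + [I]/Ki)` and intercept
#' `(1/Vm)(1 + [I]/alpha_Ki)`, so slopes and intercepts are both linear in
#' \[I\] — the basis for the secondary replots.
#'
#' @param data A [kinetic_dataset()]; all rates must be positive, with at
#'   least 4 substrate levels per inhibitor level.
#' @return An `inhib_fit` of subclass `lb_fit`; field `by_level` holds the
#'   per-level tibble (`inhibitor_conc`, `slope`, `slope_se`, `intercept`,
#'   `intercept_se`, `r`, `n`).
#' @export
fit_lineweaver_burk <- function(data) {
  data <- as_tibble(data)
  require_columns(data, c("substrate_conc", "inhibitor_conc", "rate"), "kinetics")
  zero <- which(data$rate <= 0)
  if (length(zero)) {
    abort(paste0("zero or negative rate in row(s) ", paste(zero, collapse = ", "),
                 ": reciprocal undefined"))
  }
  by_level <- data |>
    dplyr::group_by(.data$inhibitor_conc) |>
    dplyr::group_modify(function(d, key) {
      if (dplyr::n_distinct(d$substrate_conc) < 4) {
        abort("need >= 4 distinct substrate levels per inhibitor level")
      }
      inv_s <- 1 / d$substrate_conc
      inv_v <- 1 / d$rate
      m <- lm(inv_v ~ inv_s)
      cf <- summary(m)$coefficients
      tibble(
        slope = cf["inv_s", "Estimate"],
        slope_se = cf["inv_s", "Std. Error"],
        intercept = cf["(Intercept)", "Estimate"],
        intercept_se = cf["(Intercept)", "Std. Error"],
        r = stats::cor(inv_s, inv_v),
        n = nrow(d)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$inhibitor_conc)
  base <- dplyr::filter(by_level, .data$inhibitor_conc == min(.data$inhibitor_conc))
  params <- tibble(
    term = c("slope_LB_base", "intercept_LB_base"),
    estimate = c(base$slope, base$intercept),
    std.error = c(base$slope_se, base$intercept_se),
    units = c("", "")
  )
  new_inhib_fit(params, "lb_fit", n_obs = nrow(data),
                method = "Lineweaver-Burk double-reciprocal fits",
                by_level = by_level, data = data)
}

#' Secondary replots: Ki and alpha-Ki from Lineweaver-Burk lines
#'
#' Regresses the per-level Lineweaver-Burk slopes and intercepts on inhibitor
#' concentration. Because `slope_LB = (Km/Vm)(1 + [I]/Ki)`, the slope replot
#' gives `Ki = intercept / slope` of that regression; the intercept replot
#' gives `alpha_Ki` analogously. Km and Vm are recovered from the `[I] = 0`
#' limits of the replots.
#'
#' @param lb An `lb_fit` from [fit_lineweaver_burk()], or its `by_level`
#'   tibble.
#' @return An `inhib_fit` of subclass `replot_fit` with terms `ki`,
#'   `alpha_ki`, `alpha`, `km`, `vm`; fields `r_slope` / `r_intercept` hold
#'   the replot correlation coefficients, `mechanism` the label from
#'   [classify_mechanism()], and `consistent` is `FALSE` (with a warning)
#'   when a derived constant is non-positive.
#' @export
secondary_replots <- function(lb) {
  by_level <- if (inherits(lb, "lb_fit")) lb$by_level else as_tibble(lb)
  require_columns(by_level, c("inhibitor_conc", "slope", "intercept"), "replot")
  if (nrow(by_level) < 3) abort("need >= 3 inhibitor levels for secondary replots")
  i <- by_level$inhibitor_conc
  ms <- lm(slope ~ i, data = tibble(slope = by_level$slope, i = i))
  mi <- lm(icpt ~ i, data = tibble(icpt = by_level$intercept, i = i))
  cs <- summary(ms)$coefficients
  ci <- summary(mi)$coefficients
  ki <- cs["(Intercept)", "Estimate"] / cs["i", "Estimate"]
  alpha_ki <- ci["(Intercept)", "Estimate"] / ci["i", "Estimate"]
  # ratio-of-coefficients SEs by the delta method (independent-coef approx.)
  se_ratio <- function(cf, val) {
    a <- cf["(Intercept)", "Estimate"]; b <- cf["i", "Estimate"]
    abs(val) * sqrt((cf["(Intercept)", "Std. Error"] / a)^2 +
                    (cf["i", "Std. Error"] / b)^2)
  }
  vm <- 1 / ci["(Intercept)", "Estimate"]
  km <- cs["(Intercept)", "Estimate"] * vm
  consistent <- is.finite(ki) && is.finite(alpha_ki) && ki > 0 && alpha_ki > 0
  if (!consistent) {
    warn("non-positive derived inhibition constant: replots inconsistent with the mixed mechanism")
  }
  alpha <- alpha_ki / ki
  params <- tibble(
    term = c("ki", "alpha_ki", "alpha", "km", "vm"),
    estimate = c(ki, alpha_ki, alpha, km, vm),
    std.error = c(se_ratio(cs, ki), se_ratio(ci, alpha_ki), NA, NA, NA),
    units = c("uM", "uM", "", "mM", "rate")
  )
  new_inhib_fit(params, "replot_fit",
                r = stats::cor(i, by_level$slope),
                n_obs = 2L * nrow(by_level),  # two replot regressions
                method = "secondary replots (LB slope/intercept vs [I])",
                r_slope = stats::cor(i, by_level$slope),
                r_intercept = stats::cor(i, by_level$intercept),
                mechanism = if (consistent) classify_mechanism(alpha) else "inconsistent",
                consistent = consistent, by_level = by_level)
}

#' Direct nonlinear fit of the mixed-inhibition rate law
#'
#' Weighted nonlinear least squares of [mixed_rate()] on the raw rates,
#' avoiding the noise distortion of reciprocal space. Initialized from the
#' secondary-replot estimates. Uniform weights by default; `"inverse_v2"`
#' (1/v^2) mimics OLS-in-reciprocal-space behaviour.
#'
#' @param data A [kinetic_dataset()].
#' @param weights `"uniform"` or `"inverse_v2"`.
#' @param start Optional named list (`km`, `vm`, `ki`, `alpha_ki`) overriding
#'   the replot initializer.
#' @return An `inhib_fit` of subclass `mixed_fit` with terms `km`, `vm`,
#'   `ki`, `alpha_ki`, `alpha` and a `mechanism` field.
#' @export
fit_mixed_direct <- function(data, weights = c("uniform", "inverse_v2"),
                             start = NULL) {
  weights <- match.arg(weights)
  data <- as_tibble(data)
  require_columns(data, c("substrate_conc", "inhibitor_conc", "rate"), "kinetics")
  if (is.null(start)) {
    pos <- dplyr::filter(data, .data$rate > 0)
    rp <- secondary_replots(fit_lineweaver_burk(pos))
    start <- list(km = param_of(rp, "km"), vm = param_of(rp, "vm"),
                  ki = param_of(rp, "ki"), alpha_ki = param_of(rp, "alpha_ki"))
  }
  s <- data$substrate_conc; i <- data$inhibitor_conc; v <- data$rate
  w <- if (weights == "inverse_v2") 1 / pmax(v, 1e-12)^2 else rep(1, length(v))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ vm * s / (km * (1 + i / ki) + s * (1 + i / alpha_ki)),
      start = start, weights = w,
      lower = rep(1e-12, 4),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) {
      abort(paste0("direct mixed-inhibition fit did not converge (start: km=",
                   signif(start$km, 4), ", vm=", signif(start$vm, 4),
                   ", ki=", signif(start$ki, 4), ", alpha_ki=",
                   signif(start$alpha_ki, 4), "): ", conditionMessage(e)))
    }
  )
  cf <- summary(fit)$coefficients
  est <- cf[, "Estimate"]; se <- cf[, "Std. Error"]
  alpha <- est[["alpha_ki"]] / est[["ki"]]
  se_alpha <- alpha * sqrt((se[["alpha_ki"]] / est[["alpha_ki"]])^2 +
                           (se[["ki"]] / est[["ki"]])^2)
  params <- tibble(
    term = c("km", "vm", "ki", "alpha_ki", "alpha"),
    estimate = c(est[["km"]], est[["vm"]], est[["ki"]], est[["alpha_ki"]], alpha),
    std.error = c(se[["km"]], se[["vm"]], se[["ki"]], se[["alpha_ki"]], se_alpha),
    units = c("mM", "rate", "uM", "uM", "")
  )
  new_inhib_fit(params, "mixed_fit",
                residuals = as.numeric(stats::residuals(fit)),
                n_obs = nrow(data),
                method = paste0("direct nonlinear mixed-inhibition fit (",
                                weights, " weights)"),
                mechanism = classify_mechanism(alpha),
                data = data, nls_fit = fit)
}

#' @exportS3Method ggplot2::autoplot
autoplot.lb_fit <- function(object, ...) {
  d <- object$data
  d$inv_s <- 1 / d$substrate_conc
  d$inv_v <- 1 / d$rate
  d$level <- factor(d$inhibitor_conc)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$inv_s, y = .data$inv_v,
                                  colour = .data$level)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, fullrange = TRUE) +
    ggplot2::labs(x = "1/[S] (1/mM)", y = "1/v", colour = "[I] (uM)",
                  title = "Lineweaver-Burk")
}

#' @exportS3Method ggplot2::autoplot
autoplot.reversibility_result <- function(object, ...) {
  ggplot2::ggplot(object$lines,
                  ggplot2::aes(x = .data$inhibitor_conc, y = .data$slope)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "[I] (uM)", y = "d(rate)/d[E] (per nM)",
                  title = paste0("v vs [E] slopes (verdict: ", object$verdict, ")"))
}
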