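#' Fit an IC50 from a dose-response series
#'
#' Fits the four-parameter logistic (4PL)
#' \deqn{A([I]) = bottom + \frac{top - bottom}{1 + ([I]/IC_{50,app})^{h}}}
#' to relative-activity vs. inhibitor-concentration data by Levenberg-
#' Marquardt least squares, with the concentration axis handled on a log
#' scale internally for conditioning. The bottom plateau is free by default:
#' partial inhibitors (e.g. flavonoids that leave a residual ~25% activity)
#' bias a fixed-zero-floor model low.
#'
#' Two IC50s are reported: `ic50_app`, the 4PL midpoint, and `ic50`, the
#' concentration where the fitted curve crosses 50% activity — the assay's
#' operational definition. The two coincide when `bottom = 0` (and
#' `top = 100`); with a raised floor the crossing lies above the midpoint.
#'
#' @param data A [dose_response_series()] (or data frame with `conc` in uM and
#'   `rel_activity` in percent), at least 5 points spanning the 50% crossing.
#' @param fix_bottom Optional: fix the bottom plateau at this value (percent).
#' @param fix_hill Optional: fix the Hill slope.
#' @return An `inhib_fit` of subclass `ic50_fit` with parameters `top`,
#'   `bottom`, `hill`, `ic50_app` and `ic50` (the 50%-activity crossing;
#'   `NA` and flagged when the curve never crosses 50%). The field
#'   `ic50_defined` records whether the crossing exists.
#' @examples
#' d <- gen_dose_response(list(top = 100, bottom = 25, hill = 1,
#'                             ic50_app = 2.295),
#'                        conc_grid = c(0.5, 1, 2, 4, 8, 16, 40, 80),
#'                        noise_sigma = 0, seed = 1)
#' fit <- fit_ic50(d)
#' param_of(fit, "ic50")
#' @export
fit_ic50 <- function(data, fix_bottom = NULL, fix_hill = NULL) {
  data <- as_tibble(data)
  require_columns(data, c("conc", "rel_activity"), "dose_response")
  data <- dplyr::arrange(data, .data$conc)
  if (nrow(data) < 5) abort("need at least 5 concentrations to fit a 4PL")
  a <- data$rel_activity
  # accept activity on the fraction scale (0-1) as well as percent
  if (max(a) <= 2) {
    a <- a * 100
    if (!is.null(fix_bottom) && fix_bottom <= 2) fix_bottom <- fix_bottom * 100
  }
  lx <- log(data$conc)

  top0 <- max(a)
  bot0 <- if (is.null(fix_bottom)) min(a) else fix_bottom
  half <- (top0 + bot0) / 2
  lic0 <- lx[which.min(abs(a - half))]

  free <- c(top = TRUE, bottom = is.null(fix_bottom), hill = is.null(fix_hill),
            lic50 = TRUE)
  start <- list(top = top0, bottom = bot0,
                hill = if (is.null(fix_hill)) 1 else fix_hill, lic50 = lic0)

  fpl <- function(top, bottom, hill, lic50) {
    bottom + (top - bottom) / (1 + exp(hill * (lx - lic50)))
  }
  # build the model call over only the free parameters
  fixed <- start[!free]
  form <- stats::as.formula("a ~ fpl(top, bottom, hill, lic50)")
  env <- environment()
  for (nm in names(fixed)) assign(nm, fixed[[nm]], envir = env)
  lower <- c(top = 0, bottom = 0, hill = 1e-3, lic50 = min(lx) - 10)[free]
  upper <- c(top = Inf, bottom = Inf, hill = Inf, lic50 = max(lx) + 10)[free]
  fit <- minpack.lm::nlsLM(form, start = start[free],
                           lower = unname(lower), upper = unname(upper),
                           control = minpack.lm::nls.lm.control(maxiter = 200))

  est <- as.list(coef(fit))
  for (nm in names(fixed)) est[[nm]] <- fixed[[nm]]
  se <- setNames(rep(0, 4), c("top", "bottom", "hill", "lic50"))
  se[names(coef(fit))] <- summary(fit)$coefficients[, "Std. Error"]

  top <- est$top; bottom <- est$bottom; hill <- est$hill
  ic50_app <- exp(est$lic50)
  se_ic50_app <- ic50_app * se[["lic50"]]  # delta method on log scale

  # 50%-activity crossing of the fitted curve
  ic50_defined <- (bottom < 50 && top > 50)
  if (ic50_defined) {
    ratio <- (top - 50) / (50 - bottom)
    ic50 <- ic50_app * ratio^(1 / hill)
    se_ic50 <- delta_se_ic50(fit, free, fixed, hill, top, bottom, ic50_app)
  } else {
    warn("fitted curve never crosses 50% activity; operational IC50 undefined")
    ic50 <- NA_real_
    se_ic50 <- NA_real_
  }

  params <- tibble(
    term = c("top", "bottom", "hill", "ic50_app", "ic50"),
    estimate = c(top, bottom, hill, ic50_app, ic50),
    std.error = c(se[["top"]], se[["bottom"]], se[["hill"]], se_ic50_app, se_ic50),
    units = c("%", "%", "", "uM", "uM")
  )
  new_inhib_fit(params, "ic50_fit",
                residuals = as.numeric(stats::residuals(fit)),
                n_obs = nrow(data),
                method = "4PL dose-response fit",
                ic50_defined = ic50_defined,
                data = data, nls_fit = fit)
}

# SE of the 50%-crossing IC50 via numeric-gradient delta method on the free
# 4PL parameters.
delta_se_ic50 <- function(fit, free, fixed, hill, top, bottom, ic50_app) {
  cf <- coef(fit)
  V <- tryCatch(vcov(fit), error = function(e) NULL)
  if (is.null(V)) return(NA_real_)
  f <- function(p) {
    full <- as.list(p)
    for (nm in names(fixed)) full[[nm]] <- fixed[[nm]]
    with(full, exp(lic50) * ((top - 50) / (50 - bottom))^(1 / hill))
  }
  g <- vapply(seq_along(cf), function(i) {
    h <- max(abs(cf[i]) * 1e-6, 1e-9)
    p1 <- cf; p1[i] <- p1[i] + h
    p2 <- cf; p2[i] <- p2[i] - h
    (f(p1) - f(p2)) / (2 * h)
  }, numeric(1))
  sqrt(max(drop(t(g) %*% V %*% g), 0))
}

#' Evaluate a fitted 4PL curve
#'
#' @param fit An `ic50_fit`.
#' @param conc Concentrations (uM) at which to evaluate.
#' @return Predicted relative activity (percent).
#' @export
predict_activity <- function(fit, conc) {
  stopifnot(inherits(fit, "ic50_fit"))
  p <- setNames(fit$params$estimate, fit$params$term)
  p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
    (1 + (conc / p[["ic50_app"]])^p[["hill"]])
}

#' @exportS3Method ggplot2::autoplot
autoplot.ic50_fit <- function(object, n = 200, ...) {
  d <- object$data
  grid <- exp(seq(log(min(d$conc)), log(max(d$conc)), length.out = n))
  curve <- tibble(conc = grid, rel_activity = predict_activity(object, grid))
  ic50 <- param_of(object, "ic50")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$conc, y = .data$rel_activity)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[inhibitor] (uM)", y = "relative activity (%)",
                  title = "Dose-response (4PL)")
  if (is.finite(ic50)) {
    p <- p +
      ggplot2::geom_hline(yintercept = 50, linetype = "dashed", colour = "grey50") +
      ggplot2::geom_vline(xintercept = ic50, linetype = "dashed", colour = "grey50")
  }
  p
}
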