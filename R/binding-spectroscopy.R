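#' Inner-filter correction of a fluorescence titration
#'
#' Ligands that absorb at the excitation or emission wavelength attenuate the
#' measured fluorescence; before quenching analysis the raw signal is
#' corrected using the paired absorbances. The default dialect is
#' `Fc = Fm * exp((A1 + A2)/2)`; a base-10 variant
#' `Fc = Fm * 10^((A1 + A2)/2)` is selectable since both circulate in the
#' literature. The dialect used is recorded on the returned series.
#'
#' @param series A [titration_series()] with `abs_ex` / `abs_em` columns. If
#'   the absorbance columns are absent the series passes through unchanged
#'   with a warning.
#' @param dialect `"exp"` (natural) or `"ten"` (base-10).
#' @return The series with `fluorescence` replaced by the corrected values
#'   (raw values kept in `fluorescence_raw`) and attribute `ifc_dialect` set.
#' @export
inner_filter_correct <- function(series, dialect = c("exp", "ten")) {
  dialect <- match.arg(dialect)
  x <- as_tibble(series)
  require_columns(x, c("quencher_conc", "fluorescence"), "titration")
  if (!all(c("abs_ex", "abs_em") %in% names(x))) {
    warn("no absorbance channels present: inner-filter correction skipped")
    return(series)
  }
  if (any(x$abs_ex < 0 | x$abs_em < 0)) abort("absorbances must be non-negative")
  if (any(x$abs_ex > 2 | x$abs_em > 2)) {
    warn("absorbance > 2: inner-filter correction unreliable at this optical density")
  }
  half <- (x$abs_ex + x$abs_em) / 2
  factor <- if (dialect == "exp") exp(half) else 10^half
  x$fluorescence_raw <- x$fluorescence
  x$fluorescence <- x$fluorescence * factor
  out <- validate_titration(x)
  attr(out, "ifc_dialect") <- dialect
  out
}

#' Stern-Volmer quenching fit
#'
#' OLS of `F0/F` on quencher concentration (converted to mol/L) with a free
#' intercept: `F0/F = 1 + Ksv [Q]`. The bimolecular quenching rate constant
#' is `Kq = Ksv / tau0`, with `tau0` the fluorophore lifetime (1e-8 s for
#' biopolymers by default). `Kq` far above the diffusion-collision limit
#' (~2e10 L/(mol s)) indicates ground-state complex formation (static
#' quenching) rather than collisional quenching.
#'
#' @param series A (corrected) [titration_series()] with >= 5 nonzero
#'   quencher points; `F0` is the fluorescence of the zero-quencher point.
#' @param tau0 Fluorophore lifetime, s.
#' @return An `inhib_fit` of subclass `sv_fit` with terms `ksv` (L/mol),
#'   `kq` (L/(mol s)) and `sv_intercept`; fields `temperature` and
#'   `intercept_flagged` (TRUE when the intercept deviates from 1 by > 5%).
#' @export
fit_stern_volmer <- function(series, tau0 = 1e-8) {
  x <- as_tibble(series)
  require_columns(x, c("quencher_conc", "fluorescence"), "titration")
  stopifnot(tau0 > 0)
  f0 <- x$fluorescence[x$quencher_conc == 0][1]
  if (is.na(f0)) abort("series must contain a zero-quencher point defining F0")
  d <- dplyr::filter(x, .data$quencher_conc > 0)
  if (nrow(d) < 5) abort("need >= 5 nonzero quencher points")
  if (any(d$fluorescence >= f0 * 1.1)) {
    abort("fluorescence exceeds F0 by > 10% at nonzero quencher: not a quenching series")
  }
  q_molar <- d$quencher_conc * 1e-6
  ratio <- f0 / d$fluorescence
  m <- lm(ratio ~ q_molar, data = tibble(ratio = ratio, q_molar = q_molar))
  cf <- summary(m)$coefficients
  ksv <- cf["q_molar", "Estimate"]
  icpt <- cf["(Intercept)", "Estimate"]
  flagged <- abs(icpt - 1) > 0.05
  if (flagged) {
    warn(paste0("Stern-Volmer intercept ", signif(icpt, 4),
                " deviates from 1 by > 5%"))
  }
  params <- tibble(
    term = c("ksv", "kq", "sv_intercept"),
    estimate = c(ksv, ksv / tau0, icpt),
    std.error = c(cf["q_molar", "Std. Error"],
                  cf["q_molar", "Std. Error"] / tau0,
                  cf["(Intercept)", "Std. Error"]),
    units = c("L/mol", "L/(mol s)", "")
  )
  new_inhib_fit(params, "sv_fit",
                r = stats::cor(q_molar, ratio),
                residuals = stats::residuals(m),
                n_obs = nrow(d),
                method = "Stern-Volmer quenching fit",
                temperature = x$temperature[1], tau0 = tau0,
                intercept_flagged = flagged, data = x)
}

#' Classify the quenching mechanism across temperatures
#'
#' `"static"` iff the smallest `Kq` exceeds the maximum diffusion-collision
#' quenching rate constant (2.0e10 L/(mol s)) and, when two or more
#' temperatures are available, `Ksv` strictly decreases with temperature
#' (complex dissociation at higher T). `"dynamic"` iff every `Kq` is at or
#' below the diffusion limit and `Ksv` increases with temperature (faster
#' collisions). Conflicting signals give `"ambiguous"`.
#'
#' @param results A list of `sv_fit` objects, or a tibble with columns
#'   `temperature`, `ksv`, `kq`.
#' @param kq_limit Diffusion-limited quenching rate constant, L/(mol s).
#' @return `"static"`, `"dynamic"` or `"ambiguous"`.
#' @export
classify_quenching <- function(results, kq_limit = 2e10) {
  tab <- if (is.data.frame(results)) {
    as_tibble(results)
  } else {
    purrr::map_dfr(results, function(f) {
      tibble(temperature = f$temperature,
             ksv = param_of(f, "ksv"), kq = param_of(f, "kq"))
    })
  }
  require_columns(tab, c("temperature", "ksv", "kq"), "quenching")
  tab <- dplyr::arrange(tab, .data$temperature)
  if (nrow(tab) == 0) abort("need at least one temperature")
  above <- min(tab$kq) > kq_limit
  below <- max(tab$kq) <= kq_limit
  if (nrow(tab) == 1) {
    return(if (above) "static" else if (below) "dynamic" else "ambiguous")
  }
  decreasing <- all(diff(tab$ksv) < 0)
  increasing <- all(diff(tab$ksv) > 0)
  if (above && decreasing) return("static")
  if (below && increasing) return("dynamic")
  "ambiguous"
}

#' Double-log binding fit: Ka and binding-site number
#'
#' For static quenching by complex formation,
#' `log10((F0 - F)/F) = log10(Ka) + n log10([Q])` with quencher concentration
#' in mol/L; OLS in log-log space yields the binding constant `Ka`
#' (10^intercept, L/mol) and the number of binding sites `n` (slope).
#' Points with `F >= F0` (log term undefined) are dropped with a warning.
#'
#' @param series A (corrected) [titration_series()] with >= 5 usable nonzero
#'   quencher points.
#' @return An `inhib_fit` of subclass `binding_fit` with terms `ka` (L/mol)
#'   and `n_sites`; field `temperature`.
#' @export
fit_binding <- function(series) {
  x <- as_tibble(series)
  require_columns(x, c("quencher_conc", "fluorescence"), "titration")
  f0 <- x$fluorescence[x$quencher_conc == 0][1]
  if (is.na(f0)) abort("series must contain a zero-quencher point defining F0")
  d <- dplyr::filter(x, .data$quencher_conc > 0)
  bad <- d$fluorescence >= f0
  if (any(bad)) {
    warn(paste0(sum(bad), " point(s) with F >= F0 dropped (log term undefined)"))
    d <- d[!bad, , drop = FALSE]
  }
  if (nrow(d) < 5) abort("need >= 5 nonzero quencher points with F < F0")
  lq <- log10(d$quencher_conc * 1e-6)
  ly <- log10((f0 - d$fluorescence) / d$fluorescence)
  m <- lm(ly ~ lq, data = tibble(ly = ly, lq = lq))
  cf <- summary(m)$coefficients
  ka <- 10^cf["(Intercept)", "Estimate"]
  n <- cf["lq", "Estimate"]
  params <- tibble(
    term = c("ka", "n_sites"),
    estimate = c(ka, n),
    std.error = c(ka * log(10) * cf["(Intercept)", "Std. Error"],  # delta method
                  cf["lq", "Std. Error"]),
    units = c("L/mol", "")
  )
  new_inhib_fit(params, "binding_fit",
                r = stats::cor(lq, ly),
                residuals = stats::residuals(m),
                n_obs = nrow(d),
                method = "double-log binding fit",
                temperature = x$temperature[1], data = x)
}

#' van't Hoff thermodynamics of binding
#'
#' OLS of `ln Ka` on `1/T`: `ln Ka = -dH/(R T) + dS/R`, assuming a
#' temperature-independent enthalpy over the measured range. Gibbs energy is
#' computed at every input temperature both as `dG = dH - T dS` and as
#' `-R T ln Ka`; the two agree when the data are van't Hoff consistent.
#' Spontaneity (`dG < 0` at the reference temperature, the lowest supplied)
#' and the dominant-force label from [classify_forces()] are attached.
#'
#' @param ka_by_temp A tibble/data frame with columns `temperature` (K) and
#'   `ka` (L/mol), or a named numeric vector (names = temperature in K).
#'   At least two temperatures.
#' @return An `inhib_fit` of subclass `thermo_fit` with terms `dh` (kJ/mol)
#'   and `ds` (J/(mol K)); fields `dg_by_temp` (tibble with both dG
#'   definitions), `force_type`, `spontaneous`.
#' @examples
#' vant_hoff(tibble::tibble(temperature = c(298.15, 304.15, 310.15),
#'                          ka = c(5.52e4, 3.52e4, 2.05e4)))
#' @export
vant_hoff <- function(ka_by_temp) {
  tab <- if (is.data.frame(ka_by_temp)) {
    as_tibble(ka_by_temp)
  } else {
    tibble(temperature = as.numeric(names(ka_by_temp)),
           ka = as.numeric(ka_by_temp))
  }
  require_columns(tab, c("temperature", "ka"), "van't Hoff")
  tab <- dplyr::arrange(tab, .data$temperature)
  if (nrow(tab) < 2) abort("need Ka at >= 2 temperatures (slope undefined for one)")
  if (any(tab$ka <= 0)) abort("Ka values must be positive")
  inv_t <- 1 / tab$temperature
  ln_ka <- log(tab$ka)
  m <- lm(ln_ka ~ inv_t, data = tibble(ln_ka = ln_ka, inv_t = inv_t))
  cf <- summary(m)$coefficients
  dh <- -R_GAS * cf["inv_t", "Estimate"] / 1000        # kJ/mol
  ds <- R_GAS * cf["(Intercept)", "Estimate"]          # J/(mol K)
  dh_se <- R_GAS * cf["inv_t", "Std. Error"] / 1000
  ds_se <- R_GAS * cf["(Intercept)", "Std. Error"]
  dg <- tibble(
    temperature = tab$temperature,
    dg = dh - tab$temperature * ds / 1000,
    dg_from_ka = -R_GAS * tab$temperature * log(tab$ka) / 1000
  )
  force_type <- classify_forces(dh, ds)
  params <- tibble(
    term = c("dh", "ds"),
    estimate = c(dh, ds),
    std.error = c(dh_se, ds_se),
    units = c("kJ/mol", "J/(mol K)")
  )
  new_inhib_fit(params, "thermo_fit",
                r = stats::cor(inv_t, ln_ka),
                residuals = stats::residuals(m),
                n_obs = nrow(tab),
                method = "van't Hoff regression",
                dg_by_temp = dg,
                force_type = force_type,
                spontaneous = dg$dg[1] < 0,
                data = tab)
}

#' Classify dominant binding forces from thermodynamic signs
#'
#' Sign heuristics for small-molecule / biomacromolecule binding: both
#' enthalpy and entropy negative points to van der Waals contacts and
#' hydrogen bonding; both positive to hydrophobic burial; negative enthalpy
#' with positive entropy to electrostatic interactions.
#'
#' @param dh Binding enthalpy, kJ/mol (or a `thermo_fit`).
#' @param ds Binding entropy, J/(mol K); ignored when `dh` is a fit.
#' @return One of `"hydrogen bonds + van der Waals"`, `"hydrophobic"`,
#'   `"electrostatic"`, `"indeterminate"`.
#' @export
classify_forces <- function(dh, ds = NULL) {
  if (inherits(dh, "thermo_fit")) {
    ds <- param_of(dh, "ds")
    dh <- param_of(dh, "dh")
  }
  stopifnot(is.finite(dh), is.finite(ds))
  if (dh < 0 && ds < 0) return("hydrogen bonds + van der Waals")
  if (dh > 0 && ds > 0) return("hydrophobic")
  if (dh < 0 && ds > 0) return("electrostatic")
  "indeterminate"
}

#' @exportS3Method ggplot2::autoplot
autoplot.sv_fit <- function(object, ...) {
  x <- object$data
  f0 <- x$fluorescence[x$quencher_conc == 0][1]
  d <- dplyr::filter(x, .data$quencher_conc > 0)
  d$ratio <- f0 / d$fluorescence
  ggplot2::ggplot(d, ggplot2::aes(x = .data$quencher_conc * 1e-6, y = .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue", linewidth = 0.5) +
    ggplot2::labs(x = "[Q] (mol/L)", y = "F0/F", title = "Stern-Volmer plot")
}

#' @exportS3Method ggplot2::autoplot
autoplot.thermo_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = 1 / .data$temperature, y = log(.data$ka))) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue", linewidth = 0.5) +
    ggplot2::labs(x = "1/T (1/K)", y = "ln Ka", title = "van't Hoff plot")
}
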