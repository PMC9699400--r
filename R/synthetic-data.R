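#' Ground-truth preset emulating the quercetin vs. acetylcholinesterase system
#'
#' Bundles literature-reported parameter values for quercetin inhibiting
#' acetylcholinesterase (with galantamine hydrobromide as the comparator
#' drug) as generator truth, so every analysis stage can be validated by
#' parameter recovery: dose-response (IC50 4.59 uM with a ~25% residual
#' activity floor; galantamine IC50 0.29 uM), mixed-type inhibition constants
#' (Ki 6.17 uM, alpha-Ki 19.53 uM), the inactivation rate-constant ladder
#' (4.18 to 6.41 x 1e-4 1/s over 1.5-15 uM), the three-temperature quenching
#' and binding constants (Ksv 6.21/4.81/3.33 x 1e4 L/mol, Ka 5.52/3.52/2.05
#' x 1e4 L/mol, n 0.75/0.69/0.67 at 298.15/304.15/310.15 K), and a
#' level-dependent combination interaction (synergistic at 30/50% inhibition,
#' additive at 70%). Km and Vm for the kinetic design, the fluorescence
#' scale, and the inactivation plateau are not reported and are set to
#' realistic assay values (Km 0.12 mM for acetylthiocholine, unit Vm,
#' F0 1000 a.u., plateau 0.25).
#'
#' @return A named list of truth-parameter sets, one per assay class.
#' @export
quercetin_ache_preset <- function() {
  list(
    dose_response = list(top = 100, bottom = 25, hill = 1,
                         ic50_app = 4.59 / 2, ic50 = 4.59),
    comparator_dose_response = list(top = 100, bottom = 0, hill = 1,
                                    ic50_app = 0.29, ic50 = 0.29),
    kinetics = inhibition_params(km = 0.12, vm = 1, ki = 6.17, alpha_ki = 19.53),
    inactivation = tibble(
      inhibitor_conc = c(1.5, 3, 6, 15),
      k = c(4.18e-4, 5.73e-4, 6.04e-4, 6.41e-4)
    ),
    inactivation_plateau = 0.25,
    titration = tibble(
      temperature = c(298.15, 304.15, 310.15),
      ksv = c(6.21e4, 4.81e4, 3.33e4),
      ka = c(5.52e4, 3.52e4, 2.05e4),
      n = c(0.75, 0.69, 0.67)
    ),
    f0 = 1000,
    tau0 = 1e-8,
    interaction = c(`30` = 0.8, `50` = 0.85, `70` = 1.0)
  )
}

new_manifest <- function(preset, truth, noise, sigma, grid, seed, notes = character()) {
  structure(
    list(preset = preset, truth = truth, noise_model = noise, noise_sigma = sigma,
         design = grid, seed = seed, notes = notes),
    class = "generator_manifest"
  )
}

#' @export
print.generator_manifest <- function(x, ...) {
  cat("<generator manifest> preset:", x$preset, "| noise:", x$noise_model,
      "sigma =", x$noise_sigma, "| seed:", x$seed, "\n")
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Retrieve a generated table's manifest
#'
#' @param x A generator output.
#' @return The `generator_manifest` recording truth, noise and seed.
#' @export
manifest_of <- function(x) attr(x, "manifest")

apply_noise <- function(mean_value, sigma, noise = c("multiplicative", "additive")) {
  noise <- match.arg(noise)
  if (sigma == 0) return(mean_value)
  eps <- rnorm(length(mean_value))
  if (noise == "multiplicative") mean_value * (1 + sigma * eps)
  else mean_value + sigma * eps
}

#' Generate a synthetic dose-response series
#'
#' Mean activity follows the 4PL
#' `A = bottom + (top - bottom)/(1 + (conc/ic50_app)^hill)` with
#' multiplicative gaussian noise of coefficient of variation `noise_sigma`
#' (constant CV matches plate-reader error structure; additive noise is
#' selectable). The manifest warns when the grid does not span the 50%
#' crossing.
#'
#' @param params 4PL truth: list with `top`, `bottom`, `hill`, `ic50_app`
#'   (activity percent, concentration uM).
#' @param conc_grid Concentration grid, uM.
#' @param noise_sigma Noise level (fractional for multiplicative noise).
#' @param seed RNG seed (mandatory; the generator neither reads nor leaks
#'   global RNG state).
#' @param noise `"multiplicative"` or `"additive"`.
#' @param preset Preset name recorded in the manifest.
#' @return A [dose_response_series()] with a `generator_manifest` attribute.
#' @export
gen_dose_response <- function(params, conc_grid, noise_sigma, seed,
                              noise = c("multiplicative", "additive"),
                              preset = "custom") {
  noise <- match.arg(noise)
  conc_grid <- sort(conc_grid)
  mean_a <- params$bottom + (params$top - params$bottom) /
    (1 + (conc_grid / params$ic50_app)^params$hill)
  a <- with_seed(seed, apply_noise(mean_a, noise_sigma, noise))
  a <- pmax(a, 1e-6)
  out <- dose_response_series(conc_grid, a)
  notes <- character()
  crossing_in_grid <- min(mean_a) < 50 && max(mean_a) > 50
  if (!crossing_in_grid) notes <- "grid does not span the 50% activity crossing"
  attr(out, "manifest") <- new_manifest(preset, params, noise, noise_sigma,
                                        list(conc_grid = conc_grid), seed, notes)
  out
}

#' Generate a synthetic initial-rate kinetic dataset
#'
#' Rates follow the mixed-inhibition law [mixed_rate()] over a substrate x
#' inhibitor grid; when `e_grid` is supplied the rate scales linearly with
#' enzyme concentration relative to `e_ref` (the reversible case). A
#' positive `irreversible_q` instead titrates active enzyme away,
#' `E_eff = max(E - q [I], 0)`, producing the irreversible pattern of
#' positive, growing x-intercepts in v-vs-[E] plots.
#'
#' @param params An [inhibition_params()] truth set.
#' @param s_grid Substrate concentrations, mM.
#' @param i_grid Inhibitor concentrations, uM.
#' @param e_grid Optional enzyme concentrations, nM (crossed with `i_grid`
#'   at fixed `s_fixed`).
#' @param s_fixed Substrate level (mM) used when varying enzyme.
#' @param e_ref Reference enzyme concentration, nM.
#' @param irreversible_q Active-enzyme titration coefficient, nM active
#'   enzyme lost per uM inhibitor; 0 for a reversible inhibitor.
#' @inheritParams gen_dose_response
#' @return A [kinetic_dataset()] with a manifest.
#' @export
gen_kinetics <- function(params, s_grid, i_grid, e_grid = NULL,
                         noise_sigma = 0, seed,
                         s_fixed = 0.25, e_ref = 0.57, irreversible_q = 0,
                         noise = c("multiplicative", "additive"),
                         preset = "custom") {
  noise <- match.arg(noise)
  if (is.null(e_grid)) {
    grid <- tidyr::expand_grid(substrate_conc = sort(s_grid),
                               inhibitor_conc = sort(i_grid))
    grid$enzyme_conc <- e_ref
  } else {
    grid <- tidyr::expand_grid(enzyme_conc = sort(e_grid),
                               inhibitor_conc = sort(i_grid))
    grid$substrate_conc <- s_fixed
  }
  e_eff <- pmax(grid$enzyme_conc - irreversible_q * grid$inhibitor_conc, 0)
  mean_v <- mixed_rate(grid$substrate_conc, grid$inhibitor_conc, params) *
    e_eff / e_ref
  v <- with_seed(seed, apply_noise(mean_v, noise_sigma, noise))
  out <- kinetic_dataset(grid$substrate_conc, grid$inhibitor_conc,
                         grid$enzyme_conc, pmax(v, 0))
  attr(out, "manifest") <- new_manifest(
    preset, params, noise, noise_sigma,
    list(s_grid = s_grid, i_grid = i_grid, e_grid = e_grid,
         s_fixed = s_fixed, e_ref = e_ref, irreversible_q = irreversible_q),
    seed
  )
  out
}

#' Generate a synthetic inactivation time course
#'
#' `A(t) = max(exp(-k t), plateau)` with noise: first-order decay joined to
#' the late plateau seen in long time courses (residual activity that the
#' pure exponential cannot represent). Values are clamped to the valid
#' (0, 1.05] activity range after noise.
#'
#' @param k True inactivation rate constant, 1/s (>= 0).
#' @param t_grid Time points, s.
#' @param plateau Late-phase residual activity fraction (0 disables).
#' @param inhibitor_conc Inhibitor concentration label, uM.
#' @inheritParams gen_dose_response
#' @return An [inactivation_series()] with a manifest recording the decay
#'   window (times before the plateau crossing).
#' @export
gen_inactivation <- function(k, t_grid, plateau = 0, inhibitor_conc = 1,
                             noise_sigma = 0, seed,
                             noise = c("multiplicative", "additive"),
                             preset = "custom") {
  noise <- match.arg(noise)
  stopifnot(k >= 0, plateau >= 0, plateau < 1)
  t_grid <- sort(t_grid)
  mean_a <- pmax(exp(-k * t_grid), plateau)
  a <- with_seed(seed, apply_noise(mean_a, noise_sigma, noise))
  a <- pmin(pmax(a, 1e-6), 1.05)
  a[t_grid == 0] <- pmin(a[t_grid == 0], 1.0)
  decay_end <- if (plateau > 0 && k > 0) -log(plateau) / k else Inf
  out <- inactivation_series(t_grid, a, inhibitor_conc)
  attr(out, "manifest") <- new_manifest(
    preset, list(k = k, plateau = plateau, inhibitor_conc = inhibitor_conc),
    noise, noise_sigma,
    list(t_grid = t_grid, decay_window = c(0, min(decay_end, max(t_grid)))),
    seed
  )
  out
}

#' Generate synthetic fluorescence titrations
#'
#' Two mean models are available, matching the two estimators applied to
#' quenching data (they coincide only at `n = 1`, so recovery tests pair each
#' mode with its own estimator):
#' * `"stern_volmer"`: `F = F0 / (1 + Ksv [Q])`
#' * `"double_log"`:   `F = F0 / (1 + Ka [Q]^n)`
#' with `[Q]` in mol/L. One series per requested temperature; parameters are
#' taken row-wise from `truth`. When `thermo` (`dh` kJ/mol, `ds` J/(mol K))
#' is given in double-log mode, `Ka(T)` is derived from the van't Hoff line
#' instead of the truth table. Optional absorbance channels proportional to
#' `[Q]` support inner-filter testing.
#'
#' @param mode `"stern_volmer"` or `"double_log"`.
#' @param truth Tibble with one row per temperature: `temperature` (K) and
#'   `ksv` (SV mode) or `ka` and `n` (double-log mode).
#' @param q_grid Quencher ladder, uM, starting at 0.
#' @param f0 Unquenched fluorescence, arbitrary units.
#' @param thermo Optional list with `dh` and `ds` overriding `ka` via the
#'   van't Hoff relation.
#' @param abs_coeff Length-2 absorbance-per-uM coefficients for the
#'   excitation/emission channels, or `NULL` for no absorbance columns. When
#'   given, the emitted fluorescence is inner-filter attenuated by
#'   `exp(-(A_ex + A_em)/2)`, so [inner_filter_correct()] (exponential
#'   dialect) restores the ideal signal.
#' @inheritParams gen_dose_response
#' @return A named list of [titration_series()] (names = temperature), each
#'   with a manifest; a single series is returned bare when `truth` has one
#'   row.
#' @export
gen_titration <- function(mode = c("stern_volmer", "double_log"), truth,
                          q_grid, f0 = 1000, thermo = NULL, abs_coeff = NULL,
                          noise_sigma = 0, seed,
                          noise = c("multiplicative", "additive"),
                          preset = "custom") {
  mode <- match.arg(mode)
  noise <- match.arg(noise)
  truth <- as_tibble(truth)
  q_grid <- sort(q_grid)
  stopifnot(q_grid[1] == 0)
  q_molar <- q_grid * 1e-6
  series <- purrr::map(seq_len(nrow(truth)), function(row) {
    tr <- truth[row, ]
    if (mode == "stern_volmer") {
      mean_f <- f0 / (1 + tr$ksv * q_molar)
    } else {
      ka <- if (!is.null(thermo)) {
        exp(-thermo$dh * 1000 / (R_GAS * tr$temperature) + thermo$ds / R_GAS)
      } else {
        tr$ka
      }
      mean_f <- f0 / (1 + ka * q_molar^tr$n)
    }
    if (any(mean_f[q_molar > 0] >= f0)) {
      abort("parameter/grid combination yields F >= F0 at nonzero quencher")
    }
    if (!is.null(abs_coeff)) {
      mean_f <- mean_f * exp(-(abs_coeff[1] + abs_coeff[2]) * q_grid / 2)
    }
    f <- with_seed(seed + row - 1L, apply_noise(mean_f, noise_sigma, noise))
    f <- pmax(f, 1e-9)
    f[q_grid == 0] <- f0  # the zero point defines F0
    out <- titration_series(
      q_grid, f, tr$temperature,
      abs_ex = if (!is.null(abs_coeff)) abs_coeff[1] * q_grid else NULL,
      abs_em = if (!is.null(abs_coeff)) abs_coeff[2] * q_grid else NULL
    )
    attr(out, "manifest") <- new_manifest(
      preset, c(as.list(tr), list(f0 = f0, mode = mode, thermo = thermo)),
      noise, noise_sigma,
      list(q_grid = q_grid, abs_coeff = abs_coeff), seed + row - 1L
    )
    out
  })
  names(series) <- as.character(truth$temperature)
  if (length(series) == 1) series[[1]] else series
}

#' Generate a two-inhibitor combination response surface
#'
#' A [loewe_surface()] built from two single-agent 4PL truth sets and an
#' interaction-factor map; factor 1 everywhere is the Loewe-additive
#' reference (CI = 1 on every isobole), factors below 1 produce synergy of
#' known size. Deterministic (the surface is a model, not data); the seed is
#' recorded in the manifest for provenance only.
#'
#' @param dr_a,dr_b Single-agent 4PL truth lists (see [gen_dose_response()]).
#' @param interaction Interaction factor specification passed to
#'   [loewe_surface()].
#' @param seed Recorded in the manifest.
#' @param preset Preset name.
#' @return A `response_surface` with a manifest attribute.
#' @export
gen_combination_surface <- function(dr_a, dr_b, interaction = NULL, seed = 0L,
                                    preset = "custom") {
  surf <- loewe_surface(dr_a, dr_b, interaction)
  attr(surf, "manifest") <- new_manifest(
    preset, list(dr_a = dr_a, dr_b = dr_b, interaction = interaction),
    "none", 0, list(), seed
  )
  surf
}
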