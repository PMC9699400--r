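test_that("titration reader defines F0 from the zero-quencher first row", {
  path <- withr_local_tempfile()
  writeLines(c(
    "# synthetic titration, 298.15 K",
    "temperature,quencher_conc,fluorescence",
    paste(298.15, seq(0, 8, by = 0.8), round(1000 / (1 + 6.21e4 * seq(0, 8, by = 0.8) * 1e-6), 3), sep = ",")
  ), path)
  x <- read_assay_table(path, "titration")
  expect_s3_class(x, "titration_series")
  expect_identical(nrow(x), 11L)
  expect_equal(x$fluorescence[x$quencher_conc == 0], 1000)
})

test_that("dose-response rows are sorted ascending before validation", {
  path <- withr_local_tempfile()
  writeLines(c(
    "conc,rel_activity",
    "8,35", "0.5,95", "2,70", "16,30", "4,50", "1,85"
  ), path)
  x <- read_assay_table(path, "dose_response")
  expect_false(is.unsorted(x$conc, strictly = TRUE))
  expect_equal(x$rel_activity[x$conc == 0.5], 95)
})

test_that("generated kinetic tables round-trip through the reader with full row count", {
  k <- gen_kinetics(preset$kinetics, s_grid = c(0.05, 0.1, 0.5, 1),
                    i_grid = kin_i_grid, noise_sigma = 0, seed = 3)
  expect_identical(nrow(k), 16L)  # 4 substrate x 4 inhibitor levels
  path <- withr_local_tempfile()
  readr::write_csv(k, path)
  back <- read_assay_table(path, "kinetics")
  expect_equal(back$rate, k$rate, tolerance = 1e-6)
  expect_equal(back$substrate_conc, k$substrate_conc)
})

test_that("unit suffixes on headers are converted to canonical units", {
  path <- withr_local_tempfile()
  writeLines(c(
    "temperature_C,quencher_conc_nM,fluorescence",
    "25,0,1000", "25,800,952", "25,1600,910", "25,2400,870",
    "25,3200,833", "25,4000,800"
  ), path)
  x <- read_assay_table(path, "titration")
  expect_equal(x$temperature[1], 298.15)
  expect_equal(x$quencher_conc, seq(0, 4, by = 0.8))  # nM -> uM
})

test_that("schema and validation errors name the offence", {
  path <- withr_local_tempfile()
  writeLines(c("conc,activity", "1,90", "2,80", "4,60", "8,40", "16,30"), path)
  expect_error(read_assay_table(path, "dose_response"),
               "rel_activity", class = "inhibikit_schema_error")

  expect_error(dose_response_series(c(1, 2, 4, -8, 16), c(90, 70, 50, 30, 20)),
               "positive", class = "inhibikit_validation_error")
  expect_error(titration_series(c(0.8, 1.6, 2.4, 3.2, 4), rep(100, 5), 298.15),
               "quencher_conc = 0", class = "inhibikit_validation_error")
  expect_error(titration_series(c(0, 1.6, 0.8, 2.4, 3.2), rep(100, 5), 298.15),
               "increasing", class = "inhibikit_validation_error")
  expect_error(kinetic_dataset(0.25, -1, 0.57, 0.5),
               "concentration", class = "inhibikit_validation_error")
})

test_that("all generator outputs pass their validators", {
  d <- gen_preset_dose_response(noise_sigma = 0.03, seed = 7)
  expect_s3_class(d, "dose_response_series")
  k <- gen_preset_kinetics(noise_sigma = 0.02, seed = 7)
  expect_s3_class(k, "kinetic_dataset")
  a <- gen_inactivation(5e-4, seq(0, 4200, by = 300), plateau = 0.25,
                        noise_sigma = 0.02, seed = 7)
  expect_s3_class(a, "inactivation_series")
  tt <- gen_preset_titration("stern_volmer", noise_sigma = 0.01, seed = 7)
  expect_s3_class(tt, "titration_series")
})

test_that("write_report echoes parameters and round-trips at 6 significant digits", {
  k <- gen_preset_kinetics()
  rp <- suppressWarnings(secondary_replots(fit_lineweaver_burk(k)))
  dir <- withr::local_tempdir()
  paths <- write_report(list(mechanism = rp), dir)
  tab <- readr::read_csv(paths[["table"]], show_col_types = FALSE)
  ki_row <- tab[tab$parameter == "ki", ]
  expect_equal(ki_row$estimate, param_of(rp, "ki"), tolerance = 1e-6)
  expect_identical(ki_row$units, "uM")
  expect_true(file.exists(paths[["narrative"]]))
  expect_true(any(grepl("ki = 6.17", readLines(paths[["narrative"]]), fixed = TRUE)))
  expect_error(write_report(list(), dir), "non-empty")
})
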