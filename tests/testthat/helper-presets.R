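# Shared generator shortcuts used across test files.

withr_local_tempfile <- function(env = parent.frame()) {
  withr::local_tempfile(fileext = ".csv", .local_envir = env)
}

preset <- quercetin_ache_preset()

# standard dose-response grid spanning the 50% crossing (uM)
dr_grid <- c(0.5, 1, 2, 4, 8, 16, 40, 80)

# standard kinetic design: 5 substrate levels x 4 inhibitor levels
kin_s_grid <- c(0.05, 0.1, 0.25, 0.5, 1)
kin_i_grid <- c(0, 4, 8, 12)

gen_preset_kinetics <- function(noise_sigma = 0, seed = 1) {
  gen_kinetics(preset$kinetics, s_grid = kin_s_grid, i_grid = kin_i_grid,
               noise_sigma = noise_sigma, seed = seed, preset = "quercetin-ache")
}

gen_preset_dose_response <- function(noise_sigma = 0, seed = 1) {
  gen_dose_response(preset$dose_response, dr_grid, noise_sigma, seed,
                    preset = "quercetin-ache")
}

# a titration at one temperature in either mean model
gen_preset_titration <- function(mode, row = 1, noise_sigma = 0, seed = 1, ...) {
  gen_titration(mode, preset$titration[row, ], q_grid = seq(0, 8, by = 0.8),
                f0 = preset$f0, noise_sigma = noise_sigma, seed = seed, ...)
}
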