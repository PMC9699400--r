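#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Read a flat key-value run configuration
#'
#' Parses a small YAML / `key: value` text file into a run configuration for
#' [run_pipeline()]. Recognised keys: the per-assay input paths
#' (`dose_response`, `kinetics`, `inactivation`, `titration`, `combination`
#' — `titration` may list several files), `temperature_c` or `temperature_k`,
#' `tau0`, `ifc_dialect`, `window_start`/`window_end` (s), `dx_a`, `dx_b`,
#' `level`, `out`, `seed`.
#'
#' @param path Path to the configuration file.
#' @return A named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$temperature_c)) {
    cfg$temperature <- celsius_to_kelvin(cfg$temperature_c)
  } else if (!is.null(cfg$temperature_k)) {
    cfg$temperature <- cfg$temperature_k
  }
  structure(cfg, class = "run_config")
}

#' Run every applicable analysis stage over a set of assay tables
#'
#' Executes, in dependency order, each stage for which an input is present:
#' dose-response (IC50), kinetics (reversibility when enzyme concentration
#' varies, Lineweaver-Burk + secondary replots + direct mixed fit otherwise),
#' inactivation (per inhibitor concentration), fluorescence titrations
#' (inner-filter correction, Stern-Volmer, quenching classification, binding
#' fits, van't Hoff across temperatures), and the combination index
#' (using `dx` values from the config or from the fitted dose-response
#' curves). Defaults used (tau0 = 1e-8 s, inner-filter dialect, fit window,
#' temperature) are recorded in the combined report. Deterministic: two runs
#' on identical inputs produce identical tables.
#'
#' @param config A `run_config` from [read_run_config()], or a named list
#'   with the same keys.
#' @return A named list of stage results (invisibly when `out` is set, in
#'   which case [write_report()] writes the combined report there).
#' @export
run_pipeline <- function(config) {
  cfg <- as.list(config)
  assay_keys <- c("dose_response", "kinetics", "inactivation", "titration",
                  "combination")
  if (!any(vapply(assay_keys, function(k) !is.null(cfg[[k]]), logical(1)))) {
    abort("no assay inputs present in the configuration")
  }
  temperature <- cfg$temperature %||% 298.15
  tau0 <- cfg$tau0 %||% 1e-8
  dialect <- cfg$ifc_dialect %||% "exp"
  window <- c(cfg$window_start %||% 0, cfg$window_end %||% 1800)

  results <- list(
    settings = paste0("defaults: T = ", temperature, " K; tau0 = ", tau0,
                      " s; inner-filter dialect = ", dialect,
                      "; inactivation window = ", window[1], "-", window[2], " s")
  )

  if (!is.null(cfg$dose_response)) {
    dr <- read_assay_table(cfg$dose_response, "dose_response")
    results$ic50 <- fit_ic50(dr)
  }

  if (!is.null(cfg$kinetics)) {
    kin <- read_assay_table(cfg$kinetics, "kinetics")
    if (dplyr::n_distinct(kin$enzyme_conc) > 1) {
      rev <- assess_reversibility(kin)
      results$reversibility <- paste0("verdict: ", rev$verdict)
      results$reversibility_result <- rev
    } else {
      lb <- fit_lineweaver_burk(kin)
      results$lineweaver_burk <- lb
      results$replots <- secondary_replots(lb)
      results$mixed_direct <- fit_mixed_direct(kin)
      results$mechanism <- paste0("mechanism: ", results$replots$mechanism)
    }
  }

  if (!is.null(cfg$inactivation)) {
    ina <- read_assay_table(cfg$inactivation, "inactivation")
    for (ic in sort(unique(ina$inhibitor_conc))) {
      sub <- dplyr::filter(ina, .data$inhibitor_conc == ic)
      results[[paste0("inactivation_", ic, "uM")]] <-
        fit_inactivation(sub, window = window, temperature = temperature)
    }
  }

  if (!is.null(cfg$titration)) {
    paths <- unlist(cfg$titration)
    sv_fits <- list(); bind_fits <- list()
    for (p in paths) {
      series <- read_assay_table(p, "titration")
      if (all(c("abs_ex", "abs_em") %in% names(series))) {
        series <- inner_filter_correct(series, dialect = dialect)
      }
      key <- as.character(series$temperature[1])
      sv_fits[[key]] <- fit_stern_volmer(series, tau0 = tau0)
      bind_fits[[key]] <- fit_binding(series)
      results[[paste0("stern_volmer_", key, "K")]] <- sv_fits[[key]]
      results[[paste0("binding_", key, "K")]] <- bind_fits[[key]]
    }
    results$quenching <- paste0("mechanism: ", classify_quenching(sv_fits))
    if (length(bind_fits) >= 2) {
      ka_tab <- purrr::map_dfr(bind_fits, function(f) {
        tibble(temperature = f$temperature, ka = param_of(f, "ka"))
      })
      th <- vant_hoff(ka_tab)
      results$thermodynamics <- th
      results$binding_forces <- paste0(
        "forces: ", th$force_type, "; ",
        if (th$spontaneous) "spontaneous (dG < 0)" else "non-spontaneous"
      )
    }
  }

  if (!is.null(cfg$combination)) {
    combo <- read_assay_table(cfg$combination, "combination")
    dx_a <- cfg$dx_a
    dx_b <- cfg$dx_b
    level <- cfg$level %||% sort(unique(combo$inhibition_level))
    if (is.null(dx_a) && !is.null(results$ic50)) {
      dx_a <- param_of(results$ic50, "ic50")  # 50%-level single-agent dose
    }
    if (is.null(dx_a) || is.null(dx_b)) {
      abort("combination stage needs dx_a and dx_b (from config or a fitted dose-response)")
    }
    for (lv in level) {
      iso <- build_isobologram(combo, level = lv, dx_a = dx_a, dx_b = dx_b)
      results[[paste0("combination_", lv, "pct")]] <- paste0(
        "overall: ", iso$overall, " (mean CI ", signif(mean(iso$pairs$ci), 4), ")"
      )
      results[[paste0("combination_result_", lv)]] <- iso
    }
  }

  if (!is.null(cfg$out)) {
    reportable <- purrr::keep(results, ~ inherits(.x, "inhib_fit") || is.character(.x))
    write_report(reportable, cfg$out)
    return(invisible(results))
  }
  results
}
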