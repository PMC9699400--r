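#' Assay series constructors
#'
#' Each constructor builds a validated tibble carrying one assay class in the
#' package's canonical units: concentrations in uM (substrate in mM, enzyme in
#' nM), time in seconds, temperature in kelvin. Rows are one observation each,
#' so every series pipes straight into dplyr verbs and into the fitters.
#'
#' @param conc Inhibitor concentration ladder, uM, strictly positive.
#' @param rel_activity Relative enzyme activity, percent of the uninhibited
#'   control.
#' @param inhibitor_id Label for the inhibitor.
#' @param replicate_sd Optional per-point replicate standard deviation
#'   (percent).
#' @return A tibble subclassed by assay kind (`dose_response_series`,
#'   `kinetic_dataset`, `inactivation_series`, `titration_series`,
#'   `combination_design`).
#' @examples
#' dose_response_series(conc = c(1, 2, 4, 8, 16),
#'                      rel_activity = c(90, 75, 52, 35, 28))
#' @export
dose_response_series <- function(conc, rel_activity, inhibitor_id = "inhibitor",
                                 replicate_sd = NULL) {
  x <- tibble(
    inhibitor_id = inhibitor_id,
    conc = as.numeric(conc),
    rel_activity = as.numeric(rel_activity)
  )
  if (!is.null(replicate_sd)) x$replicate_sd <- as.numeric(replicate_sd)
  x <- dplyr::arrange(x, .data$conc)
  validate_dose_response(x)
}

#' @rdname dose_response_series
#' @param substrate_conc Substrate concentration, mM.
#' @param inhibitor_conc Inhibitor concentration, uM.
#' @param enzyme_conc Enzyme concentration, nM.
#' @param rate Initial reaction rate (consistent units within a dataset,
#'   e.g. delta-OD per second).
#' @export
kinetic_dataset <- function(substrate_conc, inhibitor_conc, enzyme_conc, rate) {
  x <- tibble(
    substrate_conc = as.numeric(substrate_conc),
    inhibitor_conc = as.numeric(inhibitor_conc),
    enzyme_conc = as.numeric(enzyme_conc),
    rate = as.numeric(rate)
  )
  validate_kinetic(x)
}

#' @rdname dose_response_series
#' @param time Time, seconds, ascending from 0.
#' @export
inactivation_series <- function(time, rel_activity, inhibitor_conc) {
  x <- tibble(
    inhibitor_conc = as.numeric(inhibitor_conc),
    time = as.numeric(time),
    rel_activity = as.numeric(rel_activity)
  )
  x <- dplyr::arrange(x, .data$time)
  validate_inactivation(x)
}

#' @rdname dose_response_series
#' @param temperature Temperature, kelvin.
#' @param quencher_conc Quencher ladder, uM, starting at 0.
#' @param fluorescence Measured fluorescence, arbitrary units.
#' @param abs_ex,abs_em Optional absorbances at the excitation/emission
#'   wavelengths, used for inner-filter correction.
#' @export
titration_series <- function(quencher_conc, fluorescence, temperature,
                             abs_ex = NULL, abs_em = NULL) {
  x <- tibble(
    temperature = as.numeric(temperature),
    quencher_conc = as.numeric(quencher_conc),
    fluorescence = as.numeric(fluorescence)
  )
  if (!is.null(abs_ex)) x$abs_ex <- as.numeric(abs_ex)
  if (!is.null(abs_em)) x$abs_em <- as.numeric(abs_em)
  validate_titration(x)
}

#' @rdname dose_response_series
#' @param inhibition_level Percent inhibition achieved jointly by each dose
#'   pair.
#' @param dose_a,dose_b Doses of the two inhibitors, uM.
#' @export
combination_design <- function(inhibition_level, dose_a, dose_b) {
  x <- tibble(
    inhibition_level = as.numeric(inhibition_level),
    dose_a = as.numeric(dose_a),
    dose_b = as.numeric(dose_b)
  )
  validate_combination(x)
}

new_assay_tbl <- function(x, subclass) {
  class(x) <- unique(c(subclass, class(tibble())))
  x
}

stop_validation <- function(msg) abort(msg, class = "inhibikit_validation_error")

validate_dose_response <- function(x) {
  require_columns(x, c("conc", "rel_activity"), "dose_response")
  if (nrow(x) < 5) stop_validation("dose-response series needs at least 5 points")
  if (any(!is.finite(x$conc)) || any(x$conc <= 0)) {
    stop_validation("dose-response concentrations must be finite and strictly positive")
  }
  if (is.unsorted(x$conc, strictly = TRUE)) {
    stop_validation("dose-response concentrations must be strictly increasing")
  }
  if (any(!is.finite(x$rel_activity)) || any(x$rel_activity < 0)) {
    stop_validation("relative activity must be finite and non-negative")
  }
  new_assay_tbl(x, "dose_response_series")
}

validate_kinetic <- function(x) {
  require_columns(x, c("substrate_conc", "inhibitor_conc", "enzyme_conc", "rate"),
                  "kinetics")
  conc_cols <- c("substrate_conc", "inhibitor_conc", "enzyme_conc")
  for (cl in conc_cols) {
    if (any(!is.finite(x[[cl]])) || any(x[[cl]] < 0)) {
      stop_validation(paste0("negative or non-finite concentration in column '", cl, "'"))
    }
  }
  if (any(!is.finite(x$rate)) || any(x$rate < 0)) {
    stop_validation("rates must be finite and non-negative")
  }
  new_assay_tbl(x, "kinetic_dataset")
}

validate_inactivation <- function(x, a0_tol = 0.1) {
  require_columns(x, c("inhibitor_conc", "time", "rel_activity"), "inactivation")
  # one time course per inhibitor concentration
  for (ic in unique(x$inhibitor_conc)) {
    g <- x[x$inhibitor_conc == ic, ]
    if (is.unsorted(g$time, strictly = TRUE)) {
      stop_validation("inactivation time points must be strictly increasing within each inhibitor level")
    }
    if (g$time[1] < 0) stop_validation("time must start at or after 0")
    if (abs(g$rel_activity[1] - 1) > a0_tol) {
      stop_validation("relative activity at the first time point must be ~1 (fraction of initial)")
    }
  }
  if (any(x$rel_activity <= 0) || any(x$rel_activity > 1.05)) {
    stop_validation("relative activity must lie in (0, 1.05]")
  }
  new_assay_tbl(x, "inactivation_series")
}

validate_titration <- function(x) {
  require_columns(x, c("temperature", "quencher_conc", "fluorescence"), "titration")
  if (x$quencher_conc[1] != 0) {
    stop_validation("titration must start at quencher_conc = 0 (defines F0)")
  }
  if (is.unsorted(x$quencher_conc, strictly = TRUE)) {
    stop_validation("quencher ladder must be strictly increasing")
  }
  if (any(!is.finite(x$fluorescence)) || any(x$fluorescence <= 0)) {
    stop_validation("fluorescence must be finite and strictly positive")
  }
  new_assay_tbl(x, "titration_series")
}

validate_combination <- function(x) {
  require_columns(x, c("inhibition_level", "dose_a", "dose_b"), "combination")
  if (any(x$dose_a < 0) || any(x$dose_b < 0)) {
    stop_validation("doses must be non-negative")
  }
  if (any(x$dose_a == 0 & x$dose_b == 0)) {
    stop_validation("each pair must have at least one positive dose")
  }
  new_assay_tbl(x, "combination_design")
}

require_columns <- function(x, cols, kind) {
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    abort(
      paste0("missing required column(s) for '", kind, "' table: ",
             paste(missing, collapse = ", ")),
      class = "inhibikit_schema_error"
    )
  }
  invisible(x)
}

# Recognised unit suffixes on incoming column names; values are multipliers
# into the canonical unit of that column family.
.unit_conversions <- list(
  conc = c(uM = 1, nM = 1e-3, mM = 1e3, M = 1e6),
  substrate = c(mM = 1, uM = 1e-3, M = 1e3),
  enzyme = c(nM = 1, uM = 1e3, pM = 1e-3),
  time = c(s = 1, min = 60, h = 3600)
)

#' Read a delimited assay table
#'
#' Reads a comma- or tab-separated file (header mandatory, `#` comment lines
#' ignored) into the validated series type for the declared assay class.
#' Column names may carry a unit suffix (e.g. `conc_mM`, `time_min`,
#' `temperature_C`); values are converted to the canonical units (uM / mM for
#' substrate / nM for enzyme, seconds, kelvin) before validation.
#' Dose-response rows are sorted by concentration before validation.
#'
#' @param path Path to a CSV/TSV file.
#' @param kind One of `"dose_response"`, `"kinetics"`, `"inactivation"`,
#'   `"titration"`, `"combination"`.
#' @return A validated assay tibble of the matching subclass.
#' @export
read_assay_table <- function(path, kind = c("dose_response", "kinetics",
                                            "inactivation", "titration",
                                            "combination")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  first <- readLines(path, n = 25L, warn = FALSE)
  first <- first[!startsWith(trimws(first), "#") & nzchar(trimws(first))]
  delim <- if (length(first) && grepl("\t", first[[1]])) "\t" else ","
  x <- readr::read_delim(path, delim = delim, comment = "#",
                         show_col_types = FALSE, trim_ws = TRUE)
  x <- convert_units(as_tibble(x))
  switch(kind,
    dose_response = {
      require_columns(x, c("conc", "rel_activity"), kind)
      dose_response_series(x$conc, x$rel_activity,
                           inhibitor_id = x$inhibitor_id %||% "inhibitor",
                           replicate_sd = x$replicate_sd)
    },
    kinetics = validate_kinetic(x),
    inactivation = {
      require_columns(x, c("inhibitor_conc", "time", "rel_activity"), kind)
      validate_inactivation(dplyr::arrange(x, .data$inhibitor_conc, .data$time))
    },
    titration = validate_titration(x),
    combination = validate_combination(x)
  )
}

convert_units <- function(x) {
  nm <- names(x)
  out <- x
  for (j in seq_along(nm)) {
    m <- regmatches(nm[j], regexec("^(.*)_([A-Za-z]+)$", nm[j]))[[1]]
    if (length(m) != 3) next
    base <- m[2]; unit <- m[3]
    fam <- if (base %in% c("conc", "inhibitor_conc", "quencher_conc", "dose_a", "dose_b")) {
      "conc"
    } else if (base == "substrate_conc") {
      "substrate"
    } else if (base == "enzyme_conc") {
      "enzyme"
    } else if (base == "time") {
      "time"
    } else if (base == "temperature") {
      "temperature"
    } else {
      next
    }
    if (fam == "temperature") {
      if (unit == "C") {
        out[[j]] <- celsius_to_kelvin(x[[j]])
      } else if (unit != "K") {
        abort(paste0("unknown temperature unit '", unit, "'"))
      }
    } else {
      conv <- .unit_conversions[[fam]]
      if (!unit %in% names(conv)) {
        abort(paste0("unknown unit '", unit, "' for column '", nm[j], "'"))
      }
      out[[j]] <- x[[j]] * conv[[unit]]
    }
    names(out)[j] <- base
  }
  out
}

#' Shared fit-result container
#'
#' All fitters in the package return an `inhib_fit`: a parameter table
#' (estimate, standard error, units), the Pearson r of the underlying linear
#' fit where applicable, residuals, and a method label. [generics::tidy()]
#' returns the parameter table, [generics::glance()] a one-row fit summary.
#'
#' @param params Tibble with columns `term`, `estimate`, `std.error`, `units`.
#' @param subclass Subclass tag naming the fitter.
#' @param r Pearson correlation of the underlying linear fit, or `NA`.
#' @param residuals Numeric vector of per-point residuals.
#' @param n_obs Number of observations used.
#' @param method Human-readable method label.
#' @param ... Extra fields stored on the object.
#' @return An object of class `c(subclass, "inhib_fit")`.
#' @keywords internal
new_inhib_fit <- function(params, subclass, r = NA_real_, residuals = numeric(),
                          n_obs = length(residuals), method = subclass, ...) {
  stopifnot(all(c("term", "estimate") %in% names(params)))
  if (!"std.error" %in% names(params)) params$std.error <- NA_real_
  if (!"units" %in% names(params)) params$units <- NA_character_
  bad_se <- !is.na(params$std.error) & params$std.error < 0
  if (any(bad_se)) abort("standard errors must be non-negative")
  if (n_obs < nrow(params)) abort("fewer observations than parameters")
  structure(
    list(params = params, r = r, residuals = residuals, n_obs = n_obs,
         method = method, ...),
    class = c(subclass, "inhib_fit")
  )
}

#' @exportS3Method generics::tidy
tidy.inhib_fit <- function(x, ...) x$params

#' @exportS3Method generics::glance
glance.inhib_fit <- function(x, ...) {
  tibble(r = x$r, n_obs = x$n_obs, method = x$method)
}

#' @export
print.inhib_fit <- function(x, ...) {
  cat("<", x$method, ">\n", sep = "")
  print(x$params)
  if (!is.na(x$r)) cat("Pearson r:", format(x$r, digits = 6), "\n")
  cat("n =", x$n_obs, "\n")
  invisible(x)
}

#' Extract a named parameter estimate from a fit
#'
#' @param fit An `inhib_fit`.
#' @param term Parameter name.
#' @return The numeric estimate.
#' @export
param_of <- function(fit, term) {
  i <- match(term, fit$params$term)
  if (is.na(i)) abort(paste0("no parameter '", term, "' in this fit"))
  fit$params$estimate[i]
}

#' Write a combined results report
#'
#' Writes a delimited parameter table (`parameter, estimate, std_error, units,
#' r, method, section`) and a plain-text narrative block. Numeric fields
#' round-trip through read-back to at least 6 significant digits.
#'
#' @param results Non-empty named list; each element an `inhib_fit` or a
#'   character label (narrative-only entry).
#' @param path Output path: a `.csv` file (narrative written alongside with a
#'   `.txt` extension) or a directory (writes `results.csv` and `report.txt`).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, path) {
  if (length(results) == 0) abort("`results` must be non-empty")
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    abort("`results` must be a fully named list")
  }
  if (grepl("\\.csv$", path)) {
    csv_path <- path
    txt_path <- sub("\\.csv$", ".txt", path)
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    csv_path <- file.path(path, "results.csv")
    txt_path <- file.path(path, "report.txt")
  }
  fits <- purrr::keep(results, ~ inherits(.x, "inhib_fit"))
  notes <- purrr::keep(results, is.character)
  tab <- purrr::imap_dfr(fits, function(f, nm) {
    tibble(section = nm,
           parameter = f$params$term,
           estimate = f$params$estimate,
           std_error = f$params$std.error,
           units = f$params$units,
           r = f$r, method = f$method)
  })
  readr::write_csv(tab, csv_path)
  lines <- c("Inhibitor characterization report",
             paste0("generated: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             "")
  for (nm in names(fits)) {
    f <- fits[[nm]]
    lines <- c(lines, paste0("[", nm, "] ", f$method))
    lines <- c(lines, paste0("  ", f$params$term, " = ",
                             signif(f$params$estimate, 6),
                             ifelse(is.na(f$params$units), "",
                                    paste0(" ", f$params$units))))
    if (!is.na(f$r)) lines <- c(lines, paste0("  r = ", signif(f$r, 6)))
    lines <- c(lines, "")
  }
  for (nm in names(notes)) {
    lines <- c(lines, paste0("[", nm, "] ", notes[[nm]]), "")
  }
  writeLines(lines, txt_path)
  invisible(c(table = csv_path, narrative = txt_path))
}
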