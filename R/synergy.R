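#' Combination index for a dose pair
#'
#' `CI = d1/dx1 + d2/dx2`, where `dx1`, `dx2` are the single-agent doses of
#' each drug producing the same X% inhibition the pair produces jointly.
#' CI below 0.9 indicates synergism, 0.9-1.1 an additive interaction
#' (boundaries inclusive), above 1.1 antagonism.
#'
#' @param d1,d2 Doses of the two drugs in the combination, uM (vectorized);
#'   non-negative, not both zero.
#' @param dx1,dx2 Single-agent doses achieving the same inhibition level, uM;
#'   strictly positive.
#' @return Dimensionless combination index.
#' @examples
#' compute_ci(2.3, 0.145, 4.6, 0.29)  # ~1: additive
#' @export
compute_ci <- function(d1, d2, dx1, dx2) {
  if (any(dx1 <= 0) || any(dx2 <= 0)) abort("single-agent doses dx must be positive")
  if (any(d1 < 0) || any(d2 < 0)) abort("doses must be non-negative")
  if (any(d1 == 0 & d2 == 0)) abort("at least one dose in each pair must be positive")
  d1 / dx1 + d2 / dx2
}

#' Classify a combination index
#'
#' @param ci Combination index, positive (vectorized).
#' @return `"synergism"` (< 0.9), `"additive"` (0.9-1.1, inclusive) or
#'   `"antagonism"` (> 1.1).
#' @export
classify_ci <- function(ci) {
  if (any(ci <= 0)) abort("CI must be positive")
  dplyr::case_when(
    ci < 0.9 ~ "synergism",
    ci <= 1.1 ~ "additive",
    TRUE ~ "antagonism"
  )
}

#' Two-inhibitor response surface with a Loewe-additive reference
#'
#' Builds an inhibition surface `X(d1, d2)` from two single-agent 4PL
#' dose-response parameter sets. A dose pair produces inhibition level X when
#' \deqn{d_1 / D_1(X) + d_2 / D_2(X) = \lambda(X)}
#' where `D_i(X)` is the single-agent dose of drug i achieving X%
#' inhibition (inverted from its 4PL) and `lambda` is a level-dependent
#' interaction factor: `lambda = 1` everywhere is exact Loewe additivity
#' (every isobole point has CI = 1); `lambda < 1` shrinks the doses required
#' jointly, i.e. synergy. The factor applies to the combination rule, so the
#' single-agent margins of a non-additive surface are distorted by design —
#' the surface exists to generate mixture isoboles with known CI.
#'
#' @param dr_a,dr_b Lists of 4PL parameters (`top`, `bottom`, `hill`,
#'   `ic50_app`) for drugs A and B; activity percent, doses uM.
#' @param interaction `NULL` (additive), a single factor, or a named numeric
#'   vector mapping inhibition level (percent, as names) to the factor;
#'   interpolated linearly in level with constant extrapolation.
#' @return A function of class `response_surface`: `surface(d1, d2)` returns
#'   the percent inhibition of the pair. Attributes `dose_for_level`
#'   (function `(drug, level)` giving D_i(X)) and `lambda_fun` are attached.
#' @export
loewe_surface <- function(dr_a, dr_b, interaction = NULL) {
  drugs <- list(a = dr_a, b = dr_b)
  reach <- vapply(drugs, function(p) 100 - p$bottom, numeric(1))
  # single-agent dose for X% inhibition, from inverting the 4PL
  dose_for_level <- function(drug, level) {
    p <- drugs[[drug]]
    # inhibition is 100 - A(d); spans (100 - top) .. (100 - bottom)
    num <- level - (100 - p$top)
    den <- (100 - p$bottom) - level
    if (num <= 0) return(0)
    if (den <= 0) return(Inf)
    p$ic50_app * (num / den)^(1 / p$hill)
  }
  lambda_fun <- if (is.null(interaction)) {
    function(level) rep(1, length(level))
  } else if (is.null(names(interaction))) {
    stopifnot(length(interaction) == 1, interaction > 0)
    function(level) rep(interaction, length(level))
  } else {
    lv <- as.numeric(names(interaction))
    fv <- as.numeric(interaction)
    o <- order(lv)
    function(level) stats::approx(lv[o], fv[o], xout = level, rule = 2)$y
  }
  surface <- function(d1, d2) {
    mapply(function(a, b) {
      if (a < 0 || b < 0) abort("doses must be non-negative")
      if (a == 0 && b == 0) return(0)
      xmax <- max(reach)
      g <- function(x) {
        da <- dose_for_level("a", x)
        db <- dose_for_level("b", x)
        (if (is.finite(da)) a / da else 0) +
          (if (is.finite(db)) b / db else 0) - lambda_fun(x)
      }
      # below 100 - top a drug's required dose is 0 (divide-by-zero); start above
      lo <- max(0, 100 - min(vapply(drugs, function(p) p$top, numeric(1)))) + 1e-9
      hi <- xmax - 1e-9
      if (g(hi) > 0) return(xmax)  # level saturates at the joint reach
      uniroot(g, c(lo, hi), tol = 1e-10)$root
    }, d1, d2)
  }
  structure(surface, class = c("response_surface", "function"),
            dose_for_level = dose_for_level, lambda_fun = lambda_fun,
            drugs = drugs)
}

#' Build a dose-normalized isobologram with combination indices
#'
#' In model mode (a [loewe_surface()]), drug B is fixed at fractions of its
#' single-agent dose `dx_b` for the requested inhibition level and the dose
#' of drug A completing the level is solved by bisection on the surface
#' (bracket `[0, 3 dx_a]`, relative tolerance 1e-6). In measured mode (a
#' [combination_design()] of experimentally equi-effective pairs), CI is
#' computed directly from the recorded pairs and the supplied `dx` values.
#'
#' @param x A `response_surface` or a [combination_design()].
#' @param level Target inhibition level, percent.
#' @param fractions Fractions of `dx_b` at which drug B is fixed (model
#'   mode). A fraction that alone meets or exceeds the level yields the
#'   degenerate single-agent point (drug A dose 0).
#' @param dx_a,dx_b Single-agent doses at `level`; required in measured
#'   mode, computed from the surface's single-agent curves in model mode.
#' @return A list of class `combination_result`: `pairs` (tibble with doses,
#'   normalized doses, `ci`, `classification`), `level`, `dx_a`, `dx_b`,
#'   `overall` (modal label).
#' @export
build_isobologram <- function(x, level, fractions = c(0.2, 0.4, 0.6, 0.8),
                              dx_a = NULL, dx_b = NULL) {
  if (inherits(x, "response_surface")) {
    stopifnot(all(fractions > 0), all(fractions <= 1))
    dose_for_level <- attr(x, "dose_for_level")
    dx_a <- dx_a %||% dose_for_level("a", level)
    dx_b <- dx_b %||% dose_for_level("b", level)
    if (!is.finite(dx_a) || !is.finite(dx_b) || dx_a <= 0 || dx_b <= 0) {
      abort("inhibition level unreachable by a single agent on this surface")
    }
    pairs <- purrr::map_dfr(fractions, function(f) {
      d2 <- f * dx_b
      if (x(0, d2) >= level - 1e-9) {
        # drug B alone already reaches the level: degenerate single-agent point
        return(tibble(dose_a = 0, dose_b = d2, degenerate = TRUE))
      }
      g <- function(d1) x(d1, d2) - level
      hi <- 3 * dx_a
      if (g(hi) < 0) abort(paste0("level ", level, "% unreachable at fraction ", f))
      d1 <- uniroot(g, c(0, hi), tol = 1e-6 * dx_a)$root
      tibble(dose_a = d1, dose_b = d2, degenerate = FALSE)
    })
  } else {
    design <- validate_combination(as_tibble(x))
    if (is.null(dx_a) || is.null(dx_b)) {
      abort("measured mode needs the single-agent doses dx_a and dx_b")
    }
    pairs <- design |>
      dplyr::filter(.data$inhibition_level == level) |>
      dplyr::transmute(dose_a = .data$dose_a, dose_b = .data$dose_b,
                       degenerate = FALSE)
    if (nrow(pairs) == 0) abort(paste0("no measured pairs at level ", level, "%"))
  }
  pairs <- pairs |>
    dplyr::mutate(
      normalized_a = .data$dose_a / dx_a,
      normalized_b = .data$dose_b / dx_b,
      ci = compute_ci(.data$dose_a, .data$dose_b, dx_a, dx_b),
      classification = classify_ci(.data$ci)
    )
  overall <- names(sort(table(pairs$classification), decreasing = TRUE))[1]
  structure(
    list(pairs = pairs, level = level, dx_a = dx_a, dx_b = dx_b,
         overall = overall,
         concave = all(pairs$ci < 1)),
    class = "combination_result"
  )
}

#' @export
print.combination_result <- function(x, ...) {
  cat("Isobologram at ", x$level, "% inhibition (dx_a = ", signif(x$dx_a, 4),
      " uM, dx_b = ", signif(x$dx_b, 4), " uM)\n", sep = "")
  print(x$pairs)
  cat("overall:", x$overall, "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.combination_result <- function(x, ...) {
  dplyr::mutate(x$pairs, inhibition_level = x$level, .before = 1)
}

#' @exportS3Method generics::glance
glance.combination_result <- function(x, ...) {
  tibble(inhibition_level = x$level, n_pairs = nrow(x$pairs),
         mean_ci = mean(x$pairs$ci), overall = x$overall)
}

#' @exportS3Method ggplot2::autoplot
autoplot.combination_result <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$normalized_b, y = .data$normalized_a)) +
    ggplot2::geom_abline(slope = -1, intercept = 1, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$classification)) +
    ggplot2::coord_cartesian(xlim = c(0, 1.2), ylim = c(0, 1.2)) +
    ggplot2::labs(x = "dose B / DX_B", y = "dose A / DX_A",
                  title = paste0("Dose-normalized isobologram (",
                                 object$level, "% inhibition)"))
}
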