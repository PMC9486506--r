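#' Model dose-response curve and its Hill fit
#'
#' Evaluates the resource-allocation growth model along a concentration grid
#' with expression supplied by a regulation surface, normalizes by the
#' zero-dose growth rate, and fits a Hill function to obtain the
#' dose-sensitivity `n`, exactly as for measured dose-response curves.
#'
#' When `c_grid` is `NULL`, a default grid is chosen to span the descent of
#' the curve: the concentration at which normalized growth reaches
#' `floor_level` (default 0.05) is found by root solving, and the grid is the
#' zero dose plus `n_grid` log-spaced concentrations covering the 256-fold
#' range below it -- mimicking a serial-dilution experiment spanning the
#' informative part of the curve. If the supplied grid leaves normalized
#' growth above 0.2 at its top concentration, a widen-grid warning is
#' raised.
#'
#' @param params A [model_params()] object.
#' @param surface A `regulation_surface` (wild-type or rewired).
#' @param a Limitation ratio at which to compute the curve.
#' @param c_grid Optional concentration grid, ug/ml.
#' @param n_grid Number of positive concentrations for the automatic grid.
#' @param floor_level Normalized-growth level defining the top of the
#'   automatic grid.
#' @param hill_min_rate Optional absolute growth threshold passed to
#'   [fit_hill()].
#' @return A list with `curve` (a [dose_response_curve()]) and `fit`
#'   (a `hill_fit`).
#' @export
#' @examples
#' surface <- default_regulation_surface()
#' res <- model_dose_response(default_model_params(), surface, a = 0)
#' res$fit$n
model_dose_response <- function(params, surface, a, c_grid = NULL,
                                n_grid = 25, floor_level = 0.05,
                                hill_min_rate = NULL) {
  stopifnot(inherits(params, "model_params"),
            inherits(surface, "regulation_surface"))
  growth_at <- function(conc) {
    chi <- eval_regulation(surface, a, conc, allow_nearest = TRUE)
    growth_rate_model(a, conc, chi, params)
  }
  g0 <- growth_at(0)
  if (g0 <= 0) stop("zero drug-free growth at this limitation ratio")
  if (is.null(c_grid)) {
    f <- function(lc) growth_at(exp(lc)) / g0 - floor_level
    lo <- log(params$K_Mc) - 14
    hi <- log(params$K_Mc) + 14
    if (f(hi) > 0) stop("normalized growth never reaches the floor level on the search range")
    c_top <- exp(stats::uniroot(f, lower = lo, upper = hi, tol = 1e-12)$root)
    c_grid <- c(0, exp(seq(log(c_top / 256), log(c_top), length.out = n_grid)))
  }
  growth <- vapply(c_grid, growth_at, numeric(1))
  curve <- dose_response_curve(c_grid, growth, g0 = g0)
  if (min(curve$normalized) > 0.2) {
    warning("concentration grid does not span the descent of the curve; widen it")
  }
  fit <- fit_hill(curve, hill_min_rate = hill_min_rate)
  list(curve = curve, fit = fit)
}

#' Dose-sensitivity chain of the calibrated model
#'
#' Computes, under one parameterization, the set of model dose-sensitivities
#' that summarize how growth-mediated feedback shapes the dose-response
#' curve: the wild-type curve at zero limitation, the wild-type curve at the
#' limitation ratio that halves drug-free growth, and the curves with the
#' feedback rewired to constant and inverted target regulation.
#'
#' Wild-type curves are fitted on an automatic grid spanning their descent.
#' The rewired curves are fitted on the rewiring experiment's drug gradient
#' -- a two-fold dilution series from `rewired_c_max` (default 0.9 ug/ml,
#' the anchor concentration of the rewiring) down over 11 steps plus zero
#' dose; with inverted regulation the curve may not fully descend within
#' that gradient, which is precisely why inverted-regulation steepness
#' estimates carry large uncertainties.
#'
#' @param params A [model_params()] object; default the calibrated
#'   parameters.
#' @param surface A wild-type `regulation_surface`; default the surface
#'   built from the noiseless synthetic pipeline.
#' @param rewired_c_max Top concentration of the rewired-mode gradient,
#'   ug/ml.
#' @return A list with `n_wildtype`, `n_half_growth`, `n_constant`,
#'   `n_inverted`, `a_half` (the halving limitation ratio), and `fits`
#'   (the four `hill_fit` objects).
#' @export
#' @examples
#' \donttest{
#' unlist(model_steepness_chain()[1:4])
#' }
model_steepness_chain <- function(params = default_model_params(),
                                  surface = default_regulation_surface(),
                                  rewired_c_max = 0.9) {
  stopifnot(inherits(params, "model_params"),
            inherits(surface, "regulation_surface"))
  a_half <- half_growth_limitation(params)
  grid_rewired <- c(0, rewired_c_max * 2^-(11:0))
  wt <- model_dose_response(params, surface, a = 0)
  half <- model_dose_response(params, surface, a = a_half)
  const <- suppressWarnings(
    model_dose_response(params, rewire_regulation(surface, "constant"),
                        a = 0, c_grid = grid_rewired)
  )
  inv <- suppressWarnings(
    model_dose_response(params, rewire_regulation(surface, "inverted"),
                        a = 0, c_grid = grid_rewired)
  )
  list(n_wildtype = wt$fit$n, n_half_growth = half$fit$n,
       n_constant = const$fit$n, n_inverted = inv$fit$n,
       a_half = a_half,
       fits = list(wildtype = wt$fit, half_growth = half$fit,
                   constant = const$fit, inverted = inv$fit))
}

#' Calibrated default model parameters
#'
#' The package's single shipped parameterization of the resource-allocation
#' model. The constants were chosen by the documented calibration script
#' (`inst/scripts/calibrate-defaults.R`): a coarse grid over the
#' dimensionless allocation ratio `A`, the binding constant, the demand, and
#' the regulation law's slope and convergence level, anchored so that the
#' drug-free growth rate at zero limitation is 0.9/h and the wild-type
#' synthetic pipeline yields a dose-sensitivity near 1.1 at zero limitation
#' with the characteristic steepening under limitation and feedback
#' rewiring.
#'
#' @return A [model_params()] object.
#' @export
default_model_params <- function() {
  model_params(
    omega_R = .gf_defaults$omega_R,
    omega_C = .gf_defaults$omega_C,
    K_Mc = .gf_defaults$K_Mc,
    chi_demand = .gf_defaults$chi_demand
  )
}

#' Calibrated default regulation parameters
#'
#' The generator truth paired with [default_model_params()]; see that help
#' page and the calibration script for how the constants were chosen.
#'
#' @return A [regulation_params()] object.
#' @export
default_regulation_params <- function() {
  regulation_params(
    chi_max = .gf_defaults$chi_max,
    slope_lambda = .gf_defaults$slope_lambda,
    converge_level = .gf_defaults$converge_level,
    clamp_c = 0.4
  )
}

#' Default wild-type regulation surface
#'
#' Builds the wild-type regulation surface from a noiseless synthetic
#' regulation dataset generated under the calibrated default parameters --
#' the deterministic reference surface used for model dose-response curves
#' and rewiring.
#'
#' @return A `regulation_surface`.
#' @export
default_regulation_surface <- function() {
  cfg <- synth_config(seed = 1L, noise_cv = 0)
  build_regulation_surface(generate_regulation_dataset(cfg))
}
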