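#' Resource-allocation model parameters
#'
#' Container for the four dimensional parameters of the reduced two-sector
#' proteome-allocation model of drug action: the ribosomal-sector cost
#' coefficient `omega_R` (h), the nutrient-scavenging-sector cost coefficient
#' `omega_C` (h), the drug--target binding equilibrium constant `K_Mc`
#' (ug/ml), and the cellular demand for the target enzyme `chi_demand`
#' (expression a.u.). `K_Ma` is the rescaled substrate-uptake constant; in the
#' saturated-uptake limit assumed throughout it is 0 and is kept only so the
#' limit can be relaxed explicitly.
#'
#' @param omega_R R-sector cost coefficient, h. Must be > 0.
#' @param omega_C C-sector cost coefficient, h. Must be > 0.
#' @param K_Mc Drug--target equilibrium constant, ug/ml. Must be > 0.
#' @param chi_demand Target-enzyme demand, expression a.u. Must be > 0.
#' @param K_Ma Uptake saturation constant (dimensionless); 0 by default.
#' @return An object of class `model_params`.
#' @seealso [rescaled_params()], [growth_rate_model()], [default_model_params()]
#' @export
#' @examples
#' p <- model_params(omega_R = 1, omega_C = 1, K_Mc = 0.05, chi_demand = 0.4)
#' drug_free_growth(0, p)
model_params <- function(omega_R, omega_C, K_Mc, chi_demand, K_Ma = 0) {
  stopifnot(
    is.numeric(omega_R), length(omega_R) == 1L, omega_R > 0,
    is.numeric(omega_C), length(omega_C) == 1L, omega_C > 0,
    is.numeric(K_Mc), length(K_Mc) == 1L, K_Mc > 0,
    is.numeric(chi_demand), length(chi_demand) == 1L, chi_demand > 0,
    is.numeric(K_Ma), length(K_Ma) == 1L, K_Ma >= 0
  )
  structure(
    list(omega_R = omega_R, omega_C = omega_C, K_Mc = K_Mc,
         chi_demand = chi_demand, K_Ma = K_Ma),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Resource-allocation model parameters\n")
  cat(sprintf("  omega_R:    %.6g h\n", x$omega_R))
  cat(sprintf("  omega_C:    %.6g h\n", x$omega_C))
  cat(sprintf("  K_Mc:       %.6g ug/ml\n", x$K_Mc))
  cat(sprintf("  chi_demand: %.6g a.u.\n", x$chi_demand))
  if (x$K_Ma != 0) cat(sprintf("  K_Ma:       %.6g\n", x$K_Ma))
  cat(sprintf("  (A = omega_C/omega_R = %.6g)\n", x$omega_C / x$omega_R))
  invisible(x)
}

#' Nondimensionalized model parameters
#'
#' The dimensional model has a single meaningful dimensionless parameter
#' `A = omega_C / omega_R`; the remaining three parameters are pure scales
#' (growth in units of `1/omega_R`, concentration in units of `K_Mc`,
#' expression in units of `chi_demand`). `rescaled_params()` performs this
#' reduction and `dimensional_params()` inverts it exactly.
#'
#' @param params A [model_params()] object.
#' @return An object of class `rescaled_params` with fields `A`,
#'   `scale_lambda` (h), `scale_c` (ug/ml), `scale_chi` (a.u.).
#' @export
#' @examples
#' p <- model_params(1, 0.5, 0.05, 0.4)
#' r <- rescaled_params(p)
#' identical(dimensional_params(r)$omega_C, p$omega_C)
rescaled_params <- function(params) {
  stopifnot(inherits(params, "model_params"))
  structure(
    list(A = params$omega_C / params$omega_R,
         scale_lambda = params$omega_R,
         scale_c = params$K_Mc,
         scale_chi = params$chi_demand),
    class = "rescaled_params"
  )
}

#' @rdname rescaled_params
#' @param rescaled A `rescaled_params` object.
#' @export
dimensional_params <- function(rescaled) {
  stopifnot(inherits(rescaled, "rescaled_params"))
  model_params(
    omega_R = rescaled$scale_lambda,
    omega_C = rescaled$A * rescaled$scale_lambda,
    K_Mc = rescaled$scale_c,
    chi_demand = rescaled$scale_chi
  )
}

#' @export
print.rescaled_params <- function(x, ...) {
  cat("Rescaled model parameters\n")
  cat(sprintf("  A            = %.6g (dimensionless)\n", x$A))
  cat(sprintf("  growth scale = %.6g h\n", x$scale_lambda))
  cat(sprintf("  conc scale   = %.6g ug/ml\n", x$scale_c))
  cat(sprintf("  expr scale   = %.6g a.u.\n", x$scale_chi))
  invisible(x)
}

#' Proteome sector fractions at a given growth rate
#'
#' The ribosomal sector grows linearly with the growth rate,
#' `phi_R = omega_R * lambda`, and the scavenging sector takes the rest,
#' `phi_C = 1 - phi_R` (two-sector growth law).
#'
#' @param lambda Growth rate, 1/h (vectorized).
#' @param params A [model_params()] object.
#' @return A list with numeric vectors `phi_R` and `phi_C`.
#' @export
proteome_fractions <- function(lambda, params) {
  stopifnot(inherits(params, "model_params"), is.numeric(lambda), all(lambda >= 0))
  phi_R <- params$omega_R * lambda
  if (any(phi_R > 1 + 1e-12)) {
    stop("allocation infeasible: omega_R * lambda exceeds 1")
  }
  list(phi_R = phi_R, phi_C = 1 - phi_R)
}

#' Drug-free growth rate under nutrient limitation
#'
#' Growth without drug as a function of the limitation ratio `a` (e.g.
#' alpha-methyl-glucoside to glucose): `lambda0(a) = 1 / (omega_R +
#' omega_C * (K_Ma + a + 1))`, with `K_Ma = 0` in the saturated-uptake limit.
#'
#' @param a Limitation ratio, dimensionless, >= 0 (vectorized).
#' @param params A [model_params()] object.
#' @return Growth rate(s), 1/h.
#' @export
drug_free_growth <- function(a, params) {
  stopifnot(inherits(params, "model_params"), is.numeric(a))
  if (any(a < 0)) stop("limitation ratio `a` must be non-negative")
  1 / (params$omega_R + params$omega_C * (params$K_Ma + a + 1))
}

#' Free target-enzyme concentration under drug binding
#'
#' Binding equilibrium of drug to the target enzyme (e.g. trimethoprim to
#' FolA/DHFR) with the drug treated as free ligand:
#' `free = chi / (1 + conc / K_Mc)`.
#'
#' @param chi Total target-enzyme level, a.u., >= 0 (vectorized).
#' @param conc Drug concentration, ug/ml, >= 0 (vectorized).
#' @param K_Mc Equilibrium constant, ug/ml, > 0.
#' @return Free enzyme level(s), a.u.
#' @export
free_fola <- function(chi, conc, K_Mc) {
  stopifnot(is.numeric(chi), is.numeric(conc), is.numeric(K_Mc), K_Mc > 0)
  if (any(chi < 0)) stop("`chi` must be non-negative")
  if (any(conc < 0)) stop("`conc` must be non-negative")
  chi / (1 + conc / K_Mc)
}

#' Growth rate under drug with a given target-expression level
#'
#' The full model: growth is ribosome-limited (equal to the drug-free rate)
#' while free target enzyme meets the demand, and proportional to free enzyme
#' once binding depletes it below demand:
#' `lambda = lambda0(a) * min(1, (chi / chi_demand) / (1 + conc / K_Mc))`.
#'
#' @param a Limitation ratio, >= 0.
#' @param conc Drug concentration, ug/ml, >= 0.
#' @param chi Total target-expression level, a.u., >= 0.
#' @param params A [model_params()] object.
#' @return Growth rate(s), 1/h. Arguments are recycled to a common length.
#' @export
growth_rate_model <- function(a, conc, chi, params) {
  stopifnot(inherits(params, "model_params"))
  if (any(conc < 0)) stop("`conc` must be non-negative")
  if (any(chi < 0)) stop("`chi` must be non-negative")
  lam0 <- drug_free_growth(a, params)
  lam0 * pmin(1, (chi / params$chi_demand) / (1 + conc / params$K_Mc))
}

#' Rescaled (dimensionless) growth rate
#'
#' Single-parameter form of the model after nondimensionalization:
#' `lambda_bar = min(1, chi_bar / (1 + c_bar)) / (1 + A * (a + 1))` where
#' `c_bar = conc / K_Mc`, `chi_bar = chi / chi_demand`, and
#' `lambda_bar = omega_R * lambda`.
#'
#' @param a Limitation ratio, >= 0.
#' @param c_bar Rescaled drug concentration, >= 0.
#' @param chi_bar Rescaled expression level, >= 0.
#' @param A Dimensionless parameter `omega_C / omega_R`, > 0.
#' @return Dimensionless growth rate(s).
#' @export
rescaled_growth <- function(a, c_bar, chi_bar, A) {
  stopifnot(is.numeric(A), A > 0)
  if (any(a < 0) || any(c_bar < 0) || any(chi_bar < 0)) {
    stop("all arguments must be non-negative")
  }
  pmin(1, chi_bar / (1 + c_bar)) / (1 + A * (a + 1))
}

#' Limitation ratio at which drug-free growth is halved
#'
#' Solves `lambda0(a) = lambda0(0) / 2` in closed form:
#' `a* = omega_R / omega_C + 1 = 1/A + 1`.
#'
#' @param params A [model_params()] object.
#' @return The halving limitation ratio, dimensionless.
#' @export
half_growth_limitation <- function(params) {
  stopifnot(inherits(params, "model_params"))
  params$omega_R / params$omega_C + 1
}
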