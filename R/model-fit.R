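#' Fit the drug-free growth law
#'
#' First stage of the two-stage model fit: least-squares fit of
#' `lambda0(a) = 1 / (omega_R + omega_C * (a + 1))` to measurements at
#' negligible drug concentration (`conc < conc_max`, default 0.1 ug/ml),
#' after applying the standard measurement filter. Starting values come from
#' the exactly linear relation `1/growth = omega_R + omega_C * (a + 1)`.
#'
#' @param records Data frame with columns `a`, `conc`, `growth` (and
#'   `expression` for the filter; records without an `expression` column are
#'   filtered on `a` and `growth` only).
#' @param conc_max Concentration below which the drug is considered
#'   negligible, ug/ml.
#' @return A list with `omega_R`, `omega_C`, `sd_omega_R`, `sd_omega_C`,
#'   `rss`, `n_points`, and the underlying `fit`.
#' @export
fit_drug_free <- function(records, conc_max = 0.1) {
  stopifnot(is.data.frame(records),
            all(c("a", "conc", "growth") %in% names(records)))
  if (!"expression" %in% names(records)) records$expression <- 1
  if (!"passes_filter" %in% names(records)) {
    records <- filter_measurements(records)
  }
  df <- records[records$passes_filter & records$conc < conc_max, , drop = FALSE]
  if (length(unique(df$a)) < 2L) {
    stop("need at least 2 distinct limitation ratios at negligible drug")
  }
  # linearization for starting values: 1/growth = omega_R + omega_C * (a + 1)
  lin <- stats::lm.fit(cbind(1, df$a + 1), 1 / df$growth)
  start <- pmax(lin$coefficients, 1e-6)
  fit <- minpack.lm::nlsLM(
    growth ~ 1 / (exp(lwR) + exp(lwC) * (a + 1)),
    data = df,
    start = list(lwR = log(start[[1]]), lwC = log(start[[2]])),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  omega_R <- exp(cf[["lwR"]])
  omega_C <- exp(cf[["lwC"]])
  list(omega_R = omega_R, omega_C = omega_C,
       sd_omega_R = omega_R * sqrt(vc[1, 1]),
       sd_omega_C = omega_C * sqrt(vc[2, 2]),
       rss = sum(stats::residuals(fit)^2),
       n_points = nrow(df), fit = fit)
}

#' Fit the drug-response parameters
#'
#' Second stage of the two-stage fit: with `omega_R` and `omega_C` fixed from
#' [fit_drug_free()], fits the binding constant `K_Mc` and the target demand
#' `chi_demand` by least squares of the full growth model, substituting the
#' regulation surface for the expression level at each record's `(a, c)`.
#' Because the `min()` in the model makes the objective non-smooth at the
#' ribosome-to-target-limited kink, the optimizer is derivative-free
#' (Nelder-Mead) in log-parameter space, restarted from a deterministic
#' 3 x 3 grid of starting values spanning the observed concentration and
#' expression ranges.
#'
#' `chi_demand` is identifiable only relative to the surface's expression
#' units: rescaling the surface and `chi_demand` together leaves every
#' prediction unchanged. An error is raised when all records lie in the
#' unaffected (ribosome-limited) regime, where `chi_demand` drops out.
#'
#' @param records Data frame with columns `a`, `conc`, `growth` (and
#'   optionally `expression` for filtering).
#' @param omega_R,omega_C Fixed first-stage parameters, h.
#' @param surface A `regulation_surface` supplying expression at `(a, c)`.
#' @return A list with `K_Mc`, `chi_demand`, `rss`, `n_points`,
#'   `convergence`.
#' @export
fit_drug_response <- function(records, omega_R, omega_C, surface) {
  stopifnot(is.data.frame(records), inherits(surface, "regulation_surface"),
            omega_R > 0, omega_C > 0)
  if (!"expression" %in% names(records)) records$expression <- 1
  if (!"passes_filter" %in% names(records)) {
    records <- filter_measurements(records)
  }
  df <- records[records$passes_filter, , drop = FALSE]
  if (nrow(df) < 4L) stop("too few records for the drug-response fit")
  chi <- eval_regulation(surface, df$a, df$conc, allow_nearest = TRUE)
  lam0 <- 1 / (omega_R + omega_C * (df$a + 1))

  pred <- function(K_Mc, chi_demand) {
    lam0 * pmin(1, (chi / chi_demand) / (1 + df$conc / K_Mc))
  }
  obj <- function(par) {
    sum((df$growth - pred(exp(par[1]), exp(par[2])))^2)
  }

  conc_pos <- df$conc[df$conc > 0]
  if (length(conc_pos) == 0L) stop("no positive drug concentrations in the records")
  starts_K <- stats::median(conc_pos) * c(0.1, 1, 10)
  starts_chi <- stats::median(chi) * c(0.25, 1, 4)
  best <- NULL
  for (sk in starts_K) {
    for (sc in starts_chi) {
      o <- stats::optim(c(log(sk), log(sc)), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
      if (is.null(best) || o$value < best$value) best <- o
    }
  }
  # polish from the incumbent
  best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-15))
  K_Mc <- exp(best$par[1])
  chi_demand <- exp(best$par[2])
  if (all((chi / chi_demand) / (1 + df$conc / K_Mc) >= 1)) {
    stop("all records lie in the unaffected regime; chi_demand is unidentifiable")
  }
  list(K_Mc = K_Mc, chi_demand = chi_demand, rss = best$value,
       n_points = nrow(df), convergence = best$convergence)
}

#' Two-stage model fit
#'
#' Convenience wrapper running [fit_drug_free()] on the near-zero-dose
#' records and [fit_drug_response()] on the full table with a regulation
#' surface built from the same records.
#'
#' @param records Measurement table (`a`, `conc`, `growth`, `expression`).
#' @param a_nodes,clamp_c Passed to [build_regulation_surface()].
#' @param conc_max Passed to [fit_drug_free()].
#' @return A list with `params` (a [model_params()] object), `surface`,
#'   `stage1`, `stage2`.
#' @export
fit_model_two_stage <- function(records, a_nodes = c(0, 2.5, 5, 10),
                                clamp_c = 0.4, conc_max = 0.1) {
  records <- filter_measurements(records)
  surface <- build_regulation_surface(records, a_nodes = a_nodes,
                                      clamp_c = clamp_c)
  s1 <- fit_drug_free(records, conc_max = conc_max)
  s2 <- fit_drug_response(records, s1$omega_R, s1$omega_C, surface)
  list(
    params = model_params(s1$omega_R, s1$omega_C, s2$K_Mc, s2$chi_demand),
    surface = surface, stage1 = s1, stage2 = s2
  )
}
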