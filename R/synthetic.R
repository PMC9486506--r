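# Run code with a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Mean-one multiplicative lognormal noise factors.
lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Growth-rate-dependent regulation parameters for the generator
#'
#' Parameters of the synthetic truth for target-enzyme regulation: at low
#' drug, expression declines linearly with growth rate from a fixed maximum
#' `chi_max` at zero growth (`expression = chi_max - slope_lambda * lambda`),
#' emulating constitutive-promoter behavior; as drug concentration rises, the
#' expression of all conditions blends linearly in `c` toward a common
#' `converge_level` reached at `clamp_c`, emulating promoter saturation under
#' drug.
#'
#' @param chi_max Expression at zero growth, a.u.
#' @param slope_lambda Decline of expression per unit growth rate, a.u. per
#'   (1/h).
#' @param converge_level Common expression level at `c >= clamp_c`, a.u.
#' @param clamp_c Convergence concentration, ug/ml (default 0.4).
#' @return An object of class `regulation_params`.
#' @export
regulation_params <- function(chi_max, slope_lambda, converge_level,
                              clamp_c = 0.4) {
  stopifnot(chi_max > 0, slope_lambda >= 0, converge_level > 0, clamp_c > 0)
  structure(
    list(chi_max = chi_max, slope_lambda = slope_lambda,
         converge_level = converge_level, clamp_c = clamp_c),
    class = "regulation_params"
  )
}

#' Generator truth for target expression at given growth rate and dose
#'
#' The regulation law closed by the fixed-point solver: a linear-in-growth
#' baseline at zero dose, blended linearly in concentration toward the common
#' convergence level at `clamp_c`, constant beyond.
#'
#' @param lambda Growth rate(s), 1/h.
#' @param conc Drug concentration(s), ug/ml.
#' @param regulation A [regulation_params()] object.
#' @return Expression level(s), a.u.
#' @export
chi_regulation <- function(lambda, conc, regulation) {
  stopifnot(inherits(regulation, "regulation_params"))
  base <- regulation$chi_max - regulation$slope_lambda * lambda
  w <- pmin(conc, regulation$clamp_c) / regulation$clamp_c
  (1 - w) * base + w * regulation$converge_level
}

#' Configuration of the synthetic-data generator
#'
#' Bundles the generator's stochastic and structural settings. The defaults
#' are the study conditions emulated throughout: OD sampled every 10 min,
#' multiplicative measurement noise with a 4% coefficient of variation
#' (plate-reader day-to-day variability is 3--5%), limitation grid
#' `{0, 2.5, 5, 10}`, a concentration grid covering the regression range
#' `[0, 0.4]` ug/ml and the drug-responsive regime beyond it, and the
#' calibrated model truth.
#'
#' @param seed Integer seed fixing every stochastic output.
#' @param noise_cv Multiplicative measurement noise CV (default 0.04).
#' @param sampling_interval Plate-reader sampling interval, minutes.
#' @param a_grid Limitation ratios of the synthetic measurement grid.
#' @param c_grid Drug concentrations of the grid, ug/ml.
#' @param n_replicates Replicate measurements per grid point.
#' @param truth A [model_params()] object (generator truth).
#' @param regulation A [regulation_params()] object (generator truth).
#' @param n_mutants Ensemble size for the gene-deletion-screen emulation.
#' @param mutant_g0_mean Mean drug-free growth rate of mutants, 1/h
#'   (default 85% of the unperturbed rate).
#' @param mutant_g0_cv CV of mutant drug-free growth rates (default 0.15).
#' @param screen_conc Screen drug concentration, ug/ml; default solves for
#'   ~30% wild-type inhibition.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, noise_cv = 0.04, sampling_interval = 10,
                         a_grid = c(0, 2.5, 5, 10),
                         c_grid = c(0, 0.02, 0.05, 0.1, 0.15, 0.2, 0.3, 0.4,
                                    0.6, 0.9, 1.3, 2),
                         n_replicates = 1L,
                         truth = default_model_params(),
                         regulation = default_regulation_params(),
                         n_mutants = 500L,
                         mutant_g0_mean = NULL, mutant_g0_cv = 0.15,
                         screen_conc = NULL) {
  stopifnot(inherits(truth, "model_params"),
            inherits(regulation, "regulation_params"),
            noise_cv >= 0, sampling_interval > 0, n_replicates >= 1,
            n_mutants >= 1, mutant_g0_cv >= 0)
  if (is.null(mutant_g0_mean)) {
    mutant_g0_mean <- 0.85 * drug_free_growth(0, truth)
  }
  structure(
    list(seed = as.integer(seed), noise_cv = noise_cv,
         sampling_interval = sampling_interval,
         a_grid = a_grid, c_grid = c_grid,
         n_replicates = as.integer(n_replicates),
         truth = truth, regulation = regulation,
         n_mutants = as.integer(n_mutants),
         mutant_g0_mean = mutant_g0_mean, mutant_g0_cv = mutant_g0_cv,
         screen_conc = screen_conc),
    class = "synth_config"
  )
}

#' Self-consistent growth and expression at one condition
#'
#' Closes the feedback loop the analysis assumes: expression depends on
#' growth through the regulation law and growth depends on expression through
#' the resource model. Solves `lambda = lambda_model(a, c, chi(lambda, c))`
#' by bisection on `[0, lambda0(a)]`; the solution is unique because the
#' right-hand side is non-increasing in `lambda` (expression falls with
#' growth, and growth rises with expression).
#'
#' @param a Limitation ratio.
#' @param conc Drug concentration, ug/ml.
#' @param truth A [model_params()] object.
#' @param regulation A [regulation_params()] object, or a
#'   `regulation_surface` in constant/inverted mode (expression then ignores
#'   growth and no iteration is needed).
#' @return A list with `lambda` (1/h) and `chi` (a.u.).
#' @export
solve_growth_fixed_point <- function(a, conc, truth, regulation) {
  stopifnot(inherits(truth, "model_params"))
  if (inherits(regulation, "regulation_surface")) {
    if (regulation$mode == "wildtype") {
      stop("fixed-point closure with a fitted wild-type surface is not defined; use regulation_params")
    }
    chi <- eval_regulation(regulation, a, conc)
    return(list(lambda = growth_rate_model(a, conc, chi, truth), chi = chi))
  }
  stopifnot(inherits(regulation, "regulation_params"))
  lam0 <- drug_free_growth(a, truth)
  if (chi_regulation(0, conc, regulation) < 0) {
    stop("degenerate regulation: negative expression at zero growth")
  }
  rhs <- function(lam) {
    chi <- max(0, chi_regulation(lam, conc, regulation))
    growth_rate_model(a, conc, chi, truth)
  }
  f <- function(lam) lam - rhs(lam)
  if (f(lam0) <= 0) {
    lambda <- lam0 # unaffected (ribosome-limited) regime
  } else if (rhs(0) <= 0) {
    lambda <- 0
  } else {
    lambda <- stats::uniroot(f, lower = 0, upper = lam0, tol = 1e-13)$root
  }
  list(lambda = lambda,
       chi = max(0, chi_regulation(lambda, conc, regulation)))
}

#' Generate a synthetic regulation dataset
#'
#' For every combination of limitation ratio and drug concentration in the
#' config's grids, solves the growth--expression fixed point and records
#' growth and expression with multiplicative lognormal measurement noise.
#' The generated table carries the two qualitative signatures of
#' growth-rate-dependent target regulation: expression rises as drug-free
#' growth falls, and expression across limitation levels converges to a
#' common level at concentrations at or above the clamp.
#'
#' @param config A [synth_config()].
#' @return A data frame with columns `a`, `conc`, `growth`, `expression`,
#'   `replicate`, plus noiseless `growth_true`, `expression_true`.
#' @export
generate_regulation_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      conc = config$c_grid, a = config$a_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("a", "conc", "replicate")]
  fp <- mapply(function(a, conc) {
    s <- solve_growth_fixed_point(a, conc, config$truth, config$regulation)
    c(s$lambda, s$chi)
  }, grid$a, grid$conc)
  grid$growth_true <- fp[1, ]
  grid$expression_true <- fp[2, ]
  local_seed(config$seed, {
    grid$growth <- grid$growth_true * lognoise(nrow(grid), config$noise_cv)
    grid$expression <- grid$expression_true * lognoise(nrow(grid), config$noise_cv)
  })
  rownames(grid) <- NULL
  grid[, c("a", "conc", "replicate", "growth", "expression",
           "growth_true", "expression_true")]
}

#' Generate a synthetic OD growth time series
#'
#' Exponential OD growth capped by a logistic carrying capacity, offset by
#' the blank, with multiplicative lognormal noise and a small additive noise
#' floor, sampled at the configured interval.
#'
#' @param rate Exponential growth rate, 1/h, >= 0.
#' @param od0 Initial background-subtracted OD (default 1e-3).
#' @param blank Blank OD offset (default 0.05).
#' @param duration Total duration, minutes (default 1200).
#' @param capacity Logistic carrying capacity in OD units (default 1);
#'   `Inf` gives a pure exponential.
#' @param config A [synth_config()] (supplies seed, noise CV, sampling
#'   interval).
#' @return A [well_timeseries()] of kind `"od"`.
#' @export
generate_growth_timeseries <- function(rate, od0 = 1e-3, blank = 0.05,
                                       duration = 1200, capacity = 1,
                                       config = synth_config()) {
  stopifnot(rate >= 0, od0 > 0, capacity > od0)
  t_min <- seq(0, duration, by = config$sampling_interval)
  g <- exp(rate * t_min / 60)
  od <- if (is.finite(capacity)) {
    capacity * od0 * g / (capacity + od0 * (g - 1))
  } else {
    od0 * g
  }
  noisy <- local_seed(config$seed, {
    if (config$noise_cv > 0) {
      od * lognoise(length(od), config$noise_cv) +
        stats::rnorm(length(od), sd = 1e-4) # additive read-noise floor
    } else {
      od
    }
  })
  well_timeseries(t_min, pmax(noisy, 0) + blank, "od", blank = blank,
                  medium = "minimal", label = sprintf("synthetic rate %.3g", rate))
}

#' Generate a synthetic checkerboard growth matrix
#'
#' Growth at each (limitation, concentration) grid point from the
#' self-consistent fixed point, with multiplicative measurement noise.
#'
#' @param config A [synth_config()].
#' @return A [checkerboard()] (per-row zero-dose normalization mode).
#' @export
generate_checkerboard <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  g <- outer(config$a_grid, config$c_grid, Vectorize(function(a, conc) {
    solve_growth_fixed_point(a, conc, config$truth, config$regulation)$lambda
  }))
  local_seed(config$seed, {
    g <- g * matrix(lognoise(length(g), config$noise_cv), nrow = nrow(g))
  })
  checkerboard(config$a_grid, config$c_grid, g)
}

#' Generate a synthetic gene-deletion-strain ensemble
#'
#' Emulates the structure of a genome-wide deletion screen: each strain draws
#' a drug-free growth rate from a lognormal distribution, and its growth
#' under drug follows from the growth--expression fixed point, with the
#' strain's slower growth entering solely through an effective limitation
#' ratio solved from `lambda0(a_eff) = g0`. This deliberately encodes only
#' the growth-mediated pathway -- there are no gene-specific drug effects.
#' With wild-type regulation the feedback loop is active (slow strains
#' express more target and respond less to the drug); with `"constant"`
#' regulation expression is pinned to the wild-type level at 1 ug/ml and the
#' feedback is off.
#'
#' @param config A [synth_config()].
#' @param mode `"wildtype"` (feedback on) or `"constant"` (feedback off).
#' @return A data frame with columns `strain_id`, `g0` (1/h), `g_drug`
#'   (1/h, with measurement noise), `response` (`g_drug / g0`).
#' @export
generate_mutant_ensemble <- function(config, mode = c("wildtype", "constant")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "synth_config"))
  truth <- config$truth
  lam0_wt <- drug_free_growth(0, truth)
  conc <- if (is.null(config$screen_conc)) {
    screen_concentration(config, inhibition = 0.3)
  } else {
    config$screen_conc
  }
  chi1 <- solve_growth_fixed_point(0, 1.0, truth, config$regulation)$chi

  local_seed(config$seed, {
    sdlog <- sqrt(log(1 + config$mutant_g0_cv^2))
    g0 <- stats::rlnorm(config$n_mutants,
                        meanlog = log(config$mutant_g0_mean) - sdlog^2 / 2,
                        sdlog = sdlog)
    g0 <- pmin(g0, lam0_wt * 0.999)
    g0 <- pmax(g0, 0.05)
    noise <- lognoise(config$n_mutants, config$noise_cv)
  })

  a_eff <- 1 / (truth$omega_C * g0) - truth$omega_R / truth$omega_C - 1
  g_drug <- vapply(seq_along(g0), function(i) {
    if (mode == "wildtype") {
      solve_growth_fixed_point(a_eff[i], conc, truth, config$regulation)$lambda
    } else {
      growth_rate_model(a_eff[i], conc, chi1, truth)
    }
  }, numeric(1))
  g_drug <- g_drug * noise

  data.frame(strain_id = sprintf("strain_%04d", seq_along(g0)),
             g0 = g0, g_drug = g_drug,
             response = g_drug / g0,
             stringsAsFactors = FALSE)
}

#' Drug concentration inhibiting unperturbed growth by a given fraction
#'
#' Solves, on the self-consistent wild-type curve at zero limitation, for the
#' concentration at which growth is inhibited by `inhibition` (default 30%,
#' the screen's working concentration).
#'
#' @param config A [synth_config()].
#' @param inhibition Target inhibition fraction in (0, 1).
#' @return Concentration, ug/ml.
#' @export
screen_concentration <- function(config, inhibition = 0.3) {
  stopifnot(inherits(config, "synth_config"), inhibition > 0, inhibition < 1)
  lam0 <- drug_free_growth(0, config$truth)
  target <- (1 - inhibition) * lam0
  f <- function(lc) {
    solve_growth_fixed_point(0, exp(lc), config$truth,
                             config$regulation)$lambda - target
  }
  exp(stats::uniroot(f, lower = log(1e-6), upper = log(1e4), tol = 1e-12)$root)
}
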