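#' Dose-response curve container
#'
#' Holds one dose-response curve: drug concentrations (including zero dose),
#' absolute growth rates, and the normalization constant `g0` used to express
#' growth relative to the drug-free rate. By default `g0` is the mean growth
#' rate at zero dose.
#'
#' @param conc Drug concentrations, ug/ml, non-negative.
#' @param growth Growth rates, 1/h, same length as `conc`.
#' @param g0 Normalization constant, 1/h. Default: mean growth at `conc == 0`.
#' @param sd Optional per-point standard deviations (same units as `growth`).
#' @param n_replicates Optional replicate counts per point.
#' @return An object of class `dose_response_curve`: a data frame with columns
#'   `conc`, `growth`, `normalized` (and `sd`, `n_replicates` if given),
#'   sorted by concentration, with attribute `g0`.
#' @export
#' @examples
#' curve <- dose_response_curve(c(0, 0.1, 0.3, 1, 3), c(1, 0.95, 0.7, 0.3, 0.08))
#' fit_hill(curve)
dose_response_curve <- function(conc, growth, g0 = NULL, sd = NULL,
                                n_replicates = NULL) {
  stopifnot(is.numeric(conc), is.numeric(growth), length(conc) == length(growth))
  if (any(conc < 0)) stop("concentrations must be non-negative")
  if (!is.null(sd) && any(sd < 0)) stop("`sd` must be non-negative")
  if (is.null(g0)) {
    if (!any(conc == 0)) {
      stop("no zero-dose point present; supply `g0` explicitly")
    }
    g0 <- mean(growth[conc == 0])
  }
  stopifnot(is.numeric(g0), length(g0) == 1L, g0 > 0)
  df <- data.frame(conc = conc, growth = growth, normalized = growth / g0)
  if (!is.null(sd)) df$sd <- sd
  if (!is.null(n_replicates)) df$n_replicates <- n_replicates
  df <- df[order(df$conc), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, g0 = g0, class = c("dose_response_curve", "data.frame"))
}

hill_eval <- function(conc, n, ic50) {
  ifelse(conc == 0, 1, 1 / (1 + (conc / ic50)^n))
}

#' Fit a Hill dose-response function
#'
#' Least-squares fit of `g(c)/g0 = 1 / (1 + (c/IC50)^n)` to a normalized
#' dose-response curve. The Hill exponent `n` ("dose-sensitivity") quantifies
#' the steepness of the curve; `IC50` is the concentration causing 50% growth
#' inhibition. The fit is performed in log-parameter space
#' (`log n`, `log IC50`) with a deterministic multi-start grid; parameter
#' standard deviations and 95% confidence intervals are derived from the fit
#' covariance by the delta method.
#'
#' Points whose absolute growth rate falls below `hill_min_rate` can be
#' excluded: near-zero growth rates carry little information about the shape
#' of the descent and would otherwise dominate fits with many deeply inhibited
#' points.
#'
#' @param curve A [dose_response_curve()].
#' @param hill_min_rate Optional exclusion threshold on absolute growth (1/h);
#'   points with `growth < hill_min_rate` are dropped before fitting.
#' @param weighted If `TRUE` and the curve has an `sd` column, use `1/sd^2`
#'   weights (zero or missing sd points get the median weight). Default
#'   unweighted.
#' @param n_starts Number of multi-start values for the Hill exponent
#'   (log-spaced over 0.5--8); each is paired with three IC50 starts.
#' @param g0_mode `"fixed_zero_dose"` (default) keeps the curve's
#'   normalization constant; `"fitted"` refits it as a free multiplicative
#'   amplitude (useful when the zero-dose measurement is unreliable).
#' @return An object of class `hill_fit` with elements `n`, `ic50`, `sd_n`,
#'   `sd_ic50`, `ci95_n`, `ci95_ic50`, `rss`, `g0`, `g0_mode`, `n_points`,
#'   `data` (points used), and the underlying `fit`.
#' @seealso [inhibitory_concentration()], [predict.hill_fit()]
#' @export
fit_hill <- function(curve, hill_min_rate = NULL, weighted = FALSE,
                     n_starts = 5,
                     g0_mode = c("fixed_zero_dose", "fitted")) {
  g0_mode <- match.arg(g0_mode)
  stopifnot(inherits(curve, "dose_response_curve"))
  df <- as.data.frame(curve)
  if (!is.null(hill_min_rate)) {
    df <- df[df$growth >= hill_min_rate, , drop = FALSE]
  }
  if (all(df$growth == 0)) stop("all growth rates are zero; nothing to fit")
  if (length(unique(df$conc)) < 4L) {
    warning("fewer than 4 distinct concentrations; Hill fit may be unstable")
  }
  if (!any(df$normalized > 0.5) || !any(df$normalized < 0.5)) {
    warning("no points bracket half-maximal growth; expect wide confidence intervals")
  }
  w <- rep(1, nrow(df))
  if (weighted && !is.null(df$sd)) {
    w <- 1 / df$sd^2
    bad <- !is.finite(w)
    if (any(bad)) w[bad] <- stats::median(w[!bad])
  }

  pos <- df$conc > 0
  if (!any(pos)) stop("need at least one positive concentration")
  # IC50 starts: concentration nearest half-maximal growth, bracketed by x/4 and x*4
  i_half <- which.min(abs(df$normalized[pos] - 0.5))
  ic50_0 <- df$conc[pos][i_half]
  starts_ic50 <- ic50_0 * c(0.25, 1, 4)
  starts_n <- exp(seq(log(0.5), log(8), length.out = max(2L, n_starts)))

  obj_fit <- function(ln_n, ln_ic50) {
    tryCatch(
      if (g0_mode == "fixed_zero_dose") {
        minpack.lm::nlsLM(
          normalized ~ 1 / (1 + (conc / exp(lic))^exp(ln)),
          data = df,
          start = list(ln = ln_n, lic = ln_ic50),
          weights = w,
          control = minpack.lm::nls.lm.control(maxiter = 200)
        )
      } else {
        minpack.lm::nlsLM(
          normalized ~ exp(lg) / (1 + (conc / exp(lic))^exp(ln)),
          data = df,
          start = list(ln = ln_n, lic = ln_ic50, lg = 0),
          weights = w,
          control = minpack.lm::nls.lm.control(maxiter = 200)
        )
      },
      error = function(e) NULL
    )
  }

  best <- NULL
  best_rss <- Inf
  for (sn in starts_n) {
    for (si in starts_ic50) {
      f <- obj_fit(log(sn), log(si))
      if (!is.null(f)) {
        rss <- sum(w * stats::residuals(f)^2)
        if (rss < best_rss - 1e-15) {
          best <- f
          best_rss <- rss
        }
      }
    }
  }
  if (is.null(best)) stop("Hill fit did not converge from any start")

  cf <- stats::coef(best)
  n_hat <- exp(cf[["ln"]])
  ic50_hat <- exp(cf[["lic"]])
  vc <- tryCatch(stats::vcov(best), error = function(e) matrix(NA_real_, 2, 2))
  sd_ln <- sqrt(vc[1, 1])
  sd_lic <- sqrt(vc[2, 2])
  structure(
    list(
      n = n_hat,
      ic50 = ic50_hat,
      sd_n = n_hat * sd_ln,
      sd_ic50 = ic50_hat * sd_lic,
      ci95_n = n_hat * exp(c(-1, 1) * 1.96 * sd_ln),
      ci95_ic50 = ic50_hat * exp(c(-1, 1) * 1.96 * sd_lic),
      rss = best_rss,
      g0 = attr(curve, "g0") *
        (if (g0_mode == "fitted") exp(cf[["lg"]]) else 1),
      g0_mode = g0_mode,
      n_points = nrow(df),
      data = df,
      fit = best
    ),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill dose-response fit\n")
  cat(sprintf("  n (dose-sensitivity): %.4g +/- %.3g  [95%% CI %.4g, %.4g]\n",
              x$n, x$sd_n, x$ci95_n[1], x$ci95_n[2]))
  cat(sprintf("  IC50: %.4g +/- %.3g ug/ml\n", x$ic50, x$sd_ic50))
  cat(sprintf("  RSS %.4g over %d points (g0 = %.4g /h)\n",
              x$rss, x$n_points, x$g0))
  invisible(x)
}

#' Predict normalized growth from a Hill fit
#'
#' @param object A `hill_fit`.
#' @param conc Concentrations at which to evaluate, ug/ml.
#' @param ... Unused.
#' @return Normalized growth rates (dimensionless).
#' @export
predict.hill_fit <- function(object, conc, ...) {
  hill_eval(conc, object$n, object$ic50)
}

#' Inhibitory concentration for a given inhibition fraction
#'
#' Inverts the fitted Hill function: the concentration at which normalized
#' growth equals `1 - f` is `IC50 * (f / (1 - f))^(1/n)`. `f = 0.5` returns
#' the IC50 itself; `f = 0.9` returns the IC90.
#'
#' @param fit A `hill_fit`.
#' @param f Inhibition fraction, strictly between 0 and 1 (vectorized).
#' @return Concentration(s), ug/ml.
#' @export
inhibitory_concentration <- function(fit, f) {
  stopifnot(inherits(fit, "hill_fit"), is.numeric(f))
  if (any(f <= 0 | f >= 1)) stop("inhibition fraction must lie strictly in (0, 1)")
  fit$ic50 * (f / (1 - f))^(1 / fit$n)
}
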