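#' Flag measurement records for model fitting
#'
#' Applies the fitting filter: a record passes when the limitation ratio is
#' at most 10, the growth rate is at least 0.05/h and the expression signal
#' is positive. Records outside these bounds are retained but flagged, never
#' silently dropped. Very slow growth and zero fluorescence carry high
#' measurement uncertainty, and the model is only intended to describe
#' moderate limitation.
#'
#' @param records Data frame with columns `a` (limitation ratio), `conc`
#'   (ug/ml), `growth` (1/h) and `expression` (a.u.).
#' @return The same data frame with a logical `passes_filter` column.
#' @export
filter_measurements <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("a", "growth", "expression") %in% names(records)))
  records$passes_filter <- records$a <= 10 &
    records$growth >= 0.05 &
    records$expression > 0
  records
}

#' Build a target-regulation surface from expression measurements
#'
#' Constructs the callable expression surface `F(a, c)` used as the model's
#' regulation input. Per limitation node `a`, expression is regressed on drug
#' concentration by ordinary least squares over `c` in `[0, clamp_c]`
#' (replicates at one `(a, c)` enter with equal weight); between nodes, the
#' regression-predicted expression is interpolated piecewise-linearly in `a`.
#' Expression across conditions converges to a common level at
#' concentrations around `clamp_c` (default 0.4 ug/ml), so the surface is
#' clamped: evaluation at `c > clamp_c` returns the value at `clamp_c`, and
#' measurements beyond `clamp_c` are excluded from the regressions.
#'
#' @param records Data frame with columns `a`, `conc`, `growth`,
#'   `expression`; filtered with [filter_measurements()] first (done
#'   internally if the `passes_filter` column is absent).
#' @param a_nodes Limitation nodes at which per-node regressions are fitted;
#'   default `c(0, 2.5, 5, 10)`.
#' @param clamp_c Convergence concentration, ug/ml; default 0.4.
#' @return An object of class `regulation_surface`.
#' @seealso [eval_regulation()], [rewire_regulation()]
#' @export
build_regulation_surface <- function(records, a_nodes = c(0, 2.5, 5, 10),
                                     clamp_c = 0.4) {
  stopifnot(is.data.frame(records),
            all(c("a", "conc", "expression") %in% names(records)),
            clamp_c > 0)
  if (!"passes_filter" %in% names(records)) {
    records <- filter_measurements(records)
  }
  rec <- records[records$passes_filter, , drop = FALSE]
  a_nodes <- sort(unique(a_nodes))
  coefs <- matrix(NA_real_, nrow = length(a_nodes), ncol = 2,
                  dimnames = list(NULL, c("intercept", "slope")))
  for (k in seq_along(a_nodes)) {
    sub <- rec[abs(rec$a - a_nodes[k]) < 1e-9 & rec$conc <= clamp_c, ,
               drop = FALSE]
    if (length(unique(sub$conc)) < 2L) {
      stop(sprintf("limitation node a = %g has fewer than 2 distinct concentrations in [0, %g]",
                   a_nodes[k], clamp_c))
    }
    fit <- stats::lm.fit(cbind(1, sub$conc), sub$expression)
    coefs[k, ] <- fit$coefficients
  }
  structure(
    list(mode = "wildtype", a_nodes = a_nodes, coefs = coefs,
         clamp_c = clamp_c),
    class = "regulation_surface"
  )
}

#' @export
print.regulation_surface <- function(x, ...) {
  cat(sprintf("Regulation surface (%s mode)\n", x$mode))
  if (x$mode == "wildtype") {
    cat(sprintf("  nodes a = {%s}, clamp at c = %g ug/ml\n",
                paste(x$a_nodes, collapse = ", "), x$clamp_c))
    for (k in seq_along(x$a_nodes)) {
      cat(sprintf("    a = %4g: expression = %.4g %+.4g * c\n",
                  x$a_nodes[k], x$coefs[k, 1], x$coefs[k, 2]))
    }
  } else {
    cat(sprintf("  anchor chi1 = %.4g a.u.\n", x$chi1))
  }
  invisible(x)
}

#' Evaluate a regulation surface
#'
#' Returns the expression level at limitation ratio `a` and drug
#' concentration `conc`. For a wild-type surface, `conc` is clamped to
#' `clamp_c` and the per-node regression predictions are interpolated
#' linearly in `a`; evaluation outside the node hull is refused unless
#' `allow_nearest = TRUE` (nearest-node extrapolation). Rewired surfaces
#' ignore `a`: the constant mode always returns the anchor level `chi1`, the
#' inverted mode returns `chi1 * (2 - min(conc, 1))`, i.e. `2 * chi1` at zero
#' dose decreasing linearly to `chi1` at 1 ug/ml and constant beyond.
#'
#' @param surface A `regulation_surface`.
#' @param a Limitation ratio(s).
#' @param conc Drug concentration(s), ug/ml.
#' @param allow_nearest Allow nearest-node extrapolation in `a`.
#' @return Expression level(s), a.u.
#' @export
eval_regulation <- function(surface, a, conc, allow_nearest = FALSE) {
  stopifnot(inherits(surface, "regulation_surface"))
  k <- max(length(a), length(conc))
  a <- rep_len(a, k)
  conc <- rep_len(conc, k)
  if (any(conc < 0)) stop("`conc` must be non-negative")
  if (surface$mode == "constant") {
    return(rep_len(surface$chi1, k))
  }
  if (surface$mode == "inverted") {
    return(surface$chi1 * (2 - pmin(conc, 1)))
  }
  nodes <- surface$a_nodes
  if (any(a < min(nodes) - 1e-9 | a > max(nodes) + 1e-9)) {
    if (!allow_nearest) {
      stop("limitation ratio outside the node hull; set allow_nearest = TRUE to use the nearest node")
    }
    a <- pmin(pmax(a, min(nodes)), max(nodes))
  } else {
    a <- pmin(pmax(a, min(nodes)), max(nodes))
  }
  cc <- pmin(conc, surface$clamp_c)
  node_vals <- outer(rep(1, k), surface$coefs[, "intercept"]) +
    cc %o% surface$coefs[, "slope"]
  vapply(seq_len(k), function(i) {
    stats::approx(nodes, node_vals[i, ], xout = a[i], ties = mean)$y
  }, numeric(1))
}

#' @export
#' @rdname eval_regulation
#' @param object A `regulation_surface`.
#' @param ... Unused.
predict.regulation_surface <- function(object, a, conc, ...) {
  eval_regulation(object, a, conc)
}

#' Rewire the regulation of the drug target in silico
#'
#' Replaces the measured growth-rate-dependent regulation with a synthetic
#' mode, anchored at `chi1`, the wild-type expression level at the reference
#' limitation and 1 ug/ml drug:
#' \describe{
#'   \item{`"wildtype"`}{the surface is returned unchanged (feedback intact);}
#'   \item{`"constant"`}{expression is held at `chi1` everywhere (feedback
#'     broken);}
#'   \item{`"inverted"`}{expression starts at `2 * chi1` at zero dose and
#'     decreases linearly to `chi1` at 1 ug/ml, constant beyond (feedback
#'     inverted from negative to positive).}
#' }
#'
#' @param surface A wild-type `regulation_surface`.
#' @param mode `"wildtype"`, `"constant"` or `"inverted"`.
#' @param a_ref Reference limitation ratio at which `chi1` is evaluated
#'   (default 0).
#' @return A `regulation_surface` in the requested mode.
#' @export
rewire_regulation <- function(surface, mode = c("wildtype", "constant", "inverted"),
                              a_ref = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(surface, "regulation_surface"))
  if (surface$mode != "wildtype") {
    stop("rewiring starts from a wild-type surface")
  }
  if (mode == "wildtype") return(surface)
  chi1 <- eval_regulation(surface, a_ref, 1.0)
  structure(
    list(mode = mode, chi1 = chi1, a_ref = a_ref, parent = surface),
    class = "regulation_surface"
  )
}
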