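#' Plate-reader well time series
#'
#' One well's signal over time, together with the blank (background) value
#' and the medium, which selects default fit windows downstream.
#'
#' @param time Time points, minutes, strictly increasing.
#' @param signal Signal values, same length as `time`: OD600 (a.u.),
#'   luminescence (counts per second) or fluorescence (a.u.).
#' @param signal_kind One of `"od"`, `"luminescence"`, `"fluorescence"`.
#' @param blank Background in signal units: a scalar, a per-time vector, or
#'   `NULL` to estimate it as the median of the pre-growth signal (the lowest
#'   decile of the series).
#' @param medium `"rich"` or `"minimal"`; selects window defaults in
#'   [growth_fit_config()].
#' @param label Free-text label.
#' @return An object of class `well_timeseries`.
#' @export
well_timeseries <- function(time, signal,
                            signal_kind = c("od", "luminescence", "fluorescence"),
                            blank = NULL, medium = c("minimal", "rich"),
                            label = "") {
  signal_kind <- match.arg(signal_kind)
  medium <- match.arg(medium)
  stopifnot(is.numeric(time), is.numeric(signal), length(time) == length(signal))
  if (is.unsorted(time, strictly = TRUE)) stop("`time` must be strictly increasing")
  if (is.null(blank)) {
    # no blank wells supplied: scalar background from the pre-growth signal
    k <- max(3L, ceiling(length(signal) / 10))
    blank <- stats::median(sort(signal)[seq_len(min(k, length(signal)))])
  }
  stopifnot(is.numeric(blank), length(blank) %in% c(1L, length(signal)))
  if (any(blank < 0)) stop("`blank` must be non-negative")
  structure(
    list(time = time, signal = signal, signal_kind = signal_kind,
         blank = blank, medium = medium, label = label),
    class = "well_timeseries"
  )
}

#' @export
print.well_timeseries <- function(x, ...) {
  cat(sprintf("Well time series '%s': %d points, %s signal, %s medium\n",
              x$label, length(x$time), x$signal_kind, x$medium))
  invisible(x)
}

#' Growth-fit configuration
#'
#' Window bounds and acceptance thresholds for windowed log-linear growth
#' fits. Defaults depend on the medium: rich medium uses a
#' background-subtracted OD window of 0.02--0.2, a lowest accepted rate of
#' 0.1/h and discards data after 1,000 min (to avoid sporadic fast-growing
#' mutants late in drug-containing cultures); minimal medium uses an OD
#' window of 0.03--0.12 (lower growth yield), a lowest accepted rate of
#' 0.03/h and no truncation. Both windows cover at least two doublings.
#' Luminescence fits use a counts-per-second window of 1e2--1e5.
#'
#' @param medium `"minimal"` or `"rich"`.
#' @param od_window_low,od_window_high Background-subtracted OD bounds.
#' @param min_rate Lowest accepted growth rate, 1/h.
#' @param max_time Truncation time, minutes (Inf = none).
#' @param lum_low,lum_high Luminescence window, counts per second.
#' @param hill_min_rate Optional growth-rate threshold excluded from
#'   downstream Hill fits (1/h), carried along for convenience.
#' @return An object of class `growth_fit_config`.
#' @export
growth_fit_config <- function(medium = c("minimal", "rich"),
                              od_window_low = NULL, od_window_high = NULL,
                              min_rate = NULL, max_time = NULL,
                              lum_low = 1e2, lum_high = 1e5,
                              hill_min_rate = NULL) {
  medium <- match.arg(medium)
  defaults <- if (medium == "rich") {
    list(low = 0.02, high = 0.2, min_rate = 0.1, max_time = 1000)
  } else {
    list(low = 0.03, high = 0.12, min_rate = 0.03, max_time = Inf)
  }
  cfg <- list(
    medium = medium,
    od_window_low = if (is.null(od_window_low)) defaults$low else od_window_low,
    od_window_high = if (is.null(od_window_high)) defaults$high else od_window_high,
    min_rate = if (is.null(min_rate)) defaults$min_rate else min_rate,
    max_time = if (is.null(max_time)) defaults$max_time else max_time,
    lum_low = lum_low, lum_high = lum_high,
    hill_min_rate = hill_min_rate
  )
  stopifnot(
    cfg$od_window_low > 0, cfg$od_window_low < cfg$od_window_high,
    cfg$lum_low < cfg$lum_high, cfg$min_rate >= 0
  )
  structure(cfg, class = "growth_fit_config")
}

# Longest contiguous run of TRUE; ties broken toward the earliest run.
longest_run <- function(ok) {
  if (!any(ok)) return(integer(0))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])]
  seq.int(starts[best], ends[best])
}

# Shared windowed log-linear fit on background-subtracted signal.
log_linear_fit <- function(time_min, corrected, low, high, min_rate) {
  reject <- function(reason) {
    structure(
      list(rate = NA_real_, intercept = NA_real_, window_indices = integer(0),
           r_squared = NA_real_, accepted = FALSE, rejection_reason = reason),
      class = "growth_rate_estimate"
    )
  }
  in_window <- is.finite(corrected) & corrected > 0 &
    corrected >= low & corrected <= high
  if (!any(in_window)) return(reject("no_window"))
  idx <- longest_run(in_window)
  if (length(idx) < 3L) return(reject("insufficient_points"))
  x <- time_min[idx] / 60 # fits are reported in 1/h
  y <- log(corrected[idx])
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[[2]]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  accepted <- slope >= min_rate
  structure(
    list(rate = slope, intercept = fit$coefficients[[1]],
         window_indices = range(idx), r_squared = r2,
         accepted = accepted,
         rejection_reason = if (accepted) "none" else "below_min_rate",
         used_indices = idx),
    class = "growth_rate_estimate"
  )
}

#' @export
print.growth_rate_estimate <- function(x, ...) {
  if (is.na(x$rate)) {
    cat(sprintf("Growth-rate estimate: rejected (%s)\n", x$rejection_reason))
  } else {
    cat(sprintf("Growth-rate estimate: %.4g /h (R^2 %.4f, %s%s)\n",
                x$rate, x$r_squared,
                if (x$accepted) "accepted" else "rejected: ",
                if (x$accepted) "" else x$rejection_reason))
  }
  invisible(x)
}

#' Exponential growth rate from an OD time series
#'
#' Windowed log-linear fit: least-squares slope of
#' `log(signal - blank)` versus time, converted to 1/h, over the longest
#' contiguous run of points whose background-subtracted OD lies within the
#' configured window. Points after `max_time` are discarded before windowing;
#' non-positive background-subtracted values inside the window are dropped
#' pointwise (clipping them would bias the slope). Fits with fewer than 3
#' usable points are rejected, as are slopes below the lowest accepted rate.
#'
#' @param series A [well_timeseries()] with `signal_kind = "od"`.
#' @param config A [growth_fit_config()]; defaults to the series' medium.
#' @return A `growth_rate_estimate`: `rate` (1/h), `intercept`,
#'   `window_indices`, `r_squared`, `accepted`, `rejection_reason`.
#' @export
#' @examples
#' t_min <- seq(0, 600, by = 10)
#' od <- 0.01 * exp(0.7 * t_min / 60) + 0.05
#' s <- well_timeseries(t_min, od, "od", blank = 0.05, medium = "rich")
#' fit_growth_rate(s)
fit_growth_rate <- function(series, config = NULL) {
  stopifnot(inherits(series, "well_timeseries"))
  if (series$signal_kind != "od") stop("`fit_growth_rate` requires an OD series")
  if (is.null(config)) config <- growth_fit_config(series$medium)
  keep <- series$time <= config$max_time
  corrected <- (series$signal - series$blank)[keep]
  log_linear_fit(series$time[keep], corrected,
                 config$od_window_low, config$od_window_high, config$min_rate)
}

#' Exponential growth rate from a luminescence time series
#'
#' Same windowed log-linear fit as [fit_growth_rate()], with the window
#' defined on the background-subtracted signal in counts per second
#' (default 1e2--1e5 cps), restricting the fit to strictly exponential
#' luminescence increase.
#'
#' @inheritParams fit_growth_rate
#' @return A `growth_rate_estimate`.
#' @export
fit_luminescence_rate <- function(series, config = NULL) {
  stopifnot(inherits(series, "well_timeseries"))
  if (series$signal_kind != "luminescence") {
    stop("`fit_luminescence_rate` requires a luminescence series")
  }
  if (is.null(config)) config <- growth_fit_config(series$medium)
  keep <- series$time <= config$max_time
  corrected <- (series$signal - series$blank)[keep]
  log_linear_fit(series$time[keep], corrected,
                 config$lum_low, config$lum_high, config$min_rate)
}

#' Reporter expression level from paired fluorescence and OD series
#'
#' The expression level of a fluorescent promoter/fusion reporter is the
#' slope of background-corrected fluorescence versus OD during exponential
#' growth. A reporter-less control strain grown under matched conditions
#' supplies the cellular autofluorescence: at each reporter OD point within
#' the exponential window, the control's background-subtracted fluorescence
#' is linearly interpolated to the same OD and subtracted (the control is
#' rarely sampled at exactly the same ODs). Extrapolation beyond the
#' control's OD range is refused.
#'
#' @param reporter_fluor,reporter_od Fluorescence and OD [well_timeseries()]
#'   for the reporter strain, sampled on the same time grid.
#' @param control_fluor,control_od The same for the reporter-less control.
#' @param config A [growth_fit_config()]; defaults to the reporter's medium.
#' @param rate_tolerance Maximum relative growth-rate mismatch between
#'   reporter and control before a warning flag is raised (default 0.2).
#' @return An object of class `expression_level`: `slope` (fluorescence a.u.
#'   per OD unit), `window_indices`, `r_squared`, `paired_growth_rate` (1/h),
#'   `control_growth_rate`, `rate_mismatch` (logical flag).
#' @export
expression_level <- function(reporter_fluor, reporter_od,
                             control_fluor, control_od,
                             config = NULL, rate_tolerance = 0.2) {
  stopifnot(
    inherits(reporter_fluor, "well_timeseries"),
    inherits(reporter_od, "well_timeseries"),
    inherits(control_fluor, "well_timeseries"),
    inherits(control_od, "well_timeseries")
  )
  if (reporter_od$signal_kind != "od" || control_od$signal_kind != "od") {
    stop("OD series must have signal_kind 'od'")
  }
  if (!isTRUE(all.equal(reporter_fluor$time, reporter_od$time))) {
    stop("reporter fluorescence and OD must share the same time grid")
  }
  if (!isTRUE(all.equal(control_fluor$time, control_od$time))) {
    stop("control fluorescence and OD must share the same time grid")
  }
  if (is.null(config)) config <- growth_fit_config(reporter_od$medium)

  rep_fit <- fit_growth_rate(reporter_od, config)
  ctl_fit <- fit_growth_rate(control_od, config)
  if (!rep_fit$accepted) {
    stop("reporter growth fit not accepted: ", rep_fit$rejection_reason)
  }
  if (!ctl_fit$accepted) {
    stop("control growth fit not accepted: ", ctl_fit$rejection_reason)
  }
  mismatch <- abs(rep_fit$rate - ctl_fit$rate) / rep_fit$rate > rate_tolerance
  if (mismatch) {
    warning(sprintf("reporter and control growth rates differ by more than %.0f%%",
                    100 * rate_tolerance))
  }

  idx <- rep_fit$used_indices
  rep_odc <- (reporter_od$signal - reporter_od$blank)[idx]
  rep_flc <- (reporter_fluor$signal - reporter_fluor$blank)[idx]

  ctl_odc <- control_od$signal - control_od$blank
  ctl_flc <- control_fluor$signal - control_fluor$blank
  ok <- is.finite(ctl_odc) & ctl_odc > 0
  ctl_odc <- ctl_odc[ok]
  ctl_flc <- ctl_flc[ok]
  o <- order(ctl_odc)
  ctl_odc <- ctl_odc[o]
  ctl_flc <- ctl_flc[o]
  if (min(rep_odc) < min(ctl_odc) || max(rep_odc) > max(ctl_odc)) {
    stop("control OD range does not cover the reporter window; refusing to extrapolate")
  }
  bg <- stats::approx(ctl_odc, ctl_flc, xout = rep_odc, ties = mean)$y
  corrected <- rep_flc - bg

  fit <- stats::lm.fit(cbind(1, rep_odc), corrected)
  slope <- fit$coefficients[[2]]
  if (!is.finite(slope)) stop("expression slope is not finite")
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((corrected - mean(corrected))^2)
  structure(
    list(slope = slope,
         window_indices = range(idx),
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
         paired_growth_rate = rep_fit$rate,
         control_growth_rate = ctl_fit$rate,
         rate_mismatch = mismatch),
    class = "expression_level"
  )
}

#' @export
print.expression_level <- function(x, ...) {
  cat(sprintf("Expression level: %.4g a.u./OD (growth %.3g /h, R^2 %.4f)%s\n",
              x$slope, x$paired_growth_rate, x$r_squared,
              if (x$rate_mismatch) " [growth-rate mismatch]" else ""))
  invisible(x)
}
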