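# Shared fixtures and independent oracles used across the suite.

# Exact exponential OD series (no noise) offset by a blank.
make_exp_series <- function(rate_h, od0 = 0.01, blank = 0.05,
                            t_max = 900, by = 10, medium = "rich") {
  t_min <- seq(0, t_max, by = by)
  well_timeseries(t_min, od0 * exp(rate_h * t_min / 60) + blank, "od",
                  blank = blank, medium = medium)
}

# Independent windowed log-linear regression oracle: recomputes the window
# from its definition and solves the normal equations directly.
oracle_log_linear <- function(time_min, corrected, low, high) {
  ok <- is.finite(corrected) & corrected > 0 &
    corrected >= low & corrected <= high
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  idx <- seq.int(starts[best], ends[best])
  x <- time_min[idx] / 60
  y <- log(corrected[idx])
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  list(slope = sxy / sxx, idx = idx)
}

# Hill RSS for the grid-search oracle.
hill_rss <- function(n, ic50, conc, y) {
  pred <- ifelse(conc == 0, 1, 1 / (1 + (conc / ic50)^n))
  sum((y - pred)^2)
}

# Independent Hill oracle: nested golden-section search over (log n, log ic50)
# seeded by a coarse grid; no derivative-based fitter involved.
golden <- function(f, lo, hi, tol = 1e-13) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - phi * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + phi * (b - a); f2 <- f(c2)
    }
  }
  (a + b) / 2
}

oracle_hill <- function(conc, y) {
  grid_n <- exp(seq(log(0.3), log(12), length.out = 40))
  grid_i <- exp(seq(log(min(conc[conc > 0]) / 4), log(max(conc) * 4),
                    length.out = 40))
  rss <- outer(grid_n, grid_i, Vectorize(function(n, i) hill_rss(n, i, conc, y)))
  k <- arrayInd(which.min(rss), dim(rss))
  ln <- log(grid_n[k[1]]); li <- log(grid_i[k[2]])
  for (it in 1:60) {
    li <- golden(function(v) hill_rss(exp(ln), exp(v), conc, y), li - 1, li + 1)
    ln <- golden(function(v) hill_rss(exp(v), exp(li), conc, y), ln - 1, ln + 1)
  }
  list(n = exp(ln), ic50 = exp(li))
}

# Average-rank Spearman via the Pearson-of-ranks formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Generator truth used by the parameter-recovery suite: a reserve regime in
# which drug-free records are strictly ribosome-limited (the two-stage
# procedure's own assumption) and the post-clamp concentrations straddle the
# binding constant so that K_Mc and the demand are separately identifiable.
recovery_truth <- function() model_params(2 / 3, 4 / 9, 0.6, 0.4)
recovery_regulation <- function() {
  regulation_params(1, (1 - 0.6) / 0.9, 0.95)
}
recovery_config <- function(seed, noise_cv = 0.02, n_replicates = 6L) {
  synth_config(
    seed = seed, noise_cv = noise_cv, n_replicates = n_replicates,
    c_grid = c(0, 0.02, 0.05, 0.1, 0.2, 0.3, 0.4, 0.7, 1, 1.4, 2, 3, 4.5),
    truth = recovery_truth(), regulation = recovery_regulation()
  )
}
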