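make_hill_curve <- function(n, ic50, conc = c(0, ic50 * 2^seq(-3, 4)),
                            noise_sd = 0, g0 = 0.9, seed = NULL) {
  y <- ifelse(conc == 0, 1, 1 / (1 + (conc / ic50)^n))
  if (noise_sd > 0) {
    set.seed(seed)
    y <- pmax(y + rnorm(length(y), 0, noise_sd), 1e-4)
  }
  dose_response_curve(conc, y * g0, g0 = g0)
}

test_that("noiseless Hill curves are recovered and the IC50 halves growth", {
  for (truth in list(c(1, 0.3), c(2, 1), c(5, 0.05))) {
    fit <- fit_hill(make_hill_curve(truth[1], truth[2]))
    expect_lt(abs(fit$n - truth[1]) / truth[1], 1e-6)
    expect_lt(abs(fit$ic50 - truth[2]) / truth[2], 1e-6)
    expect_equal(predict(fit, fit$ic50), 0.5, tolerance = 1e-12)
    expect_true(fit$ci95_n[1] <= fit$n && fit$n <= fit$ci95_n[2])
  }
})

test_that("fitted-normalization mode recovers a mis-specified g0", {
  conc <- c(0, 2^seq(-3, 4))
  y <- ifelse(conc == 0, 1, 1 / (1 + (conc / 1)^2))
  # zero-dose growth recorded 10% too low: the fixed mode inherits the bias
  curve <- dose_response_curve(conc, 0.9 * y, g0 = 1.0)
  fit <- fit_hill(curve, g0_mode = "fitted")
  expect_lt(abs(fit$g0 - 0.9) / 0.9, 1e-6)
  expect_lt(abs(fit$n - 2) / 2, 1e-6)
  expect_lt(abs(fit$ic50 - 1), 1e-6)
  expect_identical(fit$g0_mode, "fitted")
})

test_that("Hill fit is equivariant under concentration rescaling and reordering", {
  curve <- make_hill_curve(1.7, 0.4, noise_sd = 0.02, seed = 11)
  fit <- fit_hill(curve)
  curve10 <- dose_response_curve(curve$conc * 10, curve$growth, g0 = 0.9)
  fit10 <- fit_hill(curve10)
  expect_equal(fit10$n, fit$n, tolerance = 1e-6)
  expect_equal(fit10$ic50, fit$ic50 * 10, tolerance = 1e-6)
  perm <- c(5, 1, 8, 3, 9, 2, 7, 4, 6)
  fitp <- fit_hill(dose_response_curve(curve$conc[perm], curve$growth[perm],
                                       g0 = 0.9))
  expect_equal(fitp$n, fit$n, tolerance = 1e-10)
})

test_that("low-rate exclusion reproduces the fit without those points", {
  # base curve stays above the exclusion threshold everywhere
  curve <- make_hill_curve(1.2, 0.5, conc = c(0, 0.5 * 2^seq(-3, 1.5, 0.5)))
  extra_conc <- c(max(curve$conc) * 2, max(curve$conc) * 4)
  aug <- dose_response_curve(c(curve$conc, extra_conc),
                             c(curve$growth, 0.1, 0.1), g0 = 0.9)
  fit_aug <- fit_hill(aug, hill_min_rate = 0.2)
  fit_ref <- fit_hill(curve)
  expect_equal(fit_aug$n, fit_ref$n, tolerance = 1e-8)
  expect_equal(fit_aug$ic50, fit_ref$ic50, tolerance = 1e-8)
  expect_equal(fit_aug$n_points, fit_ref$n_points)
})

test_that("noisy Hill fits match the grid-search oracle", {
  for (seed in 1:3) {
    curve <- make_hill_curve(2, 1, conc = c(0, 2^seq(-3, 3, by = 0.5)),
                             noise_sd = 0.03, seed = seed)
    fit <- fit_hill(curve)
    ora <- oracle_hill(curve$conc, curve$normalized)
    expect_lt(abs(fit$n - ora$n) / ora$n, 1e-7)
    expect_lt(abs(fit$ic50 - ora$ic50) / ora$ic50, 1e-7)
  }
})

test_that("inhibitory concentrations follow the closed form and forward evaluation", {
  fit <- fit_hill(make_hill_curve(2, 1))
  expect_equal(inhibitory_concentration(fit, 0.5), fit$ic50, tolerance = 1e-12)
  fit1 <- fit_hill(make_hill_curve(1, 0.2))
  expect_equal(inhibitory_concentration(fit1, 0.9), 9 * fit1$ic50,
               tolerance = 1e-6)
  # consistency with forward evaluation, and monotonicity in f
  f_grid <- seq(0.05, 0.95, by = 0.05)
  ic <- inhibitory_concentration(fit, f_grid)
  expect_equal(predict(fit, ic), 1 - f_grid, tolerance = 1e-12)
  expect_true(all(diff(ic) > 0))
  expect_error(inhibitory_concentration(fit, 1), "strictly")
})

test_that("checkerboard contours match closed-form inhibitory concentrations", {
  # 2x IC50 shift equals 4 grid steps on this 2^(1/4)-spaced grid, so both
  # rows cross at the same relative position and the ratio is exact
  concs <- c(0, 0.01 * 2^seq(0, 10, by = 0.25))
  n_true <- 1.5
  ic50s <- c(0.3, 0.6)
  g <- t(vapply(ic50s, function(i) {
    ifelse(concs == 0, 1, 1 / (1 + (concs / i)^n_true)) * 0.9
  }, numeric(length(concs))))
  board <- checkerboard(c(0, 1), concs, g)
  ct <- ic_contour(board, level = 0.9)
  closed <- ic50s[1] * (0.9 / 0.1)^(1 / n_true)
  expect_lt(abs(ct$conc[1] - closed) / closed, 0.01)
  expect_equal(ct$conc[2] / ct$conc[1], 2, tolerance = 1e-10)
  expect_true(all(ct$censored == "none"))

  # contour error shrinks at least linearly with grid spacing
  concs2 <- c(0, 0.01 * 2^seq(0, 10, by = 0.0625))
  g2 <- matrix(ifelse(concs2 == 0, 1, 1 / (1 + (concs2 / 0.3)^n_true)) * 0.9,
               nrow = 1)
  ct2 <- ic_contour(checkerboard(0, concs2, g2), level = 0.9)
  expect_lt(abs(ct2$conc[1] - closed), abs(ct$conc[1] - closed) / 2)
})

test_that("censoring and fold-changes behave on degenerate boards", {
  concs <- c(0, 0.1, 0.3, 1)
  flat <- checkerboard(c(0, 1), concs, matrix(0.9, 2, 4))
  ct <- ic_contour(flat, level = 0.9)
  expect_true(all(ct$censored == "right"))
  expect_true(all(is.na(ct$conc)))

  contours <- data.frame(row_value = 0:3, conc = c(1, 2, 2, 2),
                         censored = "none", multiple_crossings = FALSE)
  fc <- fold_change_ic(contours, reference_row = 1, center_row = 3)
  expect_equal(fc$fold_change, 2)
  expect_equal(fc$sd, 0)
  # constant contour: fold-change 1
  contours$conc <- 2
  fc1 <- fold_change_ic(contours, 1, 3)
  expect_equal(fc1$fold_change, 1)
  # censored neighbor propagates
  contours$censored[4] <- "right"
  contours$conc[4] <- NA
  expect_true(fold_change_ic(contours, 1, 3)$censored)
})

test_that("model checkerboard contours shift with limitation only below the clamp", {
  mk_board <- function(n_conc) {
    cfg <- synth_config(seed = 3, noise_cv = 0,
                        a_grid = c(0, 1.25, 2.5, 3.75),
                        c_grid = c(0, exp(seq(log(0.02), log(4),
                                              length.out = n_conc))))
    generate_checkerboard(cfg)
  }
  board <- mk_board(24)
  board_d <- mk_board(240) # 10x denser oracle

  # shallow-inhibition contour (30%): crossings lie below the convergence
  # clamp, where slower conditions hold more target -> contour shifts right
  ct30 <- ic_contour(board, level = 0.3)
  fc30 <- fold_change_ic(ct30, reference_row = 1, center_row = 3)
  expect_false(fc30$censored)
  expect_gt(fc30$fold_change, 1)
  fc30_d <- fold_change_ic(ic_contour(board_d, level = 0.3), 1, 3)
  expect_lt(abs(fc30$fold_change - fc30_d$fold_change) / fc30_d$fold_change,
            0.02)

  # IC90 crossings lie beyond the clamp, where expression has converged and
  # the per-row-normalized response is identical across conditions
  ct90 <- ic_contour(board, level = 0.9)
  fc90 <- fold_change_ic(ct90, reference_row = 1, center_row = 3)
  expect_false(fc90$censored)
  expect_equal(fc90$fold_change, 1, tolerance = 1e-6)
  fc90_d <- fold_change_ic(ic_contour(board_d, level = 0.9), 1, 3)
  expect_lt(abs(fc90$fold_change - fc90_d$fold_change) / fc90_d$fold_change,
            0.02)
})
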