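test_that("proteome fractions follow the growth law and stay normalized", {
  p <- model_params(2, 1, 0.1, 0.5)
  expect_equal(proteome_fractions(0, p), list(phi_R = 0, phi_C = 1))
  fr <- proteome_fractions(0.25, p)
  expect_equal(fr$phi_R, 0.5)
  expect_equal(fr$phi_R + fr$phi_C, 1)
  expect_error(proteome_fractions(0.6, p), "infeasible")
})

test_that("drug-free growth has the stated form and halving point", {
  p <- model_params(1, 1, 0.1, 0.5)
  expect_equal(drug_free_growth(0, p), 0.5)
  a <- seq(0, 10, by = 0.5)
  expect_true(all(diff(drug_free_growth(a, p)) < 0))
  a_star <- half_growth_limitation(p)
  expect_lt(abs(drug_free_growth(a_star, p) - drug_free_growth(0, p) / 2),
            1e-12)
  expect_error(drug_free_growth(-1, p), "non-negative")
})

test_that("free enzyme follows the binding equilibrium identity", {
  expect_equal(free_fola(3, 0, 0.1), 3)
  expect_equal(free_fola(3, 0.1, 0.1), 1.5)
  # [free] * c / [bound] = K_Mc exactly
  chi <- 2.7; conc <- 0.37; K <- 0.21
  free <- free_fola(chi, conc, K)
  bound <- chi - free
  expect_equal(free * conc / bound, K, tolerance = 1e-12)
})

test_that("growth model has the exact kink and the two regimes", {
  p <- model_params(1, 0.5, 0.2, 0.4)
  lam0 <- drug_free_growth(1, p)
  # excess expression: ribosome-limited regime exactly
  expect_equal(growth_rate_model(1, 0.3, 0.4 * (1 + 0.3 / 0.2), p), lam0)
  expect_equal(growth_rate_model(1, 0, 0.2, p), lam0 / 2)
  chi <- 0.8 # reserve ratio 2: kink at c* = K_Mc
  c_star <- p$K_Mc * (chi / p$chi_demand - 1)
  cs <- seq(0, 4 * c_star, length.out = 201)
  g <- growth_rate_model(1, cs, chi, p)
  expect_true(all(g[cs <= c_star] == lam0))
  post <- g[cs > c_star + 1e-9]
  expect_true(all(diff(post) < 0))
})

test_that("dimensional and rescaled forms agree on random draws", {
  set.seed(5)
  for (i in 1:10) {
    p <- model_params(runif(1, 0.3, 3), runif(1, 0.1, 2),
                      runif(1, 0.01, 1), runif(1, 0.1, 2))
    r <- rescaled_params(p)
    back <- dimensional_params(r)
    expect_equal(unclass(back)[1:4], unclass(p)[1:4], tolerance = 1e-15)
    a <- runif(20, 0, 10); conc <- runif(20, 0, 2); chi <- runif(20, 0, 3)
    lam <- growth_rate_model(a, conc, chi, p)
    lam_bar <- rescaled_growth(a, conc / p$K_Mc, chi / p$chi_demand, r$A)
    expect_equal(lam, lam_bar / p$omega_R, tolerance = 1e-12)
  }
  # distinct dimensional parameter sets sharing A give identical rescaled
  # growth surfaces
  A1 <- rescaled_params(model_params(1, 0.5, 0.1, 0.3))$A
  A2 <- rescaled_params(model_params(2, 1, 0.7, 1.9))$A
  grid <- expand.grid(a = c(0, 2, 8), cb = c(0, 0.5, 3), xb = c(0.4, 1, 2.5))
  expect_identical(rescaled_growth(grid$a, grid$cb, grid$xb, A1),
                   rescaled_growth(grid$a, grid$cb, grid$xb, A2))
})

test_that("measurement filter flags exactly the stated records", {
  rec <- data.frame(
    a = c(12, 5, 5, 5, 0, 10.0001),
    conc = 0,
    growth = c(0.5, 0.04, 0.5, 0.5, 0.05, 0.5),
    expression = c(100, 100, 0, 1, 1, 1)
  )
  out <- filter_measurements(rec)
  expect_equal(out$passes_filter, c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
})

test_that("regulation surface reproduces an exact plane and clamps above 0.4", {
  rec <- expand.grid(a = c(0, 2.5, 5, 10), conc = c(0, 0.2, 0.4))
  rec$growth <- 0.5
  rec$expression <- (10 - rec$a) + 5 * rec$conc
  surf <- build_regulation_surface(rec)
  expect_equal(eval_regulation(surf, 2.5, 0.2), 8.5, tolerance = 1e-10)
  expect_equal(eval_regulation(surf, 7.5, 0.1), 3, tolerance = 1e-10)
  for (a in c(0, 1.3, 5, 10)) {
    expect_equal(eval_regulation(surf, a, 0.9), eval_regulation(surf, a, 0.4),
                 tolerance = 1e-12)
    expect_equal(eval_regulation(surf, a, 2.0), eval_regulation(surf, a, 0.4),
                 tolerance = 1e-12)
  }
  expect_error(eval_regulation(surf, 11, 0), "hull")
  expect_equal(eval_regulation(surf, 11, 0, allow_nearest = TRUE),
               eval_regulation(surf, 10, 0))
})

test_that("duplicated records shift node regressions as the normal equations predict", {
  rec <- expand.grid(a = 0, conc = c(0, 0.1, 0.2, 0.3, 0.4))
  rec$growth <- 0.5
  rec$expression <- c(1.02, 1.18, 1.22, 1.35, 1.38)
  dup <- rbind(rec, rec[3, ])
  surf <- build_regulation_surface(dup, a_nodes = 0)
  X <- cbind(1, dup$conc)
  beta <- solve(crossprod(X), crossprod(X, dup$expression))
  expect_equal(unname(surf$coefs[1, ]), as.numeric(beta), tolerance = 1e-12)
})

test_that("rewired surfaces implement the constant and inverted modes", {
  surf <- default_regulation_surface()
  chi1 <- eval_regulation(surf, 0, 1.0)
  const <- rewire_regulation(surf, "constant")
  inv <- rewire_regulation(surf, "inverted")
  expect_equal(eval_regulation(const, 5, 0.123), chi1)
  expect_equal(eval_regulation(const, 0, 2), chi1)
  expect_equal(eval_regulation(inv, 0, 0), 2 * chi1)
  expect_equal(eval_regulation(inv, 0, 0.5), 1.5 * chi1)
  expect_equal(eval_regulation(inv, 0, 1), chi1)
  expect_equal(eval_regulation(inv, 0, 2), chi1)
  expect_identical(rewire_regulation(surf, "wildtype"), surf)
})

test_that("drug-free fit recovers parameters and ignores duplication", {
  truth <- c(omega_R = 0.5, omega_C = 0.3)
  rec <- data.frame(a = c(0, 1, 2, 5, 10), conc = 0, expression = 1)
  rec$growth <- 1 / (truth[1] + truth[2] * (rec$a + 1))
  fit <- fit_drug_free(rec)
  expect_lt(abs(fit$omega_R - truth[1]) / truth[1], 1e-8)
  expect_lt(abs(fit$omega_C - truth[2]) / truth[2], 1e-8)
  fit2 <- fit_drug_free(rbind(rec, rec))
  expect_equal(fit2$omega_R, fit$omega_R, tolerance = 1e-10)

  # 5% noise: estimates sit within one grid cell of a dense grid-search minimum
  set.seed(9)
  noisy <- rec[rep(1:5, each = 8), ]
  noisy$growth <- noisy$growth * exp(rnorm(nrow(noisy), 0, 0.05))
  fitn <- fit_drug_free(noisy)
  wr <- seq(0.3, 0.8, length.out = 120)
  wc <- seq(0.15, 0.5, length.out = 120)
  rss <- outer(wr, wc, Vectorize(function(r, c) {
    sum((noisy$growth - 1 / (r + c * (noisy$a + 1)))^2)
  }))
  k <- arrayInd(which.min(rss), dim(rss))
  expect_lt(abs(fitn$omega_R - wr[k[1]]), diff(wr)[1])
  expect_lt(abs(fitn$omega_C - wc[k[2]]), diff(wc)[1])
})

test_that("drug-response fit is self-consistent and flags unidentifiable data", {
  truth <- recovery_truth()
  cfg <- recovery_config(seed = 1, noise_cv = 0, n_replicates = 1L)
  rec <- generate_regulation_dataset(cfg)
  surf <- build_regulation_surface(rec)
  fit <- fit_drug_response(rec, truth$omega_R, truth$omega_C, surf)
  expect_lt(abs(fit$K_Mc - truth$K_Mc) / truth$K_Mc, 1e-6)
  expect_lt(abs(fit$chi_demand - truth$chi_demand) / truth$chi_demand, 1e-6)

  # rescaling surface and demand together leaves predictions unchanged:
  # the fit recovers the ratio-consistent pair
  surf2 <- surf
  surf2$coefs <- surf$coefs / 2
  rec2 <- rec
  fit2 <- fit_drug_response(rec2, truth$omega_R, truth$omega_C, surf2)
  expect_lt(abs(fit2$chi_demand - truth$chi_demand / 2) /
              (truth$chi_demand / 2), 1e-5)
  expect_lt(abs(fit2$K_Mc - truth$K_Mc) / truth$K_Mc, 1e-5)

  # only unaffected records: chi_demand cannot be identified
  flat <- rec[rec$conc <= 0.1, ]
  expect_error(
    fit_drug_response(flat, truth$omega_R, truth$omega_C, surf),
    "unidentifiable"
  )

  # with noise, the objective at the fit is no worse than at the truth
  cfgn <- recovery_config(seed = 2, noise_cv = 0.05, n_replicates = 1L)
  recn <- generate_regulation_dataset(cfgn)
  surfn <- build_regulation_surface(recn)
  fitn <- fit_drug_response(recn, truth$omega_R, truth$omega_C, surfn)
  dfn <- filter_measurements(recn)
  dfn <- dfn[dfn$passes_filter, ]
  chi_n <- eval_regulation(surfn, dfn$a, dfn$conc, allow_nearest = TRUE)
  rss_at <- function(K, x) {
    lam0 <- 1 / (truth$omega_R + truth$omega_C * (dfn$a + 1))
    sum((dfn$growth - lam0 * pmin(1, (chi_n / x) / (1 + dfn$conc / K)))^2)
  }
  expect_lte(fitn$rss, rss_at(truth$K_Mc, truth$chi_demand) + 1e-12)
})

test_that("model dose-response reduces to a pure Hill curve without reserve", {
  p <- model_params(2 / 3, 4 / 9, 0.2, 0.5)
  # constant expression exactly at demand: curve is lambda0 / (1 + c/K_Mc)
  surf <- structure(list(mode = "constant", chi1 = p$chi_demand),
                    class = "regulation_surface")
  res <- model_dose_response(p, surf, a = 0)
  expect_lt(abs(res$fit$n - 1), 1e-6)
  expect_lt(abs(res$fit$ic50 - p$K_Mc) / p$K_Mc, 1e-6)
})

test_that("feedback rewiring orders dose-sensitivity as negative < none < positive", {
  ch <- model_steepness_chain()
  expect_lt(ch$n_wildtype, ch$n_constant)
  expect_lt(ch$n_constant, ch$n_inverted)
  # slower growth steepens the wild-type curve
  expect_gt(ch$n_half_growth, ch$n_wildtype)
})
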