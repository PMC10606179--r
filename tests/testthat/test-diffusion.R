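test_that("series solution has the analytic intercept and converges at t = 0", {
  expect_equal(fick_mr(0, 1e-9, 0.005, n_terms = 1), 8 / pi^2, tolerance = 1e-12)
  # sum over odd reciprocal squares converges to pi^2/8, so MR(0) -> 1
  expect_equal(fick_mr(0, 1e-9, 0.005, n_terms = 1e4), 1, tolerance = 1e-4)
  # hand evaluation of the first term at Deff = 1.0074e-9, L/2 = 5 mm, 1 h
  expect_equal(fick_mr_first_term(3600, 1.0074e-9, 0.005),
               8 / pi^2 * exp(-3600 * pi^2 * 1.0074e-9 / 1e-4), tolerance = 1e-12)
})

test_that("series is monotone in time, diffusivity and thickness", {
  lh <- 0.005; d <- 1.2e-9
  t <- seq(0, 10, by = 0.5) * 3600
  mr <- fick_mr(t, d, lh)
  expect_true(all(diff(mr) < 0))
  expect_true(all(fick_mr(t[-1], 2 * d, lh) < fick_mr(t[-1], d, lh)))
  # doubling the slab at fixed Deff and t raises MR (quarter the exponent)
  expect_true(all(fick_mr(t[-1], d, 2 * lh) > fick_mr(t[-1], d, lh)))
  e1 <- -log(fick_mr_first_term(3600, d, lh) / (8 / pi^2))
  e2 <- -log(fick_mr_first_term(3600, d, 2 * lh) / (8 / pi^2))
  expect_equal(e1 / e2, 4, tolerance = 1e-10)
})

test_that("partial sums only add mass at t = 0 and truncation is tight above Fo 0.2", {
  vals <- sapply(1:8, function(nt) fick_mr(0, 1e-9, 0.005, n_terms = nt))
  expect_true(all(diff(vals) > 0))
  lh <- 0.005; d <- 1e-9; tau <- lh^2 / d
  fo <- c(0.2, 0.3, 0.5, 1, 2)
  one <- fick_mr(fo * tau, d, lh, n_terms = 1)
  fifty <- fick_mr(fo * tau, d, lh, n_terms = 50)
  expect_true(all(abs(one - fifty) / fifty < 0.005))
  # below Fo 0.2 the first term alone is visibly biased
  expect_gt(abs(fick_mr(0.02 * tau, d, lh, n_terms = 1) -
                fick_mr(0.02 * tau, d, lh, n_terms = 50)) /
            fick_mr(0.02 * tau, d, lh, n_terms = 50), 0.005)
})

test_that("diffusivity regression inverts the first-term model exactly", {
  d_true <- 1.2e-9; L <- 0.01
  t_h <- 0:10
  mr <- fick_mr_first_term(t_h * 3600, d_true, L / 2)
  s <- mr_series(t_h * 3600, mr, temperature = 60, slab_thickness = L,
                 normalized = FALSE)
  est <- estimate_deff(s, intercept_mode = "fixed")
  expect_equal(est$d_eff, d_true, tolerance = 1e-6)
  expect_equal(est$r_squared, 1, tolerance = 1e-9)
  est_free <- estimate_deff(s, intercept_mode = "free")
  expect_equal(est_free$d_eff, d_true, tolerance = 1e-6)
  expect_equal(est_free$intercept, log(8 / pi^2), tolerance = 1e-9)
})

test_that("restricting the regression to Fo > 0.2 bounds full-series truncation bias", {
  d_true <- 1.2e-9; L <- 0.01
  t_h <- 0:10
  mr <- fick_mr(t_h * 3600, d_true, L / 2, n_terms = 50)
  s <- mr_series(t_h * 3600, pmin(mr, 1.02), temperature = 60,
                 slab_thickness = L, normalized = FALSE)
  est <- estimate_deff(s, intercept_mode = "fixed", min_fourier = 0.2)
  expect_equal(est$d_eff, d_true, tolerance = 0.02)
})

test_that("degenerate regressions are flagged, short series are errors", {
  s <- mr_series(c(0, 3600, 7200, 10800), rep(8 / pi^2, 4), 60, 0.01,
                 normalized = FALSE)
  expect_warning(est <- estimate_deff(s), "not physical")
  expect_equal(est$slope, 0)
  expect_true(est$non_physical)
  short <- mr_series(c(0, 3600, 7200), c(1, 0.5, 0), 60, 0.01)
  expect_error(suppressMessages(estimate_deff(short)), "3 usable")
})

test_that("Arrhenius fit recovers noise-free parameters and rejects bad input", {
  d0 <- 1e-7; ea <- 20e3
  temps <- seq(45, 80, by = 7)
  deff <- d0 * exp(-ea / (GAS_CONSTANT * (temps + 273.15)))
  fit <- fit_arrhenius(temps, deff)
  expect_equal(fit$e_a, ea, tolerance = 1e-9)
  expect_equal(fit$d0, d0, tolerance = 1e-9)
  expect_equal(predict(fit, temps), deff, tolerance = 1e-9)
  expect_error(fit_arrhenius(c(50, 50, 60), c(1, 2, 3) * 1e-9), "duplicate")
  expect_error(fit_arrhenius(c(50, 60), c(1, 2) * 1e-9), "3 temperature")
  expect_error(fit_arrhenius(c(50, 60, 70), c(1, -2, 3) * 1e-9), "positive")
})

test_that("finite-difference solver reproduces the series solution", {
  d <- 1e-9; lh <- 0.005; tau <- lh^2 / d
  fo <- c(0.01, 0.05, 0.1, 0.2, 0.5, 1, 2)
  num <- fd_solve(d, lh, fo * tau, n_nodes = 201)
  ref <- fick_mr(fo * tau, d, lh, n_terms = 200)
  expect_lt(max(abs(num - ref)), 1e-3)
  expect_equal(fd_solve(d, lh, 0), 1)
  # monotone in diffusivity at fixed time
  t1 <- 0.3 * tau
  expect_lt(fd_solve(2 * d, lh, t1), fd_solve(d, lh, t1))
})

test_that("finite-difference solution converges under grid halving", {
  d <- 1e-9; lh <- 0.005; t <- 0.25 * lh^2 / d
  ref <- fick_mr(t, d, lh, n_terms = 200)
  err <- sapply(c(51, 101, 201), function(n) abs(fd_solve(d, lh, t, n_nodes = n) - ref))
  expect_true(all(diff(err) < 0))
  expect_error(fd_solve(d, lh, t, n_nodes = 5), ">= 11")
})
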