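test_that("goodness-of-fit statistics match independent arithmetic", {
  # brute-force reimplementation on random vectors
  set.seed(42)
  for (i in 1:5) {
    e <- runif(10); p <- e + rnorm(10, sd = 0.05)
    g <- gof_stats(e, p, n_params = 2)
    sse <- 0; sst <- 0; me <- sum(e) / length(e)
    for (j in seq_along(e)) {
      sse <- sse + (p[j] - e[j])^2
      sst <- sst + (e[j] - me)^2
    }
    expect_equal(g$rmse, sqrt(sse / 10), tolerance = 1e-12)
    expect_equal(g$chi_squared, sse / 8, tolerance = 1e-12)
    expect_equal(g$r_squared, 1 - sse / sst, tolerance = 1e-12)
  }
})

test_that("goodness-of-fit handles the worked example and edge cases", {
  e <- c(1, 0.5, 0.25); p <- c(1, 0.45, 0.3)
  g <- gof_stats(e, p, n_params = 1)
  # hand arithmetic: SSE = 0.05^2 + 0.05^2 = 0.005; SST about mean 7/12 is 42/144
  expect_equal(g$rmse, sqrt(0.005 / 3), tolerance = 1e-12)
  expect_equal(g$chi_squared, 0.005 / 2, tolerance = 1e-12)
  expect_equal(g$r_squared, 1 - 0.005 / (42 / 144), tolerance = 1e-12)
  # perfect fit
  gp <- gof_stats(e, e, n_params = 1)
  expect_equal(c(gp$r_squared, gp$chi_squared, gp$rmse), c(1, 0, 0))
  # constant observations with varying predictions: R^2 <= 0, unclamped
  gc <- gof_stats(c(0.5, 0.5, 0.5), c(0.4, 0.5, 0.6), n_params = 1)
  expect_lte(gc$r_squared, 0)
  expect_error(gof_stats(e, p[1:2], 1), "lengths differ")
  expect_error(gof_stats(e, p, n_params = 3), "N > n")
})

test_that("the as-printed R-squared variant centers on the predictions", {
  e <- c(1, 0.5, 0.25); p <- c(1, 0.45, 0.3)
  g <- gof_stats(e, p, n_params = 1, r2_variant = "as_printed")
  expect_equal(g$r_squared, 1 - 0.005 / sum((e - mean(p))^2), tolerance = 1e-12)
})

test_that("noise-free single-model fits recover the generator", {
  s <- model_series("newton", c(k = 0.6))
  f <- fit_model(s, "newton")
  expect_true(f$converged)
  expect_equal(unname(f$theta_hat[["k"]]), 0.6, tolerance = 1e-6)
  s2 <- model_series("two_term", c(a = 0.32, k1 = 0.27, b = 0.68, k2 = 0.75))
  f2 <- fit_model(s2, "two_term")
  expect_lt(f2$sse, 1e-12)
})

test_that("fitting requires more observations than parameters", {
  short <- mr_series(c(0, 3600, 7200), c(1, 0.6, 0.3), 60, 0.01)
  expect_error(fit_model(short, "two_term"), "N = 3, n = 4")
})

test_that("every registered model refits its own noise-free data", {
  truths <- recovery_truth()
  for (nm in names(truths)) {
    s <- model_series(nm, truths[[nm]], hours = seq(0, 11, by = 0.5))
    f <- fit_model(s, nm)
    expect_lt(f$sse, 1e-10, label = paste(nm, "SSE"))
    if (nm == "two_term") {
      th <- f$theta_hat
      if (th[["k1"]] > th[["k2"]]) th <- th[c("b", "k2", "a", "k1")]
      expect_equal(unname(th), unname(truths[[nm]]), tolerance = 1e-4)
    } else if (!nm %in% c("modified_henderson_pabis")) {
      expect_equal(unname(f$theta_hat[names(truths[[nm]])]),
                   unname(truths[[nm]]), tolerance = 1e-4,
                   label = paste(nm, "parameters"))
    }
  }
})

test_that("noisy Newton rate recovery stays within a few percent", {
  k_true <- 0.6
  errs <- vapply(1:200, function(seed) {
    cu <- gen_drying_curve("newton", c(k = k_true), noise_sd = 0.01, seed = seed)
    f <- fit_model(moisture_ratio_series(cu), "newton", n_starts = 2)
    abs(f$theta_hat[["k"]] / k_true - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("ranking is deterministic and prefers the generating model", {
  s <- model_series("two_term", c(a = 0.3408, k1 = 0.3562, b = 0.6593, k2 = 1.3215))
  rk1 <- fit_all_models(s)
  rk2 <- fit_all_models(s)
  expect_identical(as.data.frame(rk1), as.data.frame(rk2))
  expect_identical(rk1$model[1], "two_term")
  expect_equal(nrow(rk1), 10)
  # Newton data: Newton, Page (n ~ 1) and Modified Page (n ~ 1) all reach
  # SSE ~ 0 and the parameter-count tie-break puts Newton first
  sn <- model_series("newton", c(k = 0.6))
  rkn <- fit_all_models(sn)
  top <- as.data.frame(rkn)
  expect_identical(top$model[1], "newton")
  expect_lt(top$rmse[top$model == "page"], 1e-6)
  expect_lt(top$rmse[top$model == "modified_page"], 1e-6)
  # single requested model
  expect_equal(nrow(fit_all_models(sn, "newton")), 1)
  expect_error(fit_all_models(sn, character(0)), "at least one")
})

test_that("Page and Modified Page reach the same SSE with related parameters", {
  s <- model_series("page", c(k = 0.5854, n = 0.8494))
  fp <- fit_model(s, "page")
  fm <- fit_model(s, "modified_page")
  expect_equal(fp$sse, fm$sse, tolerance = 1e-8)
  expect_equal(page_to_modified_page(fp$theta_hat[["k"]], fp$theta_hat[["n"]]),
               fm$theta_hat[["k"]], tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("per-model failures become flagged rows, not aborts", {
  short <- mr_series(c(0, 3600, 7200, 10800), c(1, 0.7, 0.45, 0.3), 60, 0.01)
  rk <- fit_all_models(short, c("newton", "modified_henderson_pabis"))
  tab <- as.data.frame(rk)
  expect_false(is.na(tab$error[tab$model == "modified_henderson_pabis"]))
  expect_true(is.na(tab$error[tab$model == "newton"]))
  expect_identical(tab$model[1], "newton")
})

test_that("Hartley Fmax statistic and Monte-Carlo decision behave", {
  g_same <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  h <- hartley_fmax(g_same, n_sim = 2000, seed = 7)
  expect_equal(h$fmax, 1)
  expect_true(h$homogeneous)
  # fixture with sample variances 1 and 4: Fmax = 4 by direct arithmetic
  g2 <- list(c(1, 2, 3), c(2, 4, 6))
  expect_equal(hartley_fmax(g2, n_sim = 500, seed = 1)$fmax, 4)
  expect_error(hartley_fmax(list(c(1, 1, 1), c(1, 2, 3)), n_sim = 100), "zero variance")
  expect_error(hartley_fmax(list(c(1, 2))), "2 groups")
})

test_that("Monte-Carlo critical values are stable across seeds", {
  g <- list(c(1, 2, 3), c(2, 4, 5), c(1, 3, 6))
  c1 <- hartley_fmax(g, n_sim = 1e5, seed = 1)$critical
  c2 <- hartley_fmax(g, n_sim = 1e5, seed = 2)$critical
  expect_lt(abs(c1 - c2) / c1, 0.02)
})
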