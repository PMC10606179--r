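test_that("registry exposes ten models with the classical arities", {
  reg <- thin_layer_models()
  expect_length(reg, 10)
  arities <- vapply(reg, `[[`, integer(1), "arity")
  expect_identical(arities[["newton"]], 1L)
  expect_identical(arities[["fick_first_term"]], 1L)
  expect_identical(arities[["page"]], 2L)
  expect_identical(arities[["modified_page"]], 2L)
  expect_identical(arities[["henderson_pabis"]], 2L)
  expect_identical(arities[["two_term_exponential"]], 2L)
  expect_identical(arities[["logarithmic"]], 3L)
  expect_identical(arities[["midili"]], 4L)
  expect_identical(arities[["two_term"]], 4L)
  expect_identical(arities[["modified_henderson_pabis"]], 6L)
  expect_error(lookup_model("weibull"), "valid names")
})

test_that("every model evaluates finitely at mid-bound parameters", {
  for (m in thin_layer_models()) {
    theta <- (m$lower + m$upper) / 2
    vals <- evaluate_model(m, theta, c(0, 1, 10))
    expect_true(all(is.finite(vals)), label = m$name)
  }
})

test_that("model intercepts and limits follow their closed forms", {
  expect_equal(evaluate_model("newton", c(k = 1.7), 0), 1)
  # two-term at the 65 degC study constants: intercept a + b = 1.0001
  th <- study_params("two_term", 65)
  expect_equal(evaluate_model("two_term", th, 0), 0.3408 + 0.6593, tolerance = 1e-12)
  # two-term-exponential intercept is exactly 1 for any (a, k)
  expect_equal(evaluate_model("two_term_exponential", c(a = 0.37, k = 2.1), 0), 1)
  # Henderson-Pabis starts at a; logarithmic tends to b
  expect_equal(evaluate_model("henderson_pabis", c(a = 0.9817, k = 0.5), 0), 0.9817)
  expect_equal(evaluate_model("logarithmic", c(a = 0.96, k = 0.55, b = 0.0276), 1e6),
               0.0276, tolerance = 1e-12)
})

test_that("model nestings hold on a time grid", {
  t_h <- seq(0, 11, by = 0.25)
  # Midilli with b = 0 is a scaled Page curve
  expect_equal(evaluate_model("midili", c(a = 0.93, k = 0.58, n = 0.88, b = 0), t_h),
               0.93 * evaluate_model("page", c(k = 0.58, n = 0.88), t_h),
               tolerance = 1e-12)
  # two-term with a + b = 1 and equal rates collapses to Newton
  expect_equal(evaluate_model("two_term", c(a = 0.4, k1 = 0.7, b = 0.6, k2 = 0.7), t_h),
               evaluate_model("newton", c(k = 0.7), t_h), tolerance = 1e-12)
  # Page and Modified Page with n = 1 coincide
  expect_equal(evaluate_model("page", c(k = 0.8, n = 1), t_h),
               evaluate_model("modified_page", c(k = 0.8, n = 1), t_h),
               tolerance = 1e-12)
})

test_that("Page and Modified Page parameterizations are exactly equivalent", {
  t_h <- seq(0, 11, by = 0.5)
  k <- 0.5854; n <- 0.8494
  k_mp <- page_to_modified_page(k, n)
  expect_equal(evaluate_model("page", c(k = k, n = n), t_h),
               evaluate_model("modified_page", c(k = k_mp, n = n), t_h),
               tolerance = 1e-12)
  expect_equal(page_to_modified_page(2.3, 1), 2.3)
  expect_error(page_to_modified_page(-1, 0.8), "positive")
  expect_error(page_to_modified_page(0.5, 0), "positive")
})

test_that("evaluation rejects arity mismatches", {
  expect_error(evaluate_model("two_term", c(a = 1, k1 = 0.5), 1), "4 parameter")
  expect_error(evaluate_model("newton", c(k = 1, n = 1), 1), "1 parameter")
})

test_that("rate-unit conversion is exact and invertible", {
  expect_equal(convert_rate(3600, "per_hour", "per_second"), 1)
  expect_equal(convert_rate(convert_rate(0.5854, "per_hour", "per_second"),
                            "per_second", "per_hour"), 0.5854)
})
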