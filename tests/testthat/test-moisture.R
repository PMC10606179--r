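test_that("wet/dry basis conversion matches hand arithmetic and round-trips", {
  # 82.63 % wt. water -> 82.63/17.37 kg water per kg dry solid
  expect_equal(wet_to_dry_basis(82.63), 82.63 / 17.37, tolerance = 1e-12)
  expect_equal(wet_to_dry_basis(50), 1)
  expect_equal(wet_to_dry_basis(0), 0)
  # round trip is the identity across the admissible range
  m_wb <- c(0, 1e-6, 5, 50, 82.63, 99, 99.9)
  expect_equal(dry_to_wet_basis(wet_to_dry_basis(m_wb)), m_wb, tolerance = 1e-12)
  expect_error(wet_to_dry_basis(100), "100")
  expect_error(wet_to_dry_basis(-3), "-3")
})

test_that("dry-basis resolution from masses matches hand arithmetic", {
  # 30 g sample at 82.63 % wt. -> dry solid 5.211 g, initial M = 4.757 kg/kg
  curve <- drying_curve(time_h = 0:2, mass_g = c(30, 20, 10), temperature = 60,
                        slab_thickness = 0.01, initial_wet_basis = 82.63)
  M <- resolve_dry_basis(curve)
  ms <- 30 * (1 - 82.63 / 100)
  expect_equal(ms, 5.211, tolerance = 1e-12)
  expect_equal(M[1], (30 - ms) / ms, tolerance = 1e-12)
  expect_equal(M[1], 82.63 / 17.37, tolerance = 1e-12)
  # m = ms gives M = 0; m = 2 ms gives M = 1
  c2 <- drying_curve(time_h = 0:2, mass_g = c(3 * ms, 2 * ms, ms),
                     temperature = 60, slab_thickness = 0.01,
                     dry_solid_mass = ms)
  expect_equal(resolve_dry_basis(c2), c(2, 1, 0))
})

test_that("slightly negative moistures are clipped with a warning, larger are errors", {
  ms <- 5
  # the constructor resolves moisture once to validate, so it warns too
  expect_warning(
    c_small <- drying_curve(time_h = 0:2, mass_g = c(10, 6, ms * 0.99),
                            temperature = 60, slab_thickness = 0.01,
                            dry_solid_mass = ms),
    "clipped")
  expect_warning(M <- resolve_dry_basis(c_small), "clipped")
  expect_equal(M[3], 0)
  expect_error(
    drying_curve(time_h = 0:2, mass_g = c(10, 6, ms * 0.9), temperature = 60,
                 slab_thickness = 0.01, dry_solid_mass = ms),
    "2%")
})

test_that("moisture-ratio series normalizes to 1 at t = 0 and tracks the data", {
  curve <- drying_curve(time_h = 0:3, mass_g = c(30, 20, 12, 7),
                        temperature = 60, slab_thickness = 0.01,
                        initial_wet_basis = 82.63)
  s <- moisture_ratio_series(curve)
  expect_s3_class(s, "mr_series")
  expect_identical(s$mr[1], 1)
  expect_true(all(diff(s$mr) < 0))
  # printed study endpoints: 82.63 % initial, 6.42 % final wet basis
  mr_final <- wet_to_dry_basis(6.42) / wet_to_dry_basis(82.63)
  expect_equal(mr_final, 0.014, tolerance = 0.001 / 0.014)
  # constant-mass curve: MR identically 1
  flat <- drying_curve(time_h = 0:2, moisture_db = c(2, 2, 2), temperature = 60,
                       slab_thickness = 0.01)
  expect_equal(moisture_ratio_series(flat)$mr, c(1, 1, 1))
  # Me equal to the final moisture drives the final MR to 0
  cme <- drying_curve(time_h = 0:2, moisture_db = c(2, 1, 0.5), temperature = 60,
                      slab_thickness = 0.01, equilibrium_moisture = 0.5)
  expect_equal(moisture_ratio_series(cme)$mr[3], 0)
})

test_that("MR is invariant under rescaling all masses", {
  mass <- c(30, 20, 12, 7)
  a <- drying_curve(time_h = 0:3, mass_g = mass, temperature = 60,
                    slab_thickness = 0.01, initial_wet_basis = 82.63)
  b <- drying_curve(time_h = 0:3, mass_g = mass * 3.7, temperature = 60,
                    slab_thickness = 0.01, initial_wet_basis = 82.63)
  expect_equal(moisture_ratio_series(a)$mr, moisture_ratio_series(b)$mr,
               tolerance = 1e-12)
})

test_that("curve invariants are enforced", {
  expect_error(drying_curve(time_h = c(0, 2, 1), mass_g = c(30, 20, 10),
                            temperature = 60, slab_thickness = 0.01,
                            initial_wet_basis = 80), "increasing")
  expect_error(drying_curve(time_h = 1:3, mass_g = c(30, 20, 10),
                            temperature = 60, slab_thickness = 0.01,
                            initial_wet_basis = 80), "time 0")
  expect_error(drying_curve(time_h = 0:2, mass_g = c(30, 20, 10),
                            temperature = 60, slab_thickness = 0.01),
               "initial_wet_basis")
  expect_error(drying_curve(time_h = 0:2, moisture_db = c(2, 1, 0.5),
                            temperature = 60, slab_thickness = 0.01,
                            equilibrium_moisture = 3), "equilibrium")
  expect_error(mr_series(0:2 * 3600, c(0.9, 0.5, 0.2), 60, 0.01), "equal 1")
})
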