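# material_props module: EN-norm calculators, unit discipline, flammability

test_that("compression stress at 10% strain follows the printed formulas", {
  # linear F = 20 X, A0 = 10000 mm2, d0 = 100 mm, no preload re-zeroing
  X <- seq(0, 15, by = 0.1)
  cv <- stress_strain_curve(X, 20 * X, A0_mm2 = 1e4, d0_mm = 100, preload_N = 0)
  res <- compute_compression(cv)
  expect_equal(qty_value(res$sigma10_kPa), 20, tolerance = 1e-9)

  # zero force everywhere -> zero stress
  cv0 <- stress_strain_curve(X, rep(0, length(X)), 1e4, 100, preload_N = 0)
  expect_equal(qty_value(compute_compression(cv0)$sigma10_kPa), 0)

  # with a preload, the origin moves to the preload crossing
  cvp <- stress_strain_curve(X, 20 * X, 1e4, 100, preload_N = 20)
  expect_equal(qty_value(compute_compression(cvp)$sigma10_kPa), 20, tolerance = 1e-9)

  # curve ending before 10% strain is an error
  short <- stress_strain_curve(seq(0, 5, 0.1), 20 * seq(0, 5, 0.1), 1e4, 100,
                               preload_N = 0)
  expect_error(compute_compression(short), class = "mycomat_insufficient_range")
})

test_that("sigma10 interpolation is grid-stable below 0.1%", {
  coarse <- synth_compression_curve(78.4, n_points = 51L, seed = 1)
  fine <- synth_compression_curve(78.4, n_points = 2001L, seed = 1)
  s1 <- qty_value(compute_compression(coarse)$sigma10_kPa)
  s2 <- qty_value(compute_compression(fine)$sigma10_kPa)
  expect_lt(abs(s1 / s2 - 1), 0.001)
})

test_that("board geometry follows a = 20 t_N + 50 and l1 = 20 t_N", {
  expect_equal(board_geometry(5)$a, 150)
  g10 <- board_geometry(10)
  expect_equal(g10$a, 250); expect_equal(g10$l1, 200)
  expect_equal(board_geometry(0)$a, 50)
  expect_error(board_geometry(-1), class = "mycomat_config")
})

test_that("flexural strength and modulus match hand-computed oracles", {
  g <- board_geometry(10) # l1 = 200, b = 50, t = 10
  rec <- bending_record(c(0, 1, 2, 2.1), c(0, 50, 100, 0), g)
  expect_equal(qty_value(flexural_strength(rec)), 6.0, tolerance = 1e-9)

  rec0 <- bending_record(c(0, 1, 2), c(0, 0, 0), g)
  expect_equal(qty_value(flexural_strength(rec0)), 0)

  # E_M hand oracle: l1=200, b=50, t=10, (F2-F1)=30, (a2-a1)=1
  recE <- bending_record(c(0, 1, 2, 3, 4), c(0, 25, 50, 75, 100), g)
  # F1 = 10, F2 = 40 -> a1 = 0.4, a2 = 1.6; (F2-F1)/(a2-a1) = 25
  expect_equal(qty_value(modulus_of_elasticity(recE)),
               200^3 * 30 / (4 * 50 * 10^3 * 1.2), tolerance = 1e-9)
  expect_equal(qty_value(modulus_of_elasticity(recE)), 1000, tolerance = 1e-9)
})

test_that("scaling laws hold under randomized geometry", {
  set.seed(10)
  for (i in 1:20) {
    tN <- runif(1, 4, 20); b <- runif(1, 30, 80); Fm <- runif(1, 10, 500)
    g <- board_geometry(tN, b = b)
    mk <- function(gg, F) bending_record(c(0, 1, 1.1), c(0, F, 0), gg)
    fm <- qty_value(flexural_strength(mk(g, Fm)))
    # f_m proportional to F_max
    expect_equal(qty_value(flexural_strength(mk(g, 2 * Fm))), 2 * fm,
                 tolerance = 1e-9)
    # f_m proportional to t^-2 at fixed l1, b
    g2 <- g; g2$t <- 2 * g$t
    expect_equal(qty_value(flexural_strength(mk(g2, Fm))), fm / 4,
                 tolerance = 1e-9)
    # E_M proportional to l1^3 and t^-3
    ramp <- function(gg) {
      r <- synth_bending_record(5, gg, stiffness_N_mm = 40, seed = i)
      qty_value(modulus_of_elasticity(r))
    }
    E1 <- ramp(g)
    g3 <- g; g3$l1 <- 2 * g$l1
    expect_equal(ramp(g3), 8 * E1, tolerance = 1e-6)
    g4 <- g; g4$t <- 2 * g$t
    expect_equal(ramp(g4), E1 / 8, tolerance = 1e-6)
    # lambda proportional to d
    l1 <- qty_value(thermal_conductivity(5, 0.04, 0.25, 300, 290))
    l2 <- qty_value(thermal_conductivity(5, 0.08, 0.25, 300, 290))
    expect_equal(l2, 2 * l1, tolerance = 1e-12)
  }
})

test_that("tension, density and soak oracles", {
  expect_equal(qty_value(transverse_tensile_strength(250, 50, 50)), 0.1,
               tolerance = 1e-12)
  expect_equal(qty_value(transverse_tensile_strength(0, 50, 50)), 0)
  expect_equal(qty_value(transverse_tensile_strength(775, 50, 50)), 0.31,
               tolerance = 1e-12)
  expect_error(transverse_tensile_strength(10, 0, 50), class = "mycomat_config")

  expect_equal(qty_value(raw_density(30, 50, 50, 10)), 1200, tolerance = 1e-12)
  expect_equal(qty_value(raw_density(0, 50, 50, 10)), 0)
  expect_equal(qty_value(raw_density(16.65, 50, 50, 10)), 666, tolerance = 1e-12)
  expect_error(raw_density(10, 50, 50, 0), class = "mycomat_config")

  sm <- soak_metrics(10, 15, 20, 20)
  expect_equal(qty_value(sm$G_t_pct), 50, tolerance = 1e-12)
  expect_equal(qty_value(sm$W_t_pct), 0)
  expect_equal(qty_value(soak_metrics(10, 12, 10, 60)$W_t_pct), 500,
               tolerance = 1e-12)
  expect_error(soak_metrics(0, 1, 1, 1), class = "mycomat_config")
})

test_that("thermal conductivity oracle and degenerate gradient", {
  expect_equal(qty_value(thermal_conductivity(9, 0.05, 0.25, 293.15, 283.15)),
               0.18, tolerance = 1e-12)
  expect_equal(qty_value(thermal_conductivity(0, 0.05, 0.25, 300, 290)), 0)
  expect_error(thermal_conductivity(5, 0.05, 0.25, 300, 300),
               class = "mycomat_zero_gradient")
})

test_that("vapour chain satisfies its algebraic identities", {
  s <- synth_vapour_series(8.22, 0.025, 2390, 0.05, n_points = 12,
                           noise_sd_g = 0, seed = 1)
  vc <- vapour_coefficients(s)
  g <- qty_value(vc$g_g_per_m2h); W <- qty_value(vc$W_mg_per_m2hPa)
  delta <- qty_value(vc$delta_mg_per_mhPa)
  # g = W * dp and delta = W * d to 1e-12 relative
  expect_equal(g, W / 1000 * 2390, tolerance = 1e-12)
  expect_equal(delta, W * 0.05, tolerance = 1e-12)
  expect_equal(vc$mu, 0.72 / delta, tolerance = 1e-12)
  # alternative air conductivity reproduces the lower resistance value
  vc2 <- vapour_coefficients(s, delta_air = 0.707)
  expect_equal(vc2$mu, 0.707 / delta, tolerance = 1e-12)
  # condition labels carry the standard pressure differences
  sC <- vapour_series(0:5, 100 + 0:5, A_m2 = 0.02, d_m = 0.05, condition = "C")
  expect_identical(sC$delta_p_Pa, 1210)
  expect_error(vapour_series(0:5, 100 + 0:5, 0.02, delta_p_Pa = 999, d_m = 0.05,
                             condition = "B"), class = "mycomat_config")
  # non-monotone garbage: no steady state
  set.seed(4)
  bad <- vapour_series(0:9, rnorm(10, 100, 5), 0.02, 2390, 0.05)
  expect_error(vapour_coefficients(bad), class = "mycomat_no_steady_state")
})

test_that("steady-state detection uses the longest trailing window", {
  # pronounced drying transient first (mass falling), then a clean uptake line
  t <- 0:19
  m <- c(105, 103, 102, 101.5, 101.2, 101.2 + 0.5 * (5:19 - 4))
  s <- vapour_series(t, m, A_m2 = 0.02, delta_p_Pa = 2390, d_m = 0.05)
  vc <- vapour_coefficients(s)
  expect_lte(vc$steady_state_points, 16L)
  expect_gte(vc$steady_state_points, 3L)
  expect_equal(qty_value(vc$G_g_per_h), 0.5, tolerance = 0.01)
})

test_that("unit tags forbid silent mixing", {
  a <- qty(1, "kPa"); b <- qty(2, "kPa"); c <- qty(3, "N mm-2")
  expect_equal(qty_value(a + b), 3)
  expect_error(a + c, class = "mycomat_unit_mismatch")
  expect_error(a < c, class = "mycomat_unit_mismatch")
  expect_true(a < b)
  prod <- qty(2, "m") * qty(3, "m")
  expect_equal(qty_value(prod), 6)
})

test_that("flammability rule set reproduces the observed classes", {
  expect_identical(
    classify_flammability(flammability_observation(120, FALSE, FALSE, "s2")),
    "B1-s2-d0")
  over <- classify_flammability(flammability_observation(200, FALSE, FALSE, "s2"))
  expect_identical(as.character(over), "unclassified")
  expect_match(attr(over, "reasons"), "150 mm")
  expect_identical(
    classify_flammability(flammability_observation(50, TRUE, FALSE, "s2")), "E")
  expect_identical(
    classify_flammability(flammability_observation(50, FALSE, FALSE, "s1",
                                                   flaming_time_s = 15)), "E")
  drop <- classify_flammability(flammability_observation(50, FALSE, TRUE, "s3"))
  expect_identical(as.character(drop), "unclassified")
  expect_error(flammability_observation(NA, FALSE, FALSE), class = "mycomat_config")
  expect_error(flammability_observation(100, FALSE, FALSE, smoke_class = "s9"),
               class = "mycomat_config")
})
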