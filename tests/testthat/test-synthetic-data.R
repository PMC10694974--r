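# synthetic_data module: phantom generators and synthetic test records

test_that("phantom config validation catches bad worlds", {
  expect_error(phantom_config(shape = c(0, 10, 10)), class = "mycomat_config")
  expect_error(phantom_config(target_solid_fraction = 0), class = "mycomat_config")
  expect_error(phantom_config(class_means = c(100, 100, 220)), class = "mycomat_config")
  expect_error(phantom_config(noise_sd = -1), class = "mycomat_config")
})

test_that("shive phantom handles degenerate porosity requests", {
  cfg <- phantom_config(shape = c(32L, 32L, 32L), target_solid_fraction = 1)
  truth <- generate_shive_phantom(cfg, 1)
  expect_equal(truth$true_solid_fraction, 1.0)
  expect_true(all(truth$labels[truth$apparent_shive_mask] == 2L))

  cfg0 <- phantom_config(shape = c(32L, 32L, 32L),
                         vessel_radii_um = c(small = 0, large = 0))
  expect_equal(generate_shive_phantom(cfg0, 1)$true_solid_fraction, 1.0)
})

test_that("shive phantom reaches the target solid fraction (brute-force count)", {
  cfg <- phantom_config(shape = c(200L, 200L, 200L), target_solid_fraction = 0.25)
  truth <- generate_shive_phantom(cfg, 1)
  # independent voxel-count oracle over the raw arrays
  eps_brute <- sum(truth$labels == 2L) / sum(truth$apparent_shive_mask)
  expect_gte(eps_brute, 0.23)
  expect_lte(eps_brute, 0.27)
  expect_equal(truth$true_solid_fraction, eps_brute)
  # apparent mask is the slab box: solid ⊆ apparent
  expect_true(all(!(truth$labels == 2L) | truth$apparent_shive_mask))
})

test_that("phantom truth satisfies the conservation and length invariants", {
  w <- small_phantom(5)
  truth <- w$truth
  n_lab <- sum(truth$labels == 0L) + sum(truth$labels == 1L) + sum(truth$labels == 2L)
  expect_identical(n_lab, length(truth$labels))
  # exact length bookkeeping: every step contributed one step length
  expect_equal(truth$true_total_length_um,
               length(truth$step_distances_um) * truth$step_length_um,
               tolerance = 1e-9)
  # branch points and tips lie on the recorded centerline
  skm <- array(FALSE, dim(truth$labels))
  skm[truth$skeleton_voxels] <- TRUE
  expect_true(all(skm[truth$branch_points]))
  expect_true(all(skm[truth$tips]))
})

test_that("growth is deterministic per seed and empty for zero budget", {
  radii <- c(small = 8, large = 12)
  counts <- c(small = Inf, large = 2)
  cfg <- phantom_config(shape = c(64L, 64L, 64L), hypha_length_budget_um = 0,
                        vessel_radii_um = radii, vessel_max_counts = counts)
  base <- generate_shive_phantom(cfg, 2)
  t0 <- grow_hyphae_phantom(base, cfg)
  expect_identical(nrow(t0$skeleton_voxels), 0L)
  expect_identical(nrow(t0$branch_points), 0L)
  expect_identical(t0$true_total_length_um, 0)

  cfg2 <- phantom_config(shape = c(64L, 64L, 64L), hypha_length_budget_um = 3000,
                         vessel_radii_um = radii, vessel_max_counts = counts)
  a <- grow_hyphae_phantom(generate_shive_phantom(cfg2, 3), cfg2, seed = 9)
  b <- grow_hyphae_phantom(generate_shive_phantom(cfg2, 3), cfg2, seed = 9)
  expect_identical(a$labels, b$labels)
  expect_identical(a$skeleton_voxels, b$skeleton_voxels)
  expect_identical(a$branch_distances_um, b$branch_distances_um)
})

test_that("constant branching rate gives a flat exact shell profile", {
  # decay = Inf: the per-shell frequency is Bernoulli(rate * step) per step
  # in every shell; each seed's shell frequencies must agree within 3
  # Monte-Carlo standard errors across seeds
  freqs <- list()
  for (s in 1:20) {
    cfg <- phantom_config(shape = c(96L, 96L, 320L), shive_slab_fraction = 0.2,
                          branch_rate_decay_um = Inf,
                          hypha_length_budget_um = 2e4,
                          n_seed_hyphae = 200L, seed = s)
    tr <- grow_hyphae_phantom(generate_shive_phantom(cfg, s), cfg)
    p <- truth_shell_profile(tr)
    freqs[[s]] <- p$frequency_per_um[1:3]
  }
  fm <- do.call(rbind, freqs)
  means <- colMeans(fm)
  ses <- apply(fm, 2, sd) / sqrt(nrow(fm))
  grand <- mean(fm)
  for (k in 1:3) expect_lt(abs(means[k] - grand), 3 * ses[k] + 1e-12)
})

test_that("finite decay length is recovered from the generated truth", {
  counts <- 0; lens <- 0
  for (s in 1:10) {
    cfg <- phantom_config(shape = c(96L, 96L, 448L), shive_slab_fraction = 0.16,
                          branch_rate_decay_um = 100,
                          hypha_length_budget_um = 5e4,
                          n_seed_hyphae = 250L, seed = s)
    tr <- grow_hyphae_phantom(generate_shive_phantom(cfg, s), cfg)
    p <- truth_shell_profile(tr)
    k <- seq_len(min(4, nrow(p)))
    counts <- counts + p$branch_count[k]
    lens <- lens + p$length_um[k]
  }
  prof <- counts / lens
  mid <- (seq_along(prof) - 0.5) * 50
  fit <- lm(log(prof) ~ mid)
  decay <- -1 / coef(fit)[["mid"]]
  expect_gt(decay, 75)
  expect_lt(decay, 125)
})

test_that("rendering is exact without noise and deterministic with it", {
  w <- small_phantom(4, shape = c(48L, 48L, 48L))
  cfg0 <- w$cfg; cfg0$noise_sd <- 0
  v0 <- render_grayscale(w$truth, cfg0)
  expect_identical(sort(unique(as.vector(v0$values))), c(60, 140, 220))
  expect_true(all(v0$values[w$truth$labels == 1L] == 140))

  v1 <- render_grayscale(w$truth, w$cfg, seed = 42)
  v2 <- render_grayscale(w$truth, w$cfg, seed = 42)
  expect_identical(v1$values, v2$values)
  expect_true(all(v1$values >= 0 & v1$values <= 255))

  bad <- w$cfg; bad$class_means <- c(220, 140, 60)
  expect_error(render_grayscale(w$truth, bad), class = "mycomat_config")
})

test_that("synthetic compression curves obey their closed form", {
  cv <- synth_compression_curve(78.4, seed = 1)
  res <- compute_compression(cv)
  expect_equal(qty_value(res$sigma10_kPa), compression_model_stress(0.1, 78.4),
               tolerance = 1e-6)
  # zero strain -> zero stress after preload-offset removal
  X0 <- 0.5
  strains <- (cv$displacement_mm - X0) / cv$d0_mm
  i0 <- which(abs(strains) < 1e-12)
  expect_equal(cv$force_N[i0] - cv$preload_N, 0)
  # density monotonicity of sigma10
  r1 <- compute_compression(synth_compression_curve(60, seed = 2))
  r2 <- compute_compression(synth_compression_curve(120, seed = 2))
  expect_lte(qty_value(r1$sigma10_kPa), qty_value(r2$sigma10_kPa))
  # stress monotone non-decreasing even with noise
  cvn <- synth_compression_curve(78.4, seed = 3, noise_sd = 0.05)
  expect_true(all(diff(cvn$force_N) >= 0))
  expect_error(synth_compression_curve(-1), class = "mycomat_config")
})

test_that("synthetic vapour series carry the encoded transmittance", {
  s <- synth_vapour_series(W_true = 8.22, A_m2 = 0.025, delta_p_Pa = 2390,
                           d_m = 0.05, n_points = 10, noise_sd_g = 0, seed = 1)
  fit <- lm(s$mass_g ~ s$time_h)
  expect_equal(coef(fit)[[2]], 8.22e-3 * 0.025 * 2390, tolerance = 1e-9)
  expect_true(all(diff(s$time_h) > 0))
  expect_identical(s$delta_p_Pa, 2390)
  # noisy recovery within 5% over 20 seeds
  recov <- vapply(1:20, function(sd) {
    ss <- synth_vapour_series(8.22, 0.025, 2390, 0.05, n_points = 50,
                              noise_sd_g = 0.05, seed = sd)
    qty_value(vapour_coefficients(ss)$W_mg_per_m2hPa)
  }, numeric(1))
  expect_true(all(abs(recov / 8.22 - 1) < 0.05))
  expect_error(synth_vapour_series(8.22, 0.025, 2390, 0.05, n_points = 2),
               class = "mycomat_config")
})

test_that("synthetic bending records invert exactly", {
  geom <- board_geometry(10)
  rec <- synth_bending_record(5, geom, stiffness_N_mm = 80, seed = 1)
  expect_equal(qty_value(flexural_strength(rec)), 5, tolerance = 1e-12)
  expect_equal(qty_value(modulus_of_elasticity(rec)),
               80 * geom$l1^3 / (4 * geom$b * geom$t^3), tolerance = 1e-9)
  # force drops to zero after the break
  expect_identical(tail(rec$force_N, 1), 0)
  # f_m = 0 -> F_max = 0
  rec0 <- synth_bending_record(0, geom, stiffness_N_mm = 80)
  expect_equal(max(rec0$force_N), 0)
  # determinism
  a <- synth_bending_record(5, geom, seed = 7, noise_sd = 0.02)
  b <- synth_bending_record(5, geom, seed = 7, noise_sd = 0.02)
  expect_identical(a$force_N, b$force_N)
  expect_error(synth_bending_record(5, geom, stiffness_N_mm = 0),
               class = "mycomat_config")
})
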