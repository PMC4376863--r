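test_that("noiseless synthetic loops lie on the model curve before unfolding", {
  ds <- cached_run("hyst_noiseless", synthesize_hysteresis(
    n_samples = 120, noise_sd = 0, seed = 3))
  truth <- attr(ds, "truth")
  expect_equal(truth$pevk_modulus, 150)
  stretch <- ds[ds$phase == "stretch", ]
  pre <- stretch[stretch$sarcomere_um < 3.0, ]   # safely before onset
  model <- passive_stress_curve(pre$sarcomere_um, default_iso, 0L, 500)
  expect_equal(pre$stress_nN_um2, model, tolerance = 1e-8)
  # determinism
  ds2 <- synthesize_hysteresis(n_samples = 120, noise_sd = 0, seed = 3)
  expect_identical(as.data.frame(ds), as.data.frame(ds2))
})

test_that("region labels partition the loop and locate the onset", {
  ds <- cached_run("hyst_noiseless", synthesize_hysteresis(
    n_samples = 120, noise_sd = 0, seed = 3))
  dsc <- classify_regions(ds)
  expect_true(all(dsc$region %in% 1:4))
  expect_true(all(dsc$region[dsc$phase == "stretch"] %in% 1:2))
  expect_true(all(dsc$region[dsc$phase == "shorten"] %in% 3:4))
  # detected boundary within 2 samples of the first unfolding event
  stretch <- which(dsc$phase == "stretch")
  cut <- max(which(dsc$region[stretch] == 1))
  # ground truth: the first clear force drop while stretching (noiseless
  # data rise monotonically between unfolding events)
  st_stress <- ds$stress_nN_um2[stretch]
  first_event <- which(diff(st_stress) < -0.01 * st_stress[-1])[1]
  expect_lte(abs(cut - first_event), 2)
})

test_that("a loop without unfolding has an empty region 2", {
  ds <- synthesize_hysteresis(n_samples = 80, noise_sd = 0, seed = 5,
                              stretch_to_um = 3.0)
  expect_equal(max(attr(ds, "truth")$n_unfolded_final), 0)
  dsc <- classify_regions(ds)
  expect_equal(sum(dsc$region == 2), 0)
})

test_that("region-1 fit recovers the generating parameters without noise", {
  ds <- cached_run("hyst_noiseless", synthesize_hysteresis(
    n_samples = 120, noise_sd = 0, seed = 3))
  dsc <- classify_regions(ds)
  r1 <- fit_region1(dsc)
  expect_true(r1$converged)
  expect_equal(r1$folded_pl, 10, tolerance = 0.01)
  expect_equal(r1$pevk_pl, 1, tolerance = 0.01)
  expect_equal(r1$pevk_modulus, 150, tolerance = 0.01)
  # optimality: the fit is at least as good as the truth
  truth_iso <- titin_isoform()
  sel <- dsc$region == 1 &
    dsc$stress_nN_um2 > 0.005 * max(dsc$stress_nN_um2[dsc$region == 1])
  s0 <- 0.02 * max(dsc$stress_nN_um2[sel])
  truth_cost <- sum(((passive_stress_curve(dsc$sarcomere_um[sel], truth_iso,
                                           0L, 500) -
                        dsc$stress_nN_um2[sel]) /
                       (dsc$stress_nN_um2[sel] + s0))^2)
  expect_lte(r1$residual_norm^2, truth_cost + 1e-8)
})

test_that("region-4 fit recovers the unfolded count exactly", {
  # direct region-4 data from the chain model at a known composition
  iso <- titin_isoform()
  sl <- seq(3.4, 2.6, by = -0.025)
  stress <- passive_stress_curve(sl, iso, 20L, 500)
  ds <- data.frame(
    sarcomere_um = c(2.5, 2.6, sl),
    stress_nN_um2 = c(passive_stress_curve(c(2.5, 2.6), iso, 0L, 500),
                      stress),
    phase = c("stretch", "stretch", rep("shorten", length(sl))),
    region = c(1L, 1L, rep(4L, length(sl))))
  r1 <- structure(list(folded_pl = 10, pevk_pl = 1, pevk_modulus = 150,
                       iso = iso, residual_norm = 0, converged = TRUE,
                       n_samples = 2,
                       se = c(folded_pl = 0, pevk_pl = 0,
                              pevk_modulus = 0)),
                  class = "calibration_result")
  r4 <- fit_region4(ds, r1)
  expect_identical(r4$n_unfolded, 20L)
  expect_equal(r4$unfolded_pl, 0.65, tolerance = 0.01)
  # exhaustive scan over every integer candidate, minimum as reported
  expect_equal(r4$scan_objective$n_unfolded, 0:50)
  expect_equal(which.min(r4$scan_objective$objective) - 1L, 20L)
})

test_that("zero-unfolding data recover a zero count", {
  iso <- titin_isoform()
  sl <- seq(3.2, 2.6, by = -0.025)
  ds <- data.frame(sarcomere_um = sl,
                   stress_nN_um2 = passive_stress_curve(sl, iso, 0L, 500),
                   phase = "shorten", region = 4L)
  r1 <- structure(list(folded_pl = 10, pevk_pl = 1, pevk_modulus = 150,
                       iso = iso, residual_norm = 0, converged = TRUE,
                       n_samples = 0,
                       se = c(folded_pl = 0, pevk_pl = 0,
                              pevk_modulus = 0)),
                  class = "calibration_result")
  r4 <- fit_region4(ds, r1)
  expect_identical(r4$n_unfolded, 0L)
})

test_that("model residuals are invariant under consistent unit rescaling", {
  # rescale every length by s and the force scale appropriately: the
  # relative residual structure of the chain model is unchanged
  s <- 1e-3   # nm -> um
  iso <- titin_isoform()
  sl <- seq(2.5, 3.2, by = 0.1)
  base <- passive_stress_curve(sl, iso, 5L, 500)
  # lengths scale by s, so forces scale by 1/s (kT fixed): the force-unit
  # parameters K0 and the A-band stiffness must follow (K0/s, k/s^2)
  iso_s <- titin_isoform(folded_pl = 10 * s, unfolded_pl = 0.65 * s,
                         pevk_pl = 1 * s, pevk_modulus = 150 / s,
                         folded_contour = 4.5 * s, unfolding_gain = 26 * s,
                         residue_contour = 0.36 * s,
                         distal_end_filament_length = 117 * s,
                         half_a_band_length = 800 * s,
                         a_band_stiffness = 1e4 / s^2)
  f_scaled <- vapply(sl * 500 * s, function(h)
    chain_force(h, iso_s, titin_state(n_unfolded = 5))$common_force,
    numeric(1))
  # forces scale by 1/s when every length (including pl) scales by s
  expect_equal(f_scaled * s * 0.5, base, tolerance = 1e-6)
})

test_that("fit errors are informative", {
  ds <- data.frame(sarcomere_um = c(2.4, 2.5), stress_nN_um2 = c(1, 2),
                   phase = c("stretch", "stretch"))
  expect_error(fit_region1(ds), "classified")
  dsc <- ds; dsc$region <- c(1L, 1L)
  expect_error(fit_region1(dsc), "region-1 samples")
})
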