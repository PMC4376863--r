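test_that("Bell rates obey the closed-form anchors", {
  up <- default_unfold
  kT <- 1.380649e-2 * up$temperature
  expect_equal(unfolding_rate(0, 1, up), up$k0)
  for (i in c(1L, 25L, 50L)) {
    w <- up$widths[i]
    expect_equal(unfolding_rate(kT / w, i, up), up$k0 * exp(1),
                 tolerance = 1e-12)
    expect_equal(unfolding_rate(2 * kT / w, i, up), up$k0 * exp(2),
                 tolerance = 1e-12)
  }
  expect_error(unfolding_rate(10, 0, up), "out of range")
  expect_error(unfolding_rate(10, 51, up), "out of range")
  expect_error(unfolding_rate(-1, 1, up), "non-negative")
})

test_that("unfolding hierarchy: later domains unfold more slowly", {
  up <- default_unfold
  r <- unfolding_rate(rep(120, 50), 1:50, up)
  expect_true(all(diff(r) <= 0))
  # calcium narrows the barriers, lowering rates at fixed force
  r_ca <- unfolding_rate(rep(120, 50), 1:50, up, calcium = TRUE)
  expect_true(all(r_ca < r))
})

test_that("mc_step respects the no-refolding and asymptotic limits", {
  up <- default_unfold
  st <- titin_state(n_unfolded = 5)
  set.seed(1)
  # negligible hazard: state unchanged
  out <- mc_step(st, 0, 1e-5, up)
  expect_identical(out$n_unfolded, 5L)
  # overwhelming hazard: everything unfolds
  out <- mc_step(st, 4000, 10, up)
  expect_identical(out$n_unfolded, 50L)
})

test_that("Monte-Carlo unfolding matches the binomial expectation", {
  up <- unfolding_params(k0 = 1e-4, width_max = 0.25, width_min = 0.15,
                         n_domains = 50L)
  force <- 140; dt <- 0.05
  kT <- 1.380649e-2 * up$temperature
  p_i <- 1 - exp(-up$k0 * exp(force * up$widths / kT) * dt)
  mu <- sum(p_i)
  sd1 <- sqrt(sum(p_i * (1 - p_i)))
  n_rep <- 10000L
  set.seed(7)
  counts <- mc_step_counts(integer(n_rep), rep(force, n_rep), dt, up)
  m <- mean(counts)
  expect_lt(abs(m - mu), 3 * sd1 / sqrt(n_rep))
  # single-strand stepper agrees too (smaller replicate budget)
  set.seed(8)
  singles <- vapply(1:2000, function(i)
    mc_step(titin_state(), force, dt, up)$n_unfolded, integer(1))
  expect_lt(abs(mean(singles) - mu), 4 * sd1 / sqrt(2000))
})

test_that("ensemble traces are seed-deterministic", {
  proto <- protocol(phase_set_length(2.4), phase_ramp(3.2, 400),
                    name = "quick")
  cfg <- ensemble_config(n_strands = 30, seed = 5, dt = 1e-3)
  tr1 <- ensemble_trace(proto, default_iso, default_unfold, cfg)
  tr2 <- ensemble_trace(proto, default_iso, default_unfold, cfg)
  expect_identical(tr1$titin_nN_um2, tr2$titin_nN_um2)
  expect_identical(tr1$mean_unfolded, tr2$mean_unfolded)
  tr3 <- ensemble_trace(proto, default_iso, default_unfold, cfg, seed = 6)
  expect_false(identical(tr3$mean_unfolded, tr2$mean_unfolded))
})

test_that("unfolded count is non-decreasing along every trajectory", {
  proto <- protocol(phase_set_length(2.4), phase_ramp(3.6, 300),
                    phase_ramp(2.8, 300), name = "updown")
  cfg <- ensemble_config(n_strands = 40, seed = 9, dt = 1e-3)
  tr <- ensemble_trace(proto, default_iso, default_unfold, cfg)
  expect_true(all(diff(tr$mean_unfolded) >= -1e-12))
  expect_gt(max(tr$mean_unfolded), 0)  # the stretch does reach unfolding
})

test_that("below slack the ensemble trace is zero with zero spread", {
  proto <- protocol(phase_set_length(1.6), phase_hold(0.5), name = "slack")
  cfg <- ensemble_config(n_strands = 20, seed = 2, dt = 1e-3)
  tr <- ensemble_trace(proto, default_iso, default_unfold, cfg)
  expect_true(all(tr$titin_nN_um2 == 0))
  expect_true(all(tr$titin_sd_nN_um2 == 0))
})

test_that("no unfolding in range implies identical strands (sd zero)", {
  proto <- protocol(phase_set_length(2.4), phase_ramp(2.8, 400),
                    name = "low")
  cfg <- ensemble_config(n_strands = 25, seed = 3, dt = 1e-3)
  tr <- ensemble_trace(proto, default_iso, default_unfold, cfg)
  expect_true(all(tr$mean_unfolded == 0))
  expect_true(all(tr$titin_sd_nN_um2 == 0))
})

test_that("passive stretch-shorten cycles show unfolding hysteresis", {
  ds <- cached_run("hyst_noiseless", synthesize_hysteresis(
    n_samples = 120, noise_sd = 0, seed = 3))
  stretch <- ds[ds$phase == "stretch", ]
  shorten <- ds[ds$phase == "shorten", ]
  # compare limbs on a common length grid within the loop
  grid <- seq(2.7, 3.5, by = 0.1)
  up <- approx(stretch$sarcomere_um, stretch$stress_nN_um2, grid)$y
  dn <- approx(shorten$sarcomere_um, shorten$stress_nN_um2, grid)$y
  expect_true(all(dn < up))
})
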