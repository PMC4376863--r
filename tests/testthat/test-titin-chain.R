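test_that("slack length marks the onset of chain force", {
  iso <- default_iso
  s0 <- slack_length(iso)
  expect_equal(chain_force(0.999 * s0, iso)$common_force, 0)
  expect_gt(chain_force(1.001 * s0, iso)$common_force, 0)
  # under the infinitesimal-probe-force rest convention the slack length is
  # essentially the rigid-compartment length: unfolding changes it only at
  # the sub-nanometre probe-extension level (folded domains, with the larger
  # pl*cl product, extend slightly more at the probe force)
  s_unf <- vapply(c(0L, 5L, 20L, 50L), function(nu)
    slack_length(iso, titin_state(n_unfolded = nu)), numeric(1))
  expect_true(all(abs(s_unf - s0) < 1e-2))
  # rigid compartments dominate the rest length
  expect_equal(s0, iso$half_a_band_length + iso$distal_end_filament_length,
               tolerance = 1e-3)
})

test_that("chain solution satisfies the equal-force and length-sum laws", {
  iso <- default_iso
  set.seed(21)
  for (i in 1:25) {
    nu <- sample(0:50, 1)
    hsl <- runif(1, 1000, 1600)
    sol <- chain_force(hsl, iso, titin_state(n_unfolded = nu))
    if (sol$slack) next
    total <- sol$proximal_total + sol$pevk + sol$distal + sol$a_band
    expect_equal(total, hsl, tolerance = 1e-6)
    # every compartment reproduces the common force through its force law
    f <- sol$common_force
    expect_equal(wlc_force(sol$folded_ig_each, iso$folded_ig), f,
                 tolerance = 1e-8 * (1 + f))
    expect_equal(ewlc_force(sol$pevk, iso$pevk), f,
                 tolerance = 1e-6 * (1 + f))
  }
})

test_that("chain force matches the independent bisection oracle", {
  iso <- default_iso
  f_pkg <- chain_force(1500, iso, titin_state(n_unfolded = 10))$common_force
  expect_equal(f_pkg, chain_force_oracle(1500, iso, 10L), tolerance = 1e-8)
  # monotone in length, non-increasing in unfolded count
  hs <- seq(1000, 1700, by = 100)
  ff <- vapply(hs, function(h) chain_force(h, iso)$common_force, numeric(1))
  expect_true(all(diff(ff) > 0))
  f_nu <- vapply(c(0L, 10L, 25L, 40L), function(nu)
    chain_force(1500, iso, titin_state(n_unfolded = nu))$common_force,
    numeric(1))
  expect_true(all(diff(f_nu) <= 0))
})

test_that("high-calcium parameter set raises passive force by 25%", {
  iso <- default_iso
  hi <- apply_calcium(iso)
  ratio <- chain_force(1700, hi)$common_force /
    chain_force(1700, iso)$common_force
  expect_equal(ratio, 1.25, tolerance = 0.005 / 1.25)
  # idempotent, invertible
  expect_identical(apply_calcium(hi), hi)
  lo <- remove_calcium(hi)
  expect_equal(lo$pevk$persistence_length, iso$pevk$persistence_length,
               tolerance = 1e-12)
  # uniformly increased force at every length above slack
  for (h in seq(950, 2000, by = 150)) {
    fl <- chain_force(h, iso)$common_force
    if (fl <= 0) next
    expect_gt(chain_force(h, hi)$common_force / fl, 1)
  }
})

test_that("actin-titin binding freezes the proximal compartment", {
  iso <- apply_calcium(default_iso)
  st <- titin_state(n_unfolded = 3)
  sol <- chain_force(1400, iso, st)
  bound <- bind_to_actin(st, sol, active = TRUE)
  expect_true(bound$actin_bound)
  expect_equal(bound$frozen_proximal_length, sol$proximal_total)
  # binding itself does not generate force
  f_after <- chain_force(1400, iso, bound)$common_force
  expect_equal(f_after, sol$common_force,
               tolerance = 1e-9 * (1 + sol$common_force))
  # the bound chain is strictly stiffer above the binding length
  dh <- 1
  k_bound <- (chain_force(1400 + dh, iso, bound)$common_force - f_after) / dh
  k_free <- (chain_force(1400 + dh, iso, st)$common_force -
               sol$common_force) / dh
  expect_gt(k_bound, k_free)
  # and carries more force at every longer length
  for (h in c(1450, 1550, 1700)) {
    expect_gt(chain_force(h, iso, bound)$common_force,
              chain_force(h, iso, st)$common_force)
  }
})

test_that("binding respects activation and prior state", {
  sol <- chain_force(1400, default_iso)
  st <- titin_state()
  expect_error(bind_to_actin(st, sol, active = FALSE), "inhibited")
  b <- bind_to_actin(st, sol)
  expect_error(bind_to_actin(b, sol), "already bound")
})

test_that("proximal length at binding reflects the stretch history", {
  iso <- default_iso
  frozen_long <- chain_force(1700, iso)$proximal_total
  frozen_short <- chain_force(1200, iso)$proximal_total
  expect_gt(frozen_long, frozen_short)
})

test_that("actin compliance arithmetic justifies the rigid-actin assumption", {
  expect_equal(actin_extension(1, 1), 20)
  expect_equal(actin_extension(0, 100), 0)
  expect_equal(actin_extension(2, 3), 120)
  expect_error(actin_extension(-1, 1), "non-negative")
})

test_that("isoform constructor enforces structural invariants", {
  expect_error(titin_isoform(n_proximal_ig = 0), "positive")
  iso <- titin_isoform()
  expect_equal(iso$unfolded_ig$contour_length -
                 iso$folded_ig$contour_length, 26)
  expect_equal(iso$pevk$contour_length, 0.36 * 800)
  expect_error(titin_state(actin_bound = TRUE), "frozen_proximal_length")
  expect_error(titin_state(n_unfolded = -1))
})
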