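test_that("canonical registry contains the standard experiments", {
  reg <- canonical_protocols()
  expect_gte(length(reg), 5)
  expect_true(all(c("beyond_overlap_2.4", "beyond_overlap_3.4", "rfe",
                    "fd", "pfe") %in% names(reg)))
  rfe <- canonical_protocols("rfe")
  ramp <- Filter(function(p) p$type == "ramp", rfe$phases)[[1]]
  expect_equal(ramp$speed, 100)
  bo <- canonical_protocols("beyond_overlap_2.4")
  targets <- vapply(Filter(function(p) p$type == "ramp", bo$phases),
                    `[[`, numeric(1), "target_um")
  expect_gt(max(targets), 4.0)
  expect_error(canonical_protocols("nope"), "unknown protocol")
})

test_that("protocol and scenario constructors validate", {
  expect_error(protocol(), "at least one phase")
  expect_error(phase_ramp(3.0, -10))
  expect_error(phase_hold(0))
  expect_error(scenario_flags("bogus"))
  s <- scenario_flags("instantaneous-binding", "immediate-unbind")
  expect_equal(s$calcium_ordering, "instantaneous-binding")
})

test_that("isometric run below titin slack is purely active", {
  proto <- protocol(phase_set_length(1.8), phase_activate(), phase_hold(1),
                    name = "short_iso")
  cfg <- ensemble_config(n_strands = 10, seed = 1, dt = 1e-4)
  tr <- cached_run("short_iso",
                   run_protocol(proto, config = cfg, xb = shared_xb()))
  last <- tail(tr, 1)
  expect_equal(last$titin_nN_um2, 0)
  expect_equal(last$total_nN_um2, last$active_nN_um2)
  expect_equal(last$active_nN_um2,
               150 * overlap_fraction(1.8, shared_xb()$fn),
               tolerance = 1e-3)
})

test_that("total stress is the sum of active and titin components", {
  proto <- protocol(phase_set_length(2.4), phase_activate(), phase_hold(0.3),
                    phase_ramp(2.8, 400), name = "sum")
  cfg <- ensemble_config(n_strands = 10, seed = 4, dt = 2e-4)
  tr <- run_protocol(proto, config = cfg, xb = shared_xb())
  expect_equal(tr$total_nN_um2, tr$active_nN_um2 + tr$titin_nN_um2)
  # length trace matches the protocol: starts at 2.4, ends at 2.8
  expect_equal(tr$sarcomere_um[1], 2.4)
  expect_equal(tail(tr$sarcomere_um, 1), 2.8, tolerance = 1e-6)
})

test_that("passive runs reproduce the deterministic chain force", {
  # no unfolding at these lengths: the ensemble equals a single chain
  proto <- protocol(phase_set_length(2.4), phase_ramp(2.9, 400),
                    name = "passive_check")
  cfg <- ensemble_config(n_strands = 15, seed = 2, dt = 1e-3)
  tr <- run_protocol(proto, config = cfg, variant = "passive",
                     xb = shared_xb())
  idx <- unique(round(seq(1, nrow(tr), length.out = 9)))
  for (i in idx) {
    expected <- chain_force(tr$sarcomere_um[i] * 500,
                            default_iso)$common_force * 500 / 1000
    expect_equal(tr$titin_nN_um2[i], expected, tolerance = 1e-8)
  }
  expect_true(all(tr$active_nN_um2 == 0))
})

test_that("runs are reproducible for a fixed seed", {
  proto <- protocol(phase_set_length(2.4), phase_activate(), phase_hold(0.2),
                    phase_ramp(3.3, 600), name = "det")
  cfg <- ensemble_config(n_strands = 20, seed = 12, dt = 2e-4)
  tr1 <- run_protocol(proto, config = cfg, xb = shared_xb())
  tr2 <- run_protocol(proto, config = cfg, xb = shared_xb())
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
})

test_that("binding requires cross-bridge interaction", {
  proto <- protocol(phase_set_length(2.4),
                    phase_activate(crossbridges = "off"),
                    phase_hold(0.2), phase_ramp(2.6, 400), name = "nobind")
  cfg <- ensemble_config(n_strands = 5, seed = 1, dt = 1e-3)
  tr <- run_protocol(proto, config = cfg, xb = shared_xb())
  ev <- attr(tr, "events")$event
  expect_false(any(grepl("actin-titin binding", ev)))
  expect_true(any(grepl("binding suppressed", ev)))
})

test_that("scenario orderings bind at the expected moments", {
  proto <- protocol(phase_set_length(2.4), phase_activate(), phase_hold(0.3),
                    phase_ramp(2.7, 400), name = "orders")
  cfg <- ensemble_config(n_strands = 5, seed = 1, dt = 1e-3)
  tr_ca <- run_protocol(proto, scenario_flags("instantaneous-calcium"),
                        config = cfg, xb = shared_xb())
  ev <- attr(tr_ca, "events")
  t_bind <- ev$time_s[grepl("actin-titin binding", ev$event)]
  expect_equal(t_bind, 0.3, tolerance = 1e-6)     # at ramp onset
  tr_b <- run_protocol(proto, scenario_flags("instantaneous-binding"),
                       config = cfg, xb = shared_xb())
  evb <- attr(tr_b, "events")
  expect_equal(evb$time_s[grepl("actin-titin binding", evb$event)], 0)
  # binding precedes the calcium event under instantaneous-binding
  expect_lt(which(grepl("binding", evb$event))[1],
            which(grepl("calcium high", evb$event))[1])
})

test_that("rupture stops a beyond-overlap stretch", {
  proto <- protocol(phase_set_length(2.4), phase_activate(), phase_hold(0.2),
                    phase_ramp(6.0, 2000), name = "fastramp")
  cfg <- ensemble_config(n_strands = 5, seed = 1, dt = 1e-4)
  tr <- run_protocol(proto, config = cfg, xb = shared_xb())
  expect_true(attr(tr, "ruptured"))
  expect_lt(tail(tr$sarcomere_um, 1), 6.0)
  expect_true(any(grepl("rupture stop", attr(tr, "events")$event)))
})

test_that("steady-state detection accepts settled and rejects drifting traces", {
  mk <- function(total) {
    structure(data.frame(time_s = seq(0, 2, by = 0.01),
                         sarcomere_um = 3,
                         active_nN_um2 = 0, titin_nN_um2 = total,
                         total_nN_um2 = total,
                         mean_unfolded = 0, titin_sd_nN_um2 = 0),
              class = c("force_trace", "data.frame"))
  }
  flat <- mk(rep(100, 201))
  expect_equal(steady_state_stress(flat), 100)
  drifting <- mk(100 - 0.5 * seq(0, 2, by = 0.01))
  expect_error(steady_state_stress(drifting), "no steady state")
  expect_equal(residual_force_enhancement(flat, flat), 0)
  expect_equal(force_depression(flat, flat), 0)
})

test_that("deactivation with immediate unbinding resets the titin state", {
  # all-reset scenario with no unfolding: post-deactivation force returns
  # to the purely passive value at the same length
  proto <- protocol(phase_set_length(2.4), phase_activate(), phase_hold(0.2),
                    phase_ramp(2.7, 400), phase_hold(0.3),
                    phase_deactivate(0.5), name = "reset")
  cfg <- ensemble_config(n_strands = 5, seed = 6, dt = 5e-4)
  tr <- run_protocol(proto, scenario_flags("instantaneous-calcium",
                                           "immediate-unbind"),
                     config = cfg, xb = shared_xb())
  passive_ref <- chain_force(2.7 * 500, default_iso)$common_force * 0.5
  last <- tail(tr, 1)
  expect_equal(last$titin_nN_um2, passive_ref, tolerance = 1e-6)
  expect_lt(last$active_nN_um2, 0.5)  # cross-bridges have detached
})
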