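test_that("overlap function interpolates the standard geometry", {
  fn <- overlap_fn()
  expect_equal(overlap_fraction(2.4, fn), 1)
  expect_equal(overlap_fraction(2.0, fn), 1)
  expect_equal(overlap_fraction(3.2, fn), 0.5)
  expect_equal(overlap_fraction(4.0, fn), 0)
  expect_equal(overlap_fraction(4.2, fn), 0)
  expect_equal(overlap_fraction(6.0, fn), 0)
  g <- overlap_fraction(seq(0.5, 6, by = 0.05), fn)
  expect_true(all(g >= 0 & g <= 1))
  expect_error(overlap_fn(c(2, 4), c(0.5, 0.2)))  # must end at zero
})

test_that("steady state balances the transition fluxes", {
  xb <- shared_xb()
  ss <- steady_state(xb)
  expect_equal(total_probability(ss), 1, tolerance = 1e-12)
  # pointwise flux balance (residual of the reaction operator)
  r1 <- xb$att * ss$p3 - (xb$f12 + xb$d1) * ss$p1 + xb$g21 * ss$p2
  r2 <- xb$f12 * ss$p1 - (xb$g21 + xb$d2) * ss$p2
  expect_lt(max(abs(r1), abs(r2)), 1e-8)
  # no attachment: all detached
  xb0 <- crossbridge_params(attach_rate = function(x) 0 * x, S = 1)
  ss0 <- steady_state(xb0)
  expect_equal(ss0$p3, 1)
  expect_true(all(ss0$p1 == 0) && all(ss0$p2 == 0))
})

test_that("time stepping is stationary at the steady state", {
  xb <- shared_xb()
  ss <- steady_state(xb)
  st <- ss
  for (i in 1:50) st <- step_pde(st, 0, 1e-4, xb)
  expect_lt(max(abs(st$p1 - ss$p1), abs(st$p2 - ss$p2), abs(st$p3 - ss$p3)),
            1e-8)
})

test_that("long-time integration converges to the algebraic steady state", {
  xb <- shared_xb()
  ss <- steady_state(xb)
  st <- detached_state(xb)
  for (i in 1:20000) st <- step_pde(st, 0, 1e-4, xb)
  expect_equal(active_force(st, 2.4, xb), active_force(ss, 2.4, xb),
               tolerance = 1e-6)
  expect_lt(max(abs(st$p2 - ss$p2)), 1e-6)
})

test_that("pure advection translates the densities and conserves mass", {
  xb <- crossbridge_params(attach_rate = function(x) 0 * x,
                           forward_rate = function(x) 0 * x,
                           reverse_rate = function(x) 0 * x,
                           detach_rate_pre = function(x) 0 * x,
                           detach_rate_post = function(x) 0 * x,
                           S = 1)
  st <- detached_state(xb)
  st$p2 <- 0.3 * exp(-(xb$x - 2)^2)   # a Gaussian bump (mass < 1)
  st$p3 <- 1 - sum(st$p2) * xb$dx
  mass0 <- sum(st$p2) * xb$dx
  v <- 1000; n <- 150   # 15 nm displacement, well inside the grid
  for (i in 1:n) st <- step_pde(st, v, 1e-4, xb)
  shift <- v * n * 1e-4
  expect_equal(sum(st$p2) * xb$dx, mass0, tolerance = 1e-6)
  # centroid moved by v*t (upwind diffusion spreads but does not displace)
  c0 <- 2; c1 <- sum(st$x * st$p2) / sum(st$p2)
  expect_equal(c1 - c0, shift, tolerance = 0.05 * shift)
})

test_that("probability is conserved through activation and ramps", {
  xb <- shared_xb()
  st <- detached_state(xb)
  for (i in 1:2000) st <- step_pde(st, 0, 1e-4, xb)          # activate
  for (i in 1:2000) st <- step_pde(st, 120, 1e-4, xb)        # stretch
  for (i in 1:2000) st <- step_pde(st, -120, 1e-4, xb)       # shorten
  for (i in 1:1000) st <- step_pde(st, 0, 1e-4, xb, active = FALSE)
  expect_equal(total_probability(st), 1, tolerance = 1e-6)
})

test_that("stretch transients raise and shortening lowers active force", {
  xb <- shared_xb()
  iso_f <- active_force(steady_state(xb), 2.4, xb)
  st <- steady_state(xb)
  for (i in 1:3000) st <- step_pde(st, 120, 1e-4, xb)
  expect_gt(active_force(st, 2.4, xb), iso_f)
  st <- steady_state(xb)
  for (i in 1:3000) st <- step_pde(st, -120, 1e-4, xb)
  expect_lt(active_force(st, 2.4, xb), iso_f)
})

test_that("active force follows the overlap function and quadrature", {
  xb <- shared_xb()
  ss <- steady_state(xb)
  expect_equal(active_force(ss, 2.4, xb), 150, tolerance = 1e-9)
  # zero state and lost overlap both give zero force
  expect_equal(active_force(detached_state(xb), 2.4, xb), 0)
  expect_equal(active_force(ss, 4.0, xb), 0)
  expect_equal(active_force(ss, 4.5, xb), 0)
  # isometric force is proportional to the overlap fraction by construction
  for (L in c(2.0, 2.6, 3.0, 3.6)) {
    expect_equal(active_force(ss, L, xb),
                 150 * overlap_fraction(L, xb$fn), tolerance = 1e-9)
  }
  # independent trapezoid quadrature oracle
  integrand <- xb$kappa * ss$x * ss$p1 + xb$kappa * (ss$x + xb$delta) * ss$p2
  trap <- sum((integrand[-1] + integrand[-length(integrand)]) / 2) * xb$dx
  expect_equal(active_force(ss, 2.4, xb), xb$S * trap, tolerance = 1e-10)
})

test_that("isometric force is grid-converged", {
  xb <- shared_xb()
  fine <- crossbridge_params(n_x = 385L, S = xb$S)
  f1 <- active_force(steady_state(xb), 2.4, xb)
  f2 <- active_force(steady_state(fine), 2.4, fine)
  expect_lt(abs(f2 - f1) / f1, 0.005)
})

test_that("grid and rate validation", {
  expect_error(crossbridge_params(n_x = 32), "at least 64")
  expect_error(crossbridge_params(attach_rate = function(x) x), "non-negative")
})
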