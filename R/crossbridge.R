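# Three-state cross-bridge distribution model.
#
# Myosin heads cycle between a detached state (probability p3), an attached
# pre-power-stroke state (density p1 over cross-bridge link length x) and an
# attached force-generating state (density p2). The densities obey the
# advection-reaction PDE
#   dp/dt + v dp/dx = A(x, p1, p2, p3)
# where v is the half-sarcomere sliding velocity (stretch positive) and A
# collects attachment, power-stroke and detachment transitions. Active
# stress is S * g(L) * int( chi1 p1 + chi2 p2 ) dx with linear elastic head
# force functions chi1 = kappa x (pre-stroke) and chi2 = kappa (x + delta)
# (post-stroke, offset by the power-stroke distance delta).

#' Piecewise-linear actin-myosin overlap function
#'
#' Maps sarcomere length (um) to fractional filament overlap in [0, 1].
#' Defaults: zero at 1.27 um, full overlap plateau from 2.0 to 2.4 um
#' (optimal overlap), descending limb to zero at 4.0 um where thick and
#' thin filaments no longer overlap; constant outside the breakpoints.
#'
#' @param lengths breakpoint sarcomere lengths (um), increasing.
#' @param fractions overlap fractions at the breakpoints, in [0, 1]; the
#'   last fraction must be 0 (no overlap at and beyond the final length).
#' @return object of class `overlap_fn`.
#' @export
overlap_fn <- function(lengths = c(1.27, 2.0, 2.4, 4.0),
                       fractions = c(0, 1, 1, 0)) {
  stopifnot(length(lengths) == length(fractions), length(lengths) >= 2,
            all(diff(lengths) > 0), all(fractions >= 0), all(fractions <= 1),
            fractions[length(fractions)] == 0)
  structure(list(lengths = lengths, fractions = fractions),
            class = "overlap_fn")
}

#' Fractional actin-myosin overlap at a sarcomere length
#'
#' @param sarcomere_length sarcomere length in um (> 0, vectorised).
#' @param fn an [overlap_fn()].
#' @return overlap fraction in [0, 1].
#' @examples
#' overlap_fraction(c(2.4, 3.2, 4.2), overlap_fn())
#' @export
overlap_fraction <- function(sarcomere_length, fn = overlap_fn()) {
  stopifnot(inherits(fn, "overlap_fn"))
  if (any(sarcomere_length <= 0)) stop("sarcomere_length must be positive")
  xs <- fn$lengths; ys <- fn$fractions
  L <- pmin(pmax(sarcomere_length, xs[1]), xs[length(xs)])
  i <- pmin(findInterval(L, xs), length(xs) - 1L)
  ys[i] + (ys[i + 1L] - ys[i]) * (L - xs[i]) / (xs[i + 1L] - xs[i])
}

#' Cross-bridge model parameters
#'
#' Transition-rate functions of the three-state model, discretised on a
#' uniform grid of cross-bridge link lengths x (nm). The published rate
#' surfaces for this model class are not reproduced here; the defaults are
#' a qualitatively faithful stretch-responsive parameterisation (Gaussian
#' attachment kernel near x = 0, fast forward power stroke, detachment
#' rising steeply at large strain) and every piece is replaceable.
#'
#' The overall scale `S` is calibrated at construction so that the
#' isometric steady-state stress at full overlap equals
#' `reference_isometric_stress`.
#'
#' @param x_min,x_max,n_x cross-bridge strain grid (nm); `n_x >= 64`.
#' @param kappa cross-bridge stiffness (pN/nm).
#' @param delta power-stroke offset (nm).
#' @param attach_rate function(x) attachment rate density (1/s/nm) from
#'   detached to pre-power-stroke.
#' @param forward_rate function(x) pre- to post-power-stroke rate (1/s).
#' @param reverse_rate function(x) reverse power-stroke rate (1/s).
#' @param detach_rate_pre function(x) detachment rate from the pre-stroke
#'   state (1/s).
#' @param detach_rate_post function(x) detachment rate from the
#'   force-generating state (1/s).
#' @param reference_isometric_stress isometric stress (nN/um^2) at full
#'   overlap used to calibrate `S`; ignored when `S` is given.
#' @param S optional explicit scaling factor.
#' @param fn an [overlap_fn()].
#' @return object of class `crossbridge_params` with precomputed rate
#'   vectors on the grid.
#' @export
crossbridge_params <- function(
    x_min = -22, x_max = 26, n_x = 193L,
    kappa = 2, delta = 8,
    attach_rate = function(x) 80 * exp(-x^2 / 2),
    forward_rate = function(x) rep(300, length(x)),
    reverse_rate = function(x) rep(30, length(x)),
    detach_rate_pre = function(x) rep(15, length(x)),
    detach_rate_post = function(x) 15 + 400 / (1 + exp(-(abs(x) - 10))),
    reference_isometric_stress = 150,
    S = NULL,
    fn = overlap_fn()) {
  n_x <- as.integer(n_x)
  if (n_x < 64L) stop("n_x must be at least 64")
  stopifnot(x_max > x_min, kappa > 0, reference_isometric_stress > 0)
  x <- seq(x_min, x_max, length.out = n_x)
  p <- structure(list(
    x = x, dx = x[2] - x[1], n_x = n_x,
    kappa = kappa, delta = delta,
    att = attach_rate(x),
    f12 = forward_rate(x),
    g21 = reverse_rate(x),
    d1 = detach_rate_pre(x),
    d2 = detach_rate_post(x),
    fn = fn,
    S = 1
  ), class = "crossbridge_params")
  rates <- c(p$att, p$f12, p$g21, p$d1, p$d2)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all transition rates must be finite and non-negative on the grid")
  p$max_rate <- max(p$f12 + p$d1, p$g21 + p$d2, sum(p$att) * p$dx)
  if (is.null(S)) {
    raw <- active_force(steady_state(p), 2.4, p)
    if (raw <= 0) stop("cannot calibrate S: zero isometric force")
    p$S <- reference_isometric_stress / raw
  } else {
    p$S <- S
  }
  p
}

#' Isometric steady state of the cross-bridge distribution
#'
#' At zero sliding velocity the PDE reduces to a pointwise algebraic
#' balance; the steady state is solved directly and normalised so that the
#' total probability (attached integral plus detached) is one. With a zero
#' attachment kernel the all-detached state is returned.
#'
#' @param params a [crossbridge_params()].
#' @return object of class `crossbridge_state` with fields `p1`, `p2`
#'   (densities, 1/nm), `p3` (detached probability) and `time`.
#' @export
steady_state <- function(params) {
  stopifnot(inherits(params, "crossbridge_params"))
  with(params, {
    denom <- f12 + d1 - g21 * f12 / (g21 + d2)  # > 0 whenever d1 or d2 > 0
    w1 <- att / denom
    w2 <- w1 * f12 / (g21 + d2)
    I <- sum(w1 + w2) * dx
    p3 <- 1 / (1 + I)
    structure(list(p1 = w1 * p3, p2 = w2 * p3, p3 = p3, time = 0,
                   x = x, dx = dx),
              class = "crossbridge_state")
  })
}

#' Detached initial cross-bridge state
#'
#' @param params a [crossbridge_params()].
#' @return an all-detached `crossbridge_state` (p3 = 1).
#' @export
detached_state <- function(params) {
  stopifnot(inherits(params, "crossbridge_params"))
  structure(list(p1 = numeric(params$n_x), p2 = numeric(params$n_x),
                 p3 = 1, time = 0, x = params$x, dx = params$dx),
            class = "crossbridge_state")
}

#' Advance the cross-bridge PDE by one time step
#'
#' First-order upwind advection in cross-bridge strain (sliding velocity
#' `v = d(HSL)/dt`, stretch positive) plus explicit forward-Euler reaction.
#' Substeps internally to satisfy the CFL condition and reaction
#' stability. Total probability is conserved by construction (the same
#' rectangle quadrature couples the attached densities and the detached
#' pool); small negative densities from roundoff are clipped at -1e-12.
#'
#' @param state a `crossbridge_state`.
#' @param v sliding velocity of the half sarcomere (nm/s); positive while
#'   stretching.
#' @param dt time step (s).
#' @param params a [crossbridge_params()].
#' @param active logical; when `FALSE` the attachment kernel is switched
#'   off (deactivated sarcomere) and attached heads detach over time.
#' @return the advanced `crossbridge_state`.
#' @export
step_pde <- function(state, v, dt, params, active = TRUE) {
  stopifnot(inherits(state, "crossbridge_state"),
            inherits(params, "crossbridge_params"), dt > 0)
  dx <- params$dx
  n_sub <- max(1L, ceiling(abs(v) * dt / dx),
               ceiling(params$max_rate * dt / 0.2))
  if (n_sub > 1e6) stop("step_pde: CFL substepping cap exceeded (v = ", v,
                        " nm/s, dt = ", dt, " s)")
  dts <- dt / n_sub
  p1 <- state$p1; p2 <- state$p2; p3 <- state$p3
  att <- if (active) params$att else 0 * params$att
  att_tot <- sum(att) * dx
  f12 <- params$f12; g21 <- params$g21; d1 <- params$d1; d2 <- params$d2
  n <- params$n_x
  nu <- v * dts / dx
  for (s in seq_len(n_sub)) {
    if (v > 0) {
      p1 <- p1 - nu * (p1 - c(0, p1[-n]))
      p2 <- p2 - nu * (p2 - c(0, p2[-n]))
    } else if (v < 0) {
      p1 <- p1 - nu * (c(p1[-1], 0) - p1)
      p2 <- p2 - nu * (c(p2[-1], 0) - p2)
    }
    r1 <- att * p3 - (f12 + d1) * p1 + g21 * p2
    r2 <- f12 * p1 - (g21 + d2) * p2
    r3 <- sum(d1 * p1 + d2 * p2) * dx - p3 * att_tot
    p1 <- p1 + dts * r1
    p2 <- p2 + dts * r2
    p3 <- p3 + dts * r3
  }
  if (any(p1 < -1e-12) || any(p2 < -1e-12) || p3 < -1e-12)
    stop("step_pde: negative probability beyond tolerance; reduce dt")
  state$p1 <- pmax(p1, 0)
  state$p2 <- pmax(p2, 0)
  state$p3 <- max(p3, 0)
  state$time <- state$time + dt
  state
}

#' Active cross-bridge stress
#'
#' Evaluates `S * g(L) * int(chi1 p1 + chi2 p2) dx` by trapezoidal
#' quadrature on the strain grid, with linear elastic head force functions
#' `chi1(x) = kappa x` and `chi2(x) = kappa (x + delta)`. Zero whenever the
#' overlap fraction vanishes (sarcomere length at or beyond 4 um with the
#' default overlap map), regardless of the attached distribution.
#'
#' @param state a `crossbridge_state`.
#' @param sarcomere_length sarcomere length in um.
#' @param params a [crossbridge_params()].
#' @param fn overlap function; defaults to the one stored in `params`.
#' @return active stress in nN/um^2.
#' @export
active_force <- function(state, sarcomere_length = 2.4, params,
                         fn = params$fn) {
  stopifnot(inherits(state, "crossbridge_state"),
            inherits(params, "crossbridge_params"))
  g <- overlap_fraction(sarcomere_length, fn)
  integrand <- params$kappa * state$x * state$p1 +
    params$kappa * (state$x + params$delta) * state$p2
  params$S * g * trapz(state$x, integrand)
}

trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1])) / 2

# total probability of a cross-bridge state (should stay at 1)
total_probability <- function(state) {
  sum(state$p1 + state$p2) * state$dx + state$p3
}
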