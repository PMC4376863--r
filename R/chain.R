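# Equal-force solve of the serial titin chain.
#
# All compartments (folded proximal IG domains, unfolded proximal IG domains,
# PEVK, distal end filament, half A-band) act in series, so they carry one
# common force. For a given half-sarcomere length HSL the common force is the
# unique f >= 0 such that the compartment extensions at f sum to HSL:
#   HSL = Nu * lu(f) + (N - Nu) * lf(f) + lPEVK(f) + ldist + d + f/k_A
# When the strand is actin-bound the proximal IG compartment contributes its
# frozen length regardless of force and only PEVK + distal + A-band respond.

# tiny probe force defining the zero-force rest configuration (below slack
# the compartment lengths are not uniquely determined by the physics; we use
# the configuration at an infinitesimal force for continuity at slack).
REST_PROBE_FORCE <- 1e-6

# vectorised total chain length at force f (f, nu, frozen may be vectors;
# frozen is NA for unbound entries)
chain_length_at <- function(f, iso, nu, frozen) {
  kT <- BOLTZMANN_PN_NM * iso$temperature
  u_p <- wlc_shape_inverse(f * iso$pevk$persistence_length / kT)
  pevk_len <- iso$pevk$contour_length *
    (u_p + f / iso$pevk$elastic_modulus)
  fixed <- iso$distal_end_filament_length + iso$half_a_band_length +
    f / iso$a_band_stiffness
  bound <- !is.na(frozen)
  prox <- numeric(length(f))
  if (any(!bound)) {
    fu <- f[!bound]
    u_f <- wlc_shape_inverse(fu * iso$folded_ig$persistence_length / kT)
    u_u <- wlc_shape_inverse(fu * iso$unfolded_ig$persistence_length / kT)
    n_u <- nu[!bound]
    prox[!bound] <- (iso$n_proximal_ig - n_u) *
      iso$folded_ig$contour_length * u_f +
      n_u * iso$unfolded_ig$contour_length * u_u
  }
  if (any(bound)) prox[bound] <- frozen[bound]
  prox + pevk_len + fixed
}

# d(chain length)/df, same vectorisation contract as chain_length_at
chain_length_deriv <- function(f, iso, nu, frozen) {
  kT <- BOLTZMANN_PN_NM * iso$temperature
  u_p <- wlc_shape_inverse(f * iso$pevk$persistence_length / kT)
  dpevk <- iso$pevk$contour_length *
    (iso$pevk$persistence_length / (kT * wlc_shape_deriv(u_p)) +
       1 / iso$pevk$elastic_modulus)
  d <- dpevk + 1 / iso$a_band_stiffness
  bound <- !is.na(frozen)
  if (any(!bound)) {
    fu <- f[!bound]
    u_f <- wlc_shape_inverse(fu * iso$folded_ig$persistence_length / kT)
    u_u <- wlc_shape_inverse(fu * iso$unfolded_ig$persistence_length / kT)
    n_u <- nu[!bound]
    d[!bound] <- d[!bound] +
      (iso$n_proximal_ig - n_u) * iso$folded_ig$contour_length *
      iso$folded_ig$persistence_length / (kT * wlc_shape_deriv(u_f)) +
      n_u * iso$unfolded_ig$contour_length *
      iso$unfolded_ig$persistence_length / (kT * wlc_shape_deriv(u_u))
  }
  d
}

# combined residual L(f) - hsl and jacobian dL/df sharing the shape
# inversions (hot path of the protocol engine)
chain_resid_jac <- function(f, hsl, iso, nu, frozen) {
  kT <- BOLTZMANN_PN_NM * iso$temperature
  pev <- iso$pevk
  u_p <- wlc_shape_inverse(f * pev$persistence_length / kT)
  L <- pev$contour_length * (u_p + f / pev$elastic_modulus) +
    iso$distal_end_filament_length + iso$half_a_band_length +
    f / iso$a_band_stiffness
  J <- pev$contour_length *
    (pev$persistence_length / (kT * wlc_shape_deriv(u_p)) +
       1 / pev$elastic_modulus) + 1 / iso$a_band_stiffness
  bound <- !is.na(frozen)
  if (all(bound)) {
    L <- L + frozen
  } else if (!any(bound)) {
    u_f <- wlc_shape_inverse(f * iso$folded_ig$persistence_length / kT)
    u_u <- wlc_shape_inverse(f * iso$unfolded_ig$persistence_length / kT)
    cf <- (iso$n_proximal_ig - nu) * iso$folded_ig$contour_length
    cu <- nu * iso$unfolded_ig$contour_length
    L <- L + cf * u_f + cu * u_u
    J <- J + cf * iso$folded_ig$persistence_length /
      (kT * wlc_shape_deriv(u_f)) +
      cu * iso$unfolded_ig$persistence_length / (kT * wlc_shape_deriv(u_u))
  } else {
    L[bound] <- L[bound] + frozen[bound]
    fu <- f[!bound]
    u_f <- wlc_shape_inverse(fu * iso$folded_ig$persistence_length / kT)
    u_u <- wlc_shape_inverse(fu * iso$unfolded_ig$persistence_length / kT)
    cf <- (iso$n_proximal_ig - nu[!bound]) * iso$folded_ig$contour_length
    cu <- nu[!bound] * iso$unfolded_ig$contour_length
    L[!bound] <- L[!bound] + cf * u_f + cu * u_u
    J[!bound] <- J[!bound] + cf * iso$folded_ig$persistence_length /
      (kT * wlc_shape_deriv(u_f)) +
      cu * iso$unfolded_ig$persistence_length / (kT * wlc_shape_deriv(u_u))
  }
  list(r = L - hsl, J = J)
}

# fast warm-started Newton used by the engine; falls back to the robust
# bracketed solve when an iterate misbehaves or convergence stalls
solve_chain_force_fast <- function(hsl, iso, nu, frozen, f_init,
                                   tol = 1e-10) {
  f <- f_init
  ok <- f > 0
  if (!all(ok))
    return(solve_chain_force(hsl, iso, nu, frozen, f_init = NULL, tol = tol))
  atol <- tol * (1 + hsl)
  for (it in 1:20) {
    rj <- chain_resid_jac(f, hsl, iso, nu, frozen)
    if (max(abs(rj$r)) < atol) return(f)
    f_new <- f - rj$r / rj$J
    if (any(!is.finite(f_new)) || any(f_new <= 0))
      return(solve_chain_force(hsl, iso, nu, frozen, f_init = NULL,
                               tol = tol))
    f <- f_new
  }
  solve_chain_force(hsl, iso, nu, frozen, f_init = NULL, tol = tol)
}

# vectorised equal-force solve: one half-sarcomere length, vectors of
# unfolding counts / frozen lengths (NA when unbound). Returns forces (pN),
# 0 below slack. Safeguarded Newton with bracket maintenance; f_init is a
# warm start (e.g. the previous time step's solution).
solve_chain_force <- function(hsl, iso, nu, frozen, f_init = NULL,
                              tol = 1e-10) {
  n <- length(nu)
  stopifnot(length(frozen) == n, all(hsl > 0),
            length(hsl) == 1L || length(hsl) == n)
  hsl_e <- rep_len(hsl, n)
  slack <- chain_length_at(rep(REST_PROBE_FORCE, n), iso, nu, frozen)
  f <- numeric(n)
  act <- which(slack < hsl_e)
  if (!length(act)) return(f)
  nu_a <- nu[act]; fr_a <- frozen[act]; hs_a <- hsl_e[act]
  atol <- tol * (1 + max(hs_a))
  lo <- rep(0, length(act))
  hi <- rep(NA_real_, length(act))
  fa <- if (!is.null(f_init)) pmax(f_init[act], REST_PROBE_FORCE)
        else rep(1, length(act))
  for (it in 1:200) {
    L <- chain_length_at(fa, iso, nu_a, fr_a)
    r <- L - hs_a
    done <- abs(r) < atol
    if (all(done)) break
    lo <- ifelse(r < 0, pmax(lo, fa), lo)
    hi <- ifelse(r > 0, ifelse(is.na(hi), fa, pmin(hi, fa)), hi)
    step <- r / chain_length_deriv(fa, iso, nu_a, fr_a)
    f_new <- fa - step
    # fall back to bracket moves where Newton leaves the admissible range
    bad <- !is.finite(f_new) | f_new <= lo |
      (!is.na(hi) & f_new >= hi)
    f_new[bad] <- ifelse(is.na(hi[bad]), pmax(2 * fa[bad], 1),
                         (lo[bad] + hi[bad]) / 2)
    fa <- ifelse(done, fa, f_new)
    if (it == 200)
      stop("solve_chain_force: no convergence at HSL ", max(hs_a), " nm")
  }
  f[act] <- fa
  f
}

# internal equal-force solve of the frozen proximal segment of a bound
# strand: force such that the proximal IG extensions sum to frozen length.
# Drives unfolding of the protected proximal domains after binding.
solve_proximal_force <- function(iso, nu, frozen, tol = 1e-10) {
  n <- length(nu)
  stopifnot(length(frozen) == n)
  kT <- BOLTZMANN_PN_NM * iso$temperature
  len_at <- function(f, n_u) {
    u_f <- wlc_shape_inverse(f * iso$folded_ig$persistence_length / kT)
    u_u <- wlc_shape_inverse(f * iso$unfolded_ig$persistence_length / kT)
    (iso$n_proximal_ig - n_u) * iso$folded_ig$contour_length * u_f +
      n_u * iso$unfolded_ig$contour_length * u_u
  }
  out <- numeric(n)
  contour <- (iso$n_proximal_ig - nu) * iso$folded_ig$contour_length +
    nu * iso$unfolded_ig$contour_length
  for (i in seq_len(n)) {
    if (frozen[i] <= len_at(REST_PROBE_FORCE, nu[i])) next
    if (frozen[i] >= contour[i])
      stop("frozen proximal length ", frozen[i],
           " nm is at or beyond the proximal contour length ", contour[i],
           " nm: no finite equal force exists")
    hi <- 1
    while (len_at(hi, nu[i]) < frozen[i]) hi <- hi * 2
    out[i] <- stats::uniroot(function(f) len_at(f, nu[i]) - frozen[i],
                             lower = 0, upper = hi, tol = tol)$root
  }
  out
}

#' Slack length of a titin strand
#'
#' The half-sarcomere length at which the chain force first exceeds zero:
#' the sum of the rigid compartment lengths (distal end filament, half
#' A-band) and the compliant compartments' rest lengths under the
#' zero-force convention (lengths at an infinitesimal probe force, which
#' keeps the configuration unique and force traces continuous across the
#' slack crossing).
#'
#' @param iso a [titin_isoform()].
#' @param state a [titin_state()].
#' @return slack half-sarcomere length in nm.
#' @export
slack_length <- function(iso, state = titin_state()) {
  validate_isoform(iso)
  stopifnot(inherits(state, "titin_state"))
  frozen <- if (state$actin_bound) state$frozen_proximal_length else NA_real_
  chain_length_at(REST_PROBE_FORCE, iso, state$n_unfolded, frozen)
}

#' Equal-force solution of the titin chain at a given half-sarcomere length
#'
#' Solves for the unique common force carried by all serial compartments
#' such that their end-to-end lengths sum to the half-sarcomere length.
#' Below the slack length the force is zero and compartments sit at their
#' rest lengths (see [slack_length()]); the returned solution then carries
#' `slack = TRUE` and the lengths do not sum to the input.
#'
#' @param half_sarcomere_length half-sarcomere length in nm (> 0). Note:
#'   half of the sarcomere length, i.e. sarcomere 3.4 um = HSL 1700 nm.
#' @param iso a [titin_isoform()].
#' @param state a [titin_state()].
#' @return object of class `chain_solution`: `common_force` (pN),
#'   per-compartment lengths (`folded_ig_each`, `unfolded_ig_each`,
#'   `proximal_total`, `pevk`, `distal`, `a_band`, all nm) and `slack`.
#' @examples
#' iso <- titin_isoform()
#' chain_force(1500, iso, titin_state(n_unfolded = 10))$common_force
#' @export
chain_force <- function(half_sarcomere_length, iso, state = titin_state()) {
  validate_isoform(iso)
  stopifnot(inherits(state, "titin_state"),
            is.numeric(half_sarcomere_length),
            length(half_sarcomere_length) == 1L,
            half_sarcomere_length > 0)
  if (state$n_unfolded > iso$n_proximal_ig)
    stop("n_unfolded exceeds the number of proximal IG domains")
  frozen <- if (state$actin_bound) state$frozen_proximal_length else NA_real_
  f <- solve_chain_force(half_sarcomere_length, iso, state$n_unfolded, frozen)
  is_slack <- f == 0
  fe <- if (is_slack) REST_PROBE_FORCE else f
  kT <- BOLTZMANN_PN_NM * iso$temperature
  u_f <- wlc_shape_inverse(fe * iso$folded_ig$persistence_length / kT)
  u_u <- wlc_shape_inverse(fe * iso$unfolded_ig$persistence_length / kT)
  folded_each <- iso$folded_ig$contour_length * u_f
  unfolded_each <- iso$unfolded_ig$contour_length * u_u
  if (state$actin_bound) {
    prox_total <- state$frozen_proximal_length
    folded_each <- NA_real_
    unfolded_each <- NA_real_
  } else {
    prox_total <- (iso$n_proximal_ig - state$n_unfolded) * folded_each +
      state$n_unfolded * unfolded_each
  }
  structure(list(
    common_force = f,
    folded_ig_each = folded_each,
    unfolded_ig_each = unfolded_each,
    proximal_total = prox_total,
    pevk = ewlc_extension(fe, iso$pevk),
    distal = iso$distal_end_filament_length,
    a_band = iso$half_a_band_length + fe / iso$a_band_stiffness,
    half_sarcomere_length = half_sarcomere_length,
    slack = is_slack
  ), class = "chain_solution")
}

#' @export
print.chain_solution <- function(x, ...) {
  cat(sprintf("chain solution at HSL %.6g nm: force %.6g pN%s\n",
              x$half_sarcomere_length, x$common_force,
              if (x$slack) " (below slack)" else ""))
  cat(sprintf("  proximal IG %.6g | PEVK %.6g | distal %.6g | A-band %.6g nm\n",
              x$proximal_total, x$pevk, x$distal, x$a_band))
  invisible(x)
}

#' Bind a titin strand to actin at the most proximal PEVK residue
#'
#' Binding happens at the nearest actin binding site (continuum
#' convention), so compartment lengths are unchanged by the binding event
#' and no force is generated by binding itself. Afterwards the proximal IG
#' compartment is frozen at its current total end-to-end length and only
#' the PEVK (plus rigid distal and A-band compartments) extends with
#' further length changes -- the free spring is shorter, so the bound chain
#' is stiffer. Binding is only possible while cross-bridge interaction is
#' enabled (activated sarcomere).
#'
#' @param state a [titin_state()]; must not already be bound.
#' @param solution the current [chain_force()] solution for this strand.
#' @param active logical; is cross-bridge interaction enabled?
#' @return the bound [titin_state()].
#' @export
bind_to_actin <- function(state, solution, active = TRUE) {
  stopifnot(inherits(state, "titin_state"),
            inherits(solution, "chain_solution"))
  if (!isTRUE(active))
    stop("titin-actin binding rejected: cross-bridge interaction is inhibited")
  if (state$actin_bound) stop("strand is already bound to actin")
  titin_state(n_unfolded = state$n_unfolded,
              calcium_bound = state$calcium_bound,
              actin_bound = TRUE,
              frozen_proximal_length = solution$proximal_total)
}

#' Release a bound titin strand from actin
#'
#' @param state a bound [titin_state()].
#' @return the unbound state (unfolding count is retained).
#' @export
unbind_from_actin <- function(state) {
  stopifnot(inherits(state, "titin_state"))
  if (!state$actin_bound) return(state)
  titin_state(n_unfolded = state$n_unfolded,
              calcium_bound = state$calcium_bound,
              actin_bound = FALSE)
}
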