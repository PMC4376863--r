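# Protocol engine: couples the cross-bridge PDE and the stochastic titin
# ensemble on a shared clock. The titin chain is solved quasi-statically at
# every step (chain equilibration is fast compared to protocol timescales);
# strands are solved in groups of identical state (same unfolding count, or
# same frozen proximal length when bound), so the per-step cost is bounded
# by the number of distinct states rather than the number of strands.
#
# While a strand is bound to actin its proximal IG segment is mechanically
# decoupled from the free spring: it is held at its frozen length, and the
# force that drives further unfolding of those protected domains is the
# internal equal force of the frozen segment (constant between unfolding or
# calcium events), not the chain force.

#' Run a half-sarcomere simulation protocol
#'
#' Integrates the cross-bridge distribution model and the Monte-Carlo titin
#' ensemble through the phases of a [protocol()], applying the titin-actin
#' binding and calcium rules selected by [scenario_flags()]:
#' at activation the calcium parameter set and/or binding are applied per
#' the scenario ordering; binding under `"instantaneous-calcium"` becomes
#' effective at the onset of the first ramp after activation, under
#' `"instantaneous-binding"` at activation itself (binding always requires
#' cross-bridge interaction to be enabled). At deactivation calcium is
#' reversed instantly and strands unbind according to the deactivation
#' flag. The run stops early, with an event logged, if any strand force
#' exceeds `rupture_force` (protein structures would start to break).
#'
#' @param proto a [protocol()].
#' @param scenario a [scenario_flags()].
#' @param iso a [titin_isoform()] (low-calcium parameter set).
#' @param unfold an [unfolding_params()].
#' @param xb a [crossbridge_params()] (built with defaults if missing).
#' @param config an [ensemble_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @param variant model variant: `"full"` (cross-bridges, calcium and
#'   titin-actin binding), `"no-binding"` (cross-bridges and calcium only),
#'   `"calcium-only"` (calcium effects, cross-bridges inhibited, hence no
#'   binding), or `"passive"` (activation phases ignored entirely).
#' @param rupture_force per-strand titin force (pN) at which the run stops.
#' @return a `force_trace`: data frame with columns `time_s`,
#'   `sarcomere_um`, `active_nN_um2`, `titin_nN_um2`, `total_nN_um2`,
#'   `mean_unfolded`, `titin_sd_nN_um2`, with attributes `events`
#'   (data frame of phase/binding events), `ruptured`, `seed`, `scenario`
#'   and `variant`.
#' @export
run_protocol <- function(proto, scenario = scenario_flags(),
                         iso = titin_isoform(),
                         unfold = unfolding_params(n_domains =
                                                     iso$n_proximal_ig),
                         xb = crossbridge_params(),
                         config = ensemble_config(),
                         seed = config$seed,
                         variant = c("full", "no-binding", "calcium-only",
                                     "passive"),
                         rupture_force = 600) {
  stopifnot(inherits(proto, "protocol"), inherits(scenario, "scenario_flags"),
            inherits(config, "ensemble_config"))
  validate_isoform(iso)
  variant <- match.arg(variant)
  if (unfold$n_domains != iso$n_proximal_ig)
    stop("unfolding_params n_domains must match the isoform")
  allow_xb <- variant %in% c("full", "no-binding")
  allow_bind <- variant == "full"
  allow_ca <- variant != "passive"

  set.seed(as.integer(seed))
  n <- config$n_strands
  dt <- config$dt
  spm <- config$strands_per_um2

  # mutable simulation state
  sl <- NA_real_                     # sarcomere length, um
  nu <- integer(n)                   # unfolded proximal IG domains
  frozen <- rep(NA_real_, n)         # frozen proximal length (bound strands)
  f_strand <- numeric(n)             # chain force per strand (pN)
  f_prox <- numeric(n)               # internal proximal force when bound
  iso_cur <- iso
  xb_state <- detached_state(xb)
  active <- FALSE                    # cross-bridge cycling on
  calcium <- FALSE
  pending_bind <- FALSE
  t_now <- 0
  ruptured <- FALSE
  events <- list()
  log_event <- function(what) events[[length(events) + 1L]] <<-
    data.frame(time_s = t_now, event = what)

  solve_titin <- function(hsl) {
    unb <- which(is.na(frozen))
    if (length(unb)) {
      uc <- sort(unique(nu[unb]))
      f_init <- f_strand[unb][match(uc, nu[unb])]
      fg <- solve_chain_force_fast(hsl, iso_cur, uc,
                                   rep(NA_real_, length(uc)), f_init)
      f_strand[unb] <<- fg[match(nu[unb], uc)]
    }
    bnd <- which(!is.na(frozen))
    if (length(bnd)) {
      ufr <- unique(frozen[bnd])
      f_init <- f_strand[bnd][match(ufr, frozen[bnd])]
      fg <- solve_chain_force_fast(hsl, iso_cur, rep(0L, length(ufr)), ufr,
                                   f_init)
      f_strand[bnd] <<- fg[match(frozen[bnd], ufr)]
    }
    invisible(NULL)
  }

  proximal_lengths_at <- function(f, counts) {
    kT <- BOLTZMANN_PN_NM * iso_cur$temperature
    u_f <- wlc_shape_inverse(f * iso_cur$folded_ig$persistence_length / kT)
    u_u <- wlc_shape_inverse(f * iso_cur$unfolded_ig$persistence_length / kT)
    (iso_cur$n_proximal_ig - counts) * iso_cur$folded_ig$contour_length * u_f +
      counts * iso_cur$unfolded_ig$contour_length * u_u
  }

  bind_all <- function() {
    unb <- which(is.na(frozen))
    if (!length(unb)) return(invisible(NULL))
    fe <- pmax(f_strand[unb], REST_PROBE_FORCE)
    frozen[unb] <<- proximal_lengths_at(fe, nu[unb])
    f_prox[unb] <<- f_strand[unb]
    log_event(sprintf("actin-titin binding (%d strands)", length(unb)))
    invisible(NULL)
  }

  unbind_all <- function() {
    bnd <- which(!is.na(frozen))
    if (!length(bnd)) return(invisible(NULL))
    frozen[bnd] <<- NA_real_
    f_prox[bnd] <<- 0
    log_event(sprintf("actin-titin unbinding (%d strands)", length(bnd)))
    invisible(NULL)
  }

  set_calcium <- function(on) {
    if (on == calcium) return(invisible(NULL))
    r <- iso_cur$calcium_force_factor
    iso_cur <<- if (on) apply_calcium(iso_cur) else remove_calcium(iso_cur)
    # the calcium set scales the titin force law uniformly, so the internal
    # force of a frozen proximal segment scales by exactly that factor
    f_prox <<- f_prox * if (on) r else 1 / r
    calcium <<- on
    log_event(if (on) "calcium high" else "calcium low")
    invisible(NULL)
  }

  # preallocate the trace
  total_steps <- protocol_step_count(proto, dt)
  cap <- total_steps %/% config$record_every + length(proto$phases) + 16L
  rec <- matrix(0, cap, 6L)
  ri <- 0L
  record <- function() {
    ri <<- ri + 1L
    if (ri > nrow(rec)) rec <<- rbind(rec, matrix(0, 4096L, 6L))
    rec[ri, ] <<- c(t_now, sl,
                    if (allow_xb) active_force(xb_state, sl, xb) else 0,
                    sum(f_strand) / n * spm / 1000,
                    sum(nu) / n,
                    stats::sd(f_strand) * spm / 1000)
  }

  record_dt <- config$record_every * dt
  next_rec <- 0
  maybe_record <- function() {
    if (t_now + 1e-12 >= next_rec) {
      record()
      next_rec <<- t_now + record_dt  # strictly ahead: guarantees progress
    }
  }

  check_rupture <- function() {
    if (max(f_strand) > rupture_force) {
      ruptured <<- TRUE
      log_event(sprintf("rupture stop: strand force %.1f pN > %.1f pN",
                        max(f_strand), rupture_force))
      record()
    }
    ruptured
  }

  drive_forces <- function() {
    d <- f_strand
    bnd <- !is.na(frozen)
    d[bnd] <- f_prox[bnd]
    d
  }

  xb_idle <- function() !active && xb_state$p3 > 1 - 1e-12

  advance_ramp <- function(n_steps, v_sl) {
    # v_sl: sarcomere-level speed in nm/s (signed); HSL rate is half that
    for (k in seq_len(n_steps)) {
      if (ruptured) return(invisible(NULL))
      sl <<- sl + v_sl * dt / 1000
      if (allow_xb && !xb_idle())
        xb_state <<- step_pde(xb_state, v_sl / 2, dt, xb, active = active)
      solve_titin(sl * 500)
      nu_new <- mc_step_counts(nu, drive_forces(), dt, unfold,
                               calcium = calcium)
      changed <- which(nu_new != nu & !is.na(frozen))
      nu <<- nu_new
      if (length(changed))
        f_prox[changed] <<- solve_proximal_force(iso_cur, nu[changed],
                                                 frozen[changed])
      t_now <<- t_now + dt
      if (check_rupture()) return(invisible(NULL))
      maybe_record()
    }
    invisible(NULL)
  }

  # one unfolding event for strand j; refreshes its force
  apply_event <- function(j) {
    nu[j] <<- min(nu[j] + 1L, unfold$n_domains)
    if (is.na(frozen[j])) {
      f_strand[j] <<- solve_chain_force_fast(sl * 500, iso_cur, nu[j],
                                             NA_real_, f_strand[j])
    } else {
      f_prox[j] <<- solve_proximal_force(iso_cur, nu[j], frozen[j])
    }
    invisible(NULL)
  }

  # hold at constant length: forces are static between unfolding events, so
  # unfolding is simulated event-by-event (exponential waiting times, the
  # continuous-time limit of the per-step Bernoulli scheme, to which it is
  # equivalent in distribution because rates are constant between events).
  # The cross-bridge PDE is stepped until its active force settles, then
  # frozen until the regime changes.
  advance_hold <- function(duration) {
    t_end <- t_now + duration
    rates <- strand_total_rates(nu, drive_forces(), unfold, calcium)
    r_tot <- sum(rates)
    next_ev <- if (r_tot > 1e-15) t_now + stats::rexp(1) / r_tot else Inf
    xb_on <- allow_xb && !xb_idle()
    settle_check <- 256L
    since_check <- 0L
    f_ref <- if (xb_on) active_force(xb_state, sl, xb) else 0
    while (t_now < t_end - 1e-9 && !ruptured) {
      if (xb_on) {
        xb_state <<- step_pde(xb_state, 0, dt, xb, active = active)
        t_now <<- t_now + dt
        since_check <- since_check + 1L
        if (since_check >= settle_check) {
          f_now <- active_force(xb_state, sl, xb)
          if (abs(f_now - f_ref) <= 1e-9 * (1 + abs(f_ref)) &&
              !(!active && xb_state$p3 < 1 - 1e-9)) xb_on <- FALSE
          f_ref <- f_now
          since_check <- 0L
        }
        if (t_now + 1e-12 >= next_ev) {
          j <- sample.int(n, 1L, prob = rates)
          apply_event(j)
          rates <- strand_total_rates(nu, drive_forces(), unfold, calcium)
          r_tot <- sum(rates)
          next_ev <- if (r_tot > 1e-15) t_now + stats::rexp(1) / r_tot
                     else Inf
          if (check_rupture()) return(invisible(NULL))
        }
        maybe_record()
      } else {
        # jump straight to the next event / record boundary / phase end
        t_jump <- min(next_ev, next_rec, t_end)
        t_now <<- max(t_jump, t_now)
        if (next_ev <= min(next_rec, t_end) + 1e-12 && is.finite(next_ev)) {
          j <- sample.int(n, 1L, prob = rates)
          apply_event(j)
          rates <- strand_total_rates(nu, drive_forces(), unfold, calcium)
          r_tot <- sum(rates)
          next_ev <- if (r_tot > 1e-15) t_now + stats::rexp(1) / r_tot
                     else Inf
          if (check_rupture()) return(invisible(NULL))
        }
        maybe_record()
      }
    }
    invisible(NULL)
  }

  for (ph in proto$phases) {
    if (ruptured) break
    switch(ph$type,
      set_length = {
        sl <- ph$sarcomere_um
        solve_titin(sl * 500)
        log_event(sprintf("set length %.3g um", sl))
        record()
      },
      activate = {
        if (variant != "passive") {
          xb_on <- allow_xb && ph$crossbridges == "on"
          want_ca <- allow_ca && ph$calcium == "high"
          can_bind <- allow_bind && ph$crossbridges == "on"
          if (!can_bind && allow_bind && ph$crossbridges == "off")
            log_event("binding suppressed: cross-bridge interaction inhibited")
          if (scenario$calcium_ordering == "instantaneous-binding") {
            if (can_bind) bind_all()
            if (want_ca) set_calcium(TRUE)
          } else {
            if (want_ca) set_calcium(TRUE)
            pending_bind <- can_bind
          }
          active <- xb_on
          solve_titin(sl * 500)
          log_event(sprintf("activate (crossbridges %s, calcium %s)",
                            ph$crossbridges, ph$calcium))
          record()
        } else {
          log_event("activation ignored (passive variant)")
        }
      },
      ramp = {
        if (pending_bind) {
          bind_all()
          pending_bind <- FALSE
          solve_titin(sl * 500)
        }
        v_sl <- ph$speed * sl * sign(ph$target_um - sl)
        n_steps <- max(1L, round(abs(ph$target_um - sl) * 1000 /
                                   (abs(v_sl) * dt)))
        log_event(sprintf("ramp to %.3g um at %.4g nm/s", ph$target_um, v_sl))
        advance_ramp(n_steps, v_sl)
        if (!ruptured) {
          # absorb step-count roundoff: land exactly on the target length
          sl <- ph$target_um
          solve_titin(sl * 500)
        }
      },
      hold = {
        advance_hold(ph$duration_s)
      },
      deactivate = {
        active <- FALSE
        pending_bind <- FALSE
        set_calcium(FALSE)
        if (scenario$deactivation_unbinding == "immediate-unbind")
          unbind_all()
        solve_titin(sl * 500)
        log_event("deactivate")
        record()
        if (ph$hold_s > 0) advance_hold(ph$hold_s)
      },
      stop("unknown phase type: ", ph$type)
    )
  }
  record()

  idx <- seq_len(ri)
  trace <- data.frame(time_s = rec[idx, 1], sarcomere_um = rec[idx, 2],
                      active_nN_um2 = rec[idx, 3],
                      titin_nN_um2 = rec[idx, 4],
                      mean_unfolded = rec[idx, 5],
                      titin_sd_nN_um2 = rec[idx, 6])
  trace$total_nN_um2 <- trace$active_nN_um2 + trace$titin_nN_um2
  trace <- trace[, c("time_s", "sarcomere_um", "active_nN_um2",
                     "titin_nN_um2", "total_nN_um2", "mean_unfolded",
                     "titin_sd_nN_um2")]
  structure(trace,
            events = do.call(rbind, events),
            ruptured = ruptured,
            seed = as.integer(seed),
            scenario = scenario,
            variant = variant,
            class = c("force_trace", "data.frame"))
}

protocol_step_count <- function(proto, dt) {
  total <- 0
  sl <- 2.4
  for (ph in proto$phases) {
    if (ph$type == "set_length") sl <- ph$sarcomere_um
    if (ph$type == "ramp") {
      total <- total + abs(ph$target_um - sl) * 1000 / (ph$speed * sl * dt)
      sl <- ph$target_um
    }
    if (ph$type == "hold") total <- total + ph$duration_s / dt
    if (ph$type == "deactivate") total <- total + ph$hold_s / dt
  }
  as.integer(ceiling(total)) + 1L
}

#' Passive titin ensemble trace
#'
#' Runs a protocol with activation phases ignored: the trace contains the
#' Monte-Carlo mean titin stress (and its across-strand standard
#' deviation), normalised to a 1 um^2 half-sarcomere cross-section via
#' `config$strands_per_um2`. Reproducible for a fixed seed.
#'
#' @inheritParams run_protocol
#' @return a `force_trace` (active stress identically zero).
#' @export
ensemble_trace <- function(proto, iso = titin_isoform(),
                           unfold = unfolding_params(n_domains =
                                                       iso$n_proximal_ig),
                           config = ensemble_config(),
                           seed = config$seed) {
  run_protocol(proto, scenario_flags(), iso, unfold,
               xb = minimal_crossbridge_params(), config = config,
               seed = seed, variant = "passive")
}

# cached tiny cross-bridge parameter set for passive runs (never stepped)
minimal_crossbridge_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- crossbridge_params()
    cache
  }
})
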