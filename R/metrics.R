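#' Steady-state total stress of a force trace
#'
#' Averages the total stress over the trailing `window` seconds of a
#' trace, after checking that the force has settled: the relative drift
#' (fitted linear slope times the window, relative to the mean) must stay
#' below `drift_tol` percent. Errors with a drift diagnostic otherwise.
#'
#' @param trace a `force_trace` from [run_protocol()].
#' @param window trailing window length (s).
#' @param drift_tol maximum tolerated drift over the window (% of the mean).
#' @param end_time optional right edge of the window (s); defaults to the
#'   end of the trace (use the pre-deactivation time for protocols that
#'   end with a deactivation).
#' @return mean total stress (nN/um^2) over the window.
#' @export
steady_state_stress <- function(trace, window = 1, drift_tol = 0.1,
                                end_time = NULL) {
  stopifnot(inherits(trace, "force_trace"))
  t_end <- if (is.null(end_time)) max(trace$time_s) else end_time
  sel <- trace$time_s >= t_end - window & trace$time_s <= t_end
  if (sum(sel) < 5)
    stop("steady_state_stress: fewer than 5 samples in the trailing window")
  tt <- trace$time_s[sel]
  ff <- trace$total_nN_um2[sel]
  m <- mean(ff)
  slope <- stats::coef(stats::lm(ff ~ tt))[[2]]
  drift_pct <- abs(slope) * window / max(abs(m), .Machine$double.eps) * 100
  if (drift_pct > drift_tol)
    stop(sprintf(paste0("no steady state: drift %.3f%% over the trailing ",
                        "%.3g s window exceeds %.3g%%"),
                 drift_pct, window, drift_tol))
  m
}

#' Residual force enhancement
#'
#' Percent excess of the steady-state total force after an active stretch
#' over the corresponding isometric force at the final length (an
#' isometric run activated at that length, same scenario flags).
#'
#' @param stretch_trace trace of the active-stretch protocol.
#' @param isometric_trace trace of the isometric reference at the final
#'   length.
#' @param window,drift_tol passed to [steady_state_stress()].
#' @return enhancement in percent (positive = enhanced).
#' @export
residual_force_enhancement <- function(stretch_trace, isometric_trace,
                                       window = 1, drift_tol = 0.1) {
  fs <- steady_state_stress(stretch_trace, window, drift_tol)
  fi <- steady_state_stress(isometric_trace, window, drift_tol)
  100 * (fs / fi - 1)
}

#' Force depression
#'
#' Percent change of the steady-state total force after active shortening
#' relative to the isometric force at the final length (negative =
#' depressed). Same computation as [residual_force_enhancement()]; the
#' separate name documents the expected sign.
#'
#' @inheritParams residual_force_enhancement
#' @param shorten_trace trace of the active-shortening protocol.
#' @return depression in percent (negative when force is depressed).
#' @export
force_depression <- function(shorten_trace, isometric_trace,
                             window = 1, drift_tol = 0.1) {
  residual_force_enhancement(shorten_trace, isometric_trace,
                             window, drift_tol)
}

#' Passive force enhancement after deactivation
#'
#' Runs a protocol that ends with a deactivation phase under both
#' deactivation extremes (`keep-bound`, `immediate-unbind`), plus a purely
#' passive control following the same length trajectory, and reports the
#' percent excess of the post-deactivation total force over the passive
#' force at the same length and time,
#' `100 * (post-deactivation / passive - 1)`, for each scenario.
#'
#' @param proto a [protocol()] whose final phase is [phase_deactivate()].
#' @param calcium_ordering activation ordering used for both runs.
#' @inheritParams run_protocol
#' @return named numeric vector `c(keep_bound, immediate_unbind)` (percent).
#' @export
passive_force_enhancement <- function(proto,
                                      calcium_ordering =
                                        "instantaneous-calcium",
                                      iso = titin_isoform(),
                                      unfold = unfolding_params(
                                        n_domains = iso$n_proximal_ig),
                                      xb = crossbridge_params(),
                                      config = ensemble_config(),
                                      seed = config$seed) {
  last_ph <- proto$phases[[length(proto$phases)]]
  if (last_ph$type != "deactivate")
    stop("passive_force_enhancement needs a protocol ending in deactivation")
  traces <- lapply(c("keep-bound", "immediate-unbind"), function(mode)
    run_protocol(proto, scenario_flags(calcium_ordering, mode), iso, unfold,
                 xb, config, seed = seed))
  control <- run_protocol(strip_activation(proto), scenario_flags(), iso,
                          unfold, xb, config, seed = seed,
                          variant = "passive")
  ref <- utils::tail(control$total_nN_um2, 1)
  vals <- vapply(traces, function(tr) utils::tail(tr$total_nN_um2, 1),
                 numeric(1))
  stats::setNames(100 * (vals / ref - 1), c("keep_bound", "immediate_unbind"))
}
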