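#' Experimental protocol for a half-sarcomere simulation
#'
#' A protocol is an ordered list of phases built with the `phase_*`
#' constructors: [phase_set_length()], [phase_activate()], [phase_ramp()],
#' [phase_hold()], [phase_deactivate()]. Lengths are sarcomere lengths in
#' um (the simulated half sarcomere has half that length in nm); ramp
#' speeds are expressed in nm/s per sarcomere length, i.e. the absolute
#' sarcomere-level speed is `speed * SL_onset` nm/s where `SL_onset` is the
#' sarcomere length (um) when the ramp starts.
#'
#' @param ... phase objects.
#' @param name optional protocol name.
#' @return object of class `protocol`.
#' @export
protocol <- function(..., name = NULL) {
  phases <- list(...)
  if (length(phases) == 1L && is.list(phases[[1]]) &&
      !inherits(phases[[1]], "protocol_phase"))
    phases <- phases[[1]]
  if (!length(phases)) stop("a protocol needs at least one phase")
  ok <- vapply(phases, inherits, logical(1), what = "protocol_phase")
  if (!all(ok)) stop("all protocol elements must be phase_* objects")
  structure(list(phases = phases, name = name), class = "protocol")
}

new_phase <- function(type, ...) {
  structure(c(list(type = type), list(...)), class = "protocol_phase")
}

#' @rdname protocol
#' @param sarcomere_um sarcomere length to set instantaneously (um).
#' @export
phase_set_length <- function(sarcomere_um) {
  stopifnot(sarcomere_um > 0)
  new_phase("set_length", sarcomere_um = sarcomere_um)
}

#' @rdname protocol
#' @param crossbridges `"on"` or `"off"`; whether cross-bridge cycling is
#'   enabled by the activation (titin-actin binding requires `"on"`).
#' @param calcium `"high"` or `"low"`; titin parameter set to apply.
#' @export
phase_activate <- function(crossbridges = "on", calcium = "high") {
  crossbridges <- match.arg(crossbridges, c("on", "off"))
  calcium <- match.arg(calcium, c("high", "low"))
  new_phase("activate", crossbridges = crossbridges, calcium = calcium)
}

#' @rdname protocol
#' @param target_um target sarcomere length (um).
#' @param speed ramp speed in nm/s per sarcomere length (> 0).
#' @export
phase_ramp <- function(target_um, speed = 100) {
  stopifnot(target_um > 0, speed > 0)
  new_phase("ramp", target_um = target_um, speed = speed)
}

#' @rdname protocol
#' @param duration_s hold duration (s).
#' @export
phase_hold <- function(duration_s) {
  stopifnot(duration_s > 0)
  new_phase("hold", duration_s = duration_s)
}

#' @rdname protocol
#' @param hold_s duration held after deactivation (s).
#' @export
phase_deactivate <- function(hold_s = 5) {
  stopifnot(hold_s >= 0)
  new_phase("deactivate", hold_s = hold_s)
}

#' @export
print.protocol <- function(x, ...) {
  cat("protocol", if (!is.null(x$name)) sQuote(x$name) else "",
      "with", length(x$phases), "phases\n")
  for (ph in x$phases) {
    args <- ph[setdiff(names(ph), "type")]
    cat("  -", ph$type, paste(names(args), unlist(args), sep = "=",
                              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Scenario flags for titin-actin coupling
#'
#' Two orderings of the calcium and binding events at activation, and two
#' extremes of what happens at deactivation, since neither rate is known:
#'
#' * `calcium_ordering = "instantaneous-calcium"` (default): calcium
#'   stiffening is instantaneous at activation; actin-titin binding only
#'   becomes effective at the onset of the first externally imposed ramp
#'   after activation.
#' * `calcium_ordering = "instantaneous-binding"`: binding is the fast
#'   process and happens at activation (with the strand still in its
#'   low-calcium configuration); calcium stiffening follows once bound.
#' * `deactivation_unbinding = "keep-bound"`: titin stays bound to actin
#'   after deactivation while calcium effects reverse.
#' * `deactivation_unbinding = "immediate-unbind"`: titin unbinds within
#'   milliseconds of deactivation.
#'
#' @param calcium_ordering one of `"instantaneous-calcium"`,
#'   `"instantaneous-binding"`.
#' @param deactivation_unbinding one of `"keep-bound"`,
#'   `"immediate-unbind"`.
#' @return object of class `scenario_flags`.
#' @export
scenario_flags <- function(calcium_ordering = c("instantaneous-calcium",
                                                "instantaneous-binding"),
                           deactivation_unbinding = c("keep-bound",
                                                      "immediate-unbind")) {
  structure(list(calcium_ordering = match.arg(calcium_ordering),
                 deactivation_unbinding = match.arg(deactivation_unbinding)),
            class = "scenario_flags")
}

#' Registry of canonical simulation protocols
#'
#' Named protocols for the standard history-dependence experiments:
#'
#' * `beyond_overlap_2.4`: activate at optimal overlap (2.4 um) and stretch
#'   actively beyond actin-myosin overlap towards 6 um (the run stops when
#'   the rupture force is exceeded).
#' * `beyond_overlap_3.4`: passive stretch to 3.4 um, activate there, then
#'   stretch actively beyond overlap.
#' * `rfe`: residual force enhancement; activate at 2.4 um, stretch to
#'   3.0 um at 100 nm/s per sarcomere length, hold.
#' * `rfe_iso`: matching isometric reference activated at 3.0 um.
#' * `fd`: force depression; passive stretch to 2.6 um, activate, shorten
#'   to 2.4 um, hold.
#' * `fd_iso`: matching isometric reference activated at 2.4 um.
#' * `pfe`: the rfe protocol followed by deactivation with a 5 s hold.
#'
#' Model-variant conditions (purely passive, calcium effects without
#' cross-bridges, cross-bridges without titin-actin binding, full model)
#' are selected through the `variant` argument of [run_protocol()], which
#' applies to any of these protocols.
#'
#' @param name optional single protocol name to return; with `NULL` the
#'   whole named list is returned.
#' @param hold_s steady-state hold duration after ramps (s).
#' @return a named list of [protocol()] objects, or one protocol.
#' @export
canonical_protocols <- function(name = NULL, hold_s = 120) {
  reg <- list(
    beyond_overlap_2.4 = protocol(
      phase_set_length(2.4), phase_activate(), phase_hold(1),
      phase_ramp(6.0, 100), name = "beyond_overlap_2.4"),
    beyond_overlap_3.4 = protocol(
      phase_set_length(2.4), phase_ramp(3.4, 100), phase_activate(),
      phase_hold(1), phase_ramp(6.0, 100), name = "beyond_overlap_3.4"),
    rfe = protocol(
      phase_set_length(2.4), phase_activate(), phase_hold(1),
      phase_ramp(3.0, 100), phase_hold(hold_s), name = "rfe"),
    rfe_iso = protocol(
      phase_set_length(3.0), phase_activate(),
      phase_hold(1 + 2.5 + hold_s), name = "rfe_iso"),
    fd = protocol(
      phase_set_length(2.4), phase_ramp(2.6, 100), phase_activate(),
      phase_hold(1), phase_ramp(2.4, 100), phase_hold(hold_s),
      name = "fd"),
    fd_iso = protocol(
      phase_set_length(2.4), phase_activate(),
      phase_hold(2 + hold_s), name = "fd_iso"),
    pfe = protocol(
      phase_set_length(2.4), phase_activate(), phase_hold(1),
      phase_ramp(3.0, 100), phase_hold(hold_s), phase_deactivate(5),
      name = "pfe")
  )
  if (is.null(name)) return(reg)
  if (!name %in% names(reg))
    stop("unknown protocol ", sQuote(name), "; available: ",
         paste(names(reg), collapse = ", "))
  reg[[name]]
}

# a protocol with activation/deactivation stripped (purely passive control
# following the same length trajectory and total duration)
strip_activation <- function(proto) {
  phases <- list()
  for (ph in proto$phases) {
    if (ph$type == "activate") next
    if (ph$type == "deactivate") {
      if (ph$hold_s > 0) phases <- c(phases, list(phase_hold(ph$hold_s)))
      next
    }
    phases <- c(phases, list(ph))
  }
  protocol(phases, name = paste0(proto$name, "_passive"))
}
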