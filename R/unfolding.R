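#' Force-dependent IG-domain unfolding parameters
#'
#' Two-state, no-refolding unfolding kinetics of the proximal IG domains.
#' The unfolding rate of domain `i` under force `f` follows the Bell model
#' \deqn{k_i(f) = k_0 \exp(f \, \Delta x_i / k_B T)}
#' where the activation-barrier width `Delta x_i` decreases weakly with the
#' domain index: later domains need higher forces, giving the hierarchical
#' unfolding pattern seen in titin. Under high calcium the widths are
#' multiplied by `calcium_width_multiplier <= 1`, raising unfolding forces.
#' Refolding is not modelled (its rate is negligible while the strand
#' remains under load).
#'
#' @param k0 zero-force unfolding rate (1/s).
#' @param width_max,width_min barrier widths (nm) of the first and last
#'   proximal IG domain; widths are linearly interpolated in between.
#' @param n_domains number of proximal IG domains (must match the isoform).
#' @param widths optional explicit non-increasing width vector (nm);
#'   overrides `width_max`/`width_min`.
#' @param calcium_width_multiplier factor (<= 1) applied to all widths
#'   under high calcium; default 0.87 raises the mean unfolding force by
#'   roughly 15%.
#' @param temperature absolute temperature (K).
#' @return object of class `unfolding_params`.
#' @export
unfolding_params <- function(k0 = 1e-4, width_max = 0.25, width_min = 0.15,
                             n_domains = 50L, widths = NULL,
                             calcium_width_multiplier = 0.87,
                             temperature = DEFAULT_TEMPERATURE) {
  n_domains <- as.integer(n_domains)
  stopifnot(n_domains >= 1L, k0 > 0, temperature > 0,
            calcium_width_multiplier > 0, calcium_width_multiplier <= 1)
  if (is.null(widths)) {
    stopifnot(width_max > 0, width_min > 0, width_max >= width_min)
    widths <- seq(width_max, width_min, length.out = n_domains)
  }
  widths <- as.numeric(widths)
  if (length(widths) != n_domains)
    stop("widths must have one entry per proximal IG domain")
  if (any(widths <= 0)) stop("barrier widths must be positive")
  if (any(diff(widths) > 1e-12))
    stop("barrier widths must be non-increasing with domain index ",
         "(weak unfolding hierarchy)")
  structure(list(k0 = k0, widths = widths, n_domains = n_domains,
                 calcium_width_multiplier = calcium_width_multiplier,
                 temperature = temperature),
            class = "unfolding_params")
}

effective_widths <- function(params, calcium) {
  if (isTRUE(calcium)) params$widths * params$calcium_width_multiplier
  else params$widths
}

#' Bell-model unfolding rate of one proximal IG domain
#'
#' @param force tensile force on the strand (pN, >= 0).
#' @param domain_index domain index (1-based, 1 = widest barrier = unfolds
#'   first).
#' @param params an [unfolding_params()] object.
#' @param calcium logical; use the calcium-scaled barrier widths.
#' @return unfolding rate in 1/s (vectorised over `force`).
#' @export
unfolding_rate <- function(force, domain_index, params, calcium = FALSE) {
  stopifnot(inherits(params, "unfolding_params"))
  if (any(force < 0)) stop("force must be non-negative")
  domain_index <- as.integer(domain_index)
  if (any(domain_index < 1L) || any(domain_index > params$n_domains))
    stop("domain_index out of range 1..", params$n_domains)
  w <- effective_widths(params, calcium)[domain_index]
  kT <- BOLTZMANN_PN_NM * params$temperature
  params$k0 * exp(force * w / kT)
}

#' One Monte-Carlo unfolding step for a single titin strand
#'
#' Each still-folded proximal domain unfolds independently within `dt` with
#' probability `1 - exp(-k_i(force) dt)`; within a step unfolding proceeds
#' in hierarchy order (the state only tracks the count, and the first
#' still-folded domains are filled first). The count never decreases. If
#' the fastest rate times `dt` reaches 0.1 the step is subdivided
#' internally. Uses R's global random number generator.
#'
#' @param state a [titin_state()].
#' @param force tensile force driving unfolding (pN).
#' @param dt time step (s).
#' @param params an [unfolding_params()].
#' @param n_domains total number of proximal IG domains.
#' @param calcium logical; calcium-scaled widths.
#' @return the updated [titin_state()].
#' @export
mc_step <- function(state, force, dt, params,
                    n_domains = params$n_domains, calcium = FALSE) {
  stopifnot(inherits(state, "titin_state"), dt > 0, force >= 0)
  nu <- state$n_unfolded
  if (nu >= n_domains) return(state)
  w <- effective_widths(params, calcium)
  kT <- BOLTZMANN_PN_NM * params$temperature
  rates <- params$k0 * exp(force * w[(nu + 1L):n_domains] / kT)
  # independent two-state domains: substepping is statistically redundant,
  # so the substep count is capped (p saturates at 1 for huge hazards)
  n_sub <- min(max(1L, ceiling(max(rates) * dt / 0.1)), 1024L)
  dts <- dt / n_sub
  for (s in seq_len(n_sub)) {
    folded <- length(rates)
    if (!folded) break
    fired <- stats::runif(folded) < (1 - exp(-rates * dts))
    k <- sum(fired)
    if (k > 0) {
      nu <- nu + k
      rates <- rates[seq_len(folded - k) + k]
    }
  }
  state$n_unfolded <- as.integer(nu)
  state
}

# Vectorised ensemble Monte-Carlo update.
#
# nu: integer unfolding counts per strand; force: per-strand force (pN);
# returns the new counts. Exact per-domain Bernoulli sampling, but using a
# single uniform per strand to decide whether anything fires (the
# no-event probability is exp(-dt * sum of folded-domain rates)), and only
# then resolving which domains unfold by exact inversion of the
# first-success index plus independent draws for the remainder. Substeps
# internally when the fastest rate times dt reaches 0.1.
mc_step_counts <- function(nu, force, dt, params, calcium = FALSE) {
  n_dom <- params$n_domains
  w <- effective_widths(params, calcium)
  kT <- BOLTZMANN_PN_NM * params$temperature
  open <- nu < n_dom
  if (!any(open)) return(nu)
  # fastest rate: first folded domain at the largest force among open strands
  kmax <- params$k0 * exp(max(force[open]) * w[pmin(nu[open] + 1L, n_dom)] / kT)
  # quick skip: if even an upper bound on the total firing probability is
  # negligible, do not touch the random number stream
  if (sum(open) * n_dom * max(kmax) * dt < 1e-12) return(nu)
  n_sub <- min(max(1L, ceiling(max(kmax) * dt / 0.1)), 1024L)
  dts <- dt / n_sub
  for (s in seq_len(n_sub)) {
    open_idx <- which(nu < n_dom)
    if (!length(open_idx)) break
    # per-strand total folded rate via per-(force, nu) tail sums; distinct
    # forces are few because strands are solved in groups
    fo <- force[open_idx]
    nuo <- nu[open_idx]
    uf <- unique(fo)
    # tail_mat[m, j] = sum of rates of domains m..n_dom at force uf[j]
    tail_mat <- vapply(uf, function(fj)
      rev(cumsum(rev(params$k0 * exp(fj * w / kT)))), numeric(n_dom))
    fmatch <- match(fo, uf)
    total <- tail_mat[cbind(nuo + 1L, fmatch)]
    p_none <- exp(-dts * total)
    u <- stats::runif(length(open_idx))
    firing <- which(u >= p_none)
    for (i in firing) {
      idx <- open_idx[i]
      k_i <- params$k0 * exp(fo[i] * w[(nuo[i] + 1L):n_dom] / kT)
      # first-success index by inversion of the conditional survival
      surv <- exp(-dts * cumsum(k_i))              # P(no success in 1..m)
      wcond <- (u[i] - p_none[i]) / (1 - p_none[i])
      cond_surv <- (surv - p_none[i]) / (1 - p_none[i])
      first <- which(cond_surv <= 1 - wcond)[1]
      if (is.na(first)) first <- length(k_i)
      extra <- 0L
      if (first < length(k_i)) {
        later <- (first + 1L):length(k_i)
        extra <- sum(stats::runif(length(later)) <
                       (1 - exp(-k_i[later] * dts)))
      }
      nu[idx] <- min(n_dom, nu[idx] + 1L + extra)
    }
  }
  nu
}

# per-strand total unfolding rate: sum of Bell rates over still-folded
# domains at the strand's driving force (0 for fully unfolded strands)
strand_total_rates <- function(nu, force, params, calcium = FALSE) {
  n_dom <- params$n_domains
  w <- effective_widths(params, calcium)
  kT <- BOLTZMANN_PN_NM * params$temperature
  out <- numeric(length(nu))
  open <- which(nu < n_dom)
  if (!length(open)) return(out)
  fo <- force[open]
  uf <- unique(fo)
  K <- params$k0 * exp(outer(w[n_dom:1] / kT, uf))   # reversed domain order
  tail_mat <- apply(K, 2L, cumsum)[n_dom:1, , drop = FALSE]
  out[open] <- tail_mat[cbind(nu[open] + 1L, match(fo, uf))]
  out
}

#' Ensemble configuration for Monte-Carlo titin simulations
#'
#' @param n_strands number of independent titin strands (the canonical
#'   normalization treats 500 strands as one half sarcomere of 1 um^2
#'   cross-section).
#' @param seed integer seed for R's random number generator.
#' @param dt simulation time step (s).
#' @param strands_per_um2 strand count equivalent to 1 um^2 cross-section,
#'   used to convert mean strand force (pN) to stress (nN/um^2).
#' @param record_every record the trace every this many steps.
#' @return object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_strands = 500L, seed = 1L, dt = 1e-4,
                            strands_per_um2 = 500,
                            record_every = 50L) {
  n_strands <- as.integer(n_strands)
  stopifnot(n_strands >= 1L, dt > 0, strands_per_um2 > 0, record_every >= 1L)
  structure(list(n_strands = n_strands, seed = as.integer(seed), dt = dt,
                 strands_per_um2 = strands_per_um2,
                 record_every = as.integer(record_every)),
            class = "ensemble_config")
}
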