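# Parameter estimation from passive stretch-shorten hysteresis loops.
#
# A passive loop separates into four parts: (1) stretch below the
# inflection where no IG domains unfold yet; (2) stretch with progressive
# unfolding; (3) early shortening, an indefinite state where unfolding may
# still continue while force drops sharply; (4) late shortening where the
# unfolding count is frozen and a single fixed-composition chain follows
# the data exactly. Region 1 identifies the folded-IG persistence length
# and the PEVK persistence length and stretch modulus; region 4 identifies
# the number of unfolded domains and their persistence length. Region 3 is
# excluded from all fits.

#' Predicted passive stress along a sarcomere-length grid
#'
#' Equal-force chain solution per length, converted to ensemble stress via
#' the strand surface density.
#'
#' @param sl_um sarcomere lengths (um).
#' @param iso a [titin_isoform()].
#' @param n_unfolded unfolded proximal IG count used for every length.
#' @param strands_per_um2 strand count per um^2 cross-section.
#' @return stress in nN/um^2 (same length as `sl_um`).
#' @export
passive_stress_curve <- function(sl_um, iso, n_unfolded = 0L,
                                 strands_per_um2 = 500) {
  n <- length(sl_um)
  f <- solve_chain_force(sl_um * 500, iso,
                         rep(as.integer(n_unfolded), n), rep(NA_real_, n))
  f * strands_per_um2 / 1000
}

#' Synthetic passive hysteresis dataset
#'
#' Simulates a passive stretch-shorten cycle of a titin strand ensemble
#' (default: a single strand, which keeps the integer unfolding count of
#' the shortening limb well-defined), subsamples it to `n_samples` points
#' and applies multiplicative Gaussian noise. Stands in for myofibril
#' hysteresis measurements when fitting is exercised without lab data.
#'
#' @param iso ground-truth [titin_isoform()].
#' @param unfold ground-truth [unfolding_params()].
#' @param n_samples number of retained (length, stress) samples.
#' @param noise_sd multiplicative noise standard deviation (e.g. 0.02).
#' @param seed integer seed.
#' @param start_um,stretch_to_um loop start and turnaround sarcomere
#'   lengths (um).
#' @param speed ramp speed (nm/s per sarcomere length).
#' @param n_strands ensemble size.
#' @param strands_per_um2 stress normalization.
#' @param dt simulation time step (s).
#' @return a `hysteresis_dataset`: data frame with `sarcomere_um`,
#'   `stress_nN_um2`, `phase` (`"stretch"`/`"shorten"`); attribute `truth`
#'   records the generating parameters and the final unfolding count.
#' @export
synthesize_hysteresis <- function(iso = titin_isoform(),
                                  unfold = unfolding_params(
                                    n_domains = iso$n_proximal_ig),
                                  n_samples = 100L, noise_sd = 0.02,
                                  seed = 1L,
                                  start_um = 2.4, stretch_to_um = 3.8,
                                  speed = 100, n_strands = 1L,
                                  strands_per_um2 = 500, dt = 1e-3) {
  proto <- protocol(phase_set_length(start_um),
                    phase_ramp(stretch_to_um, speed),
                    phase_ramp(start_um, speed),
                    name = "passive_hysteresis")
  # choose the recording cadence so the trace itself is the uniform sample
  # grid (non-uniform spacing would alias into the unfolding-step detector)
  delta <- (stretch_to_um - start_um) * 1000
  t_total <- delta / (speed * start_um) + delta / (speed * stretch_to_um)
  rec_every <- max(1L, round(t_total / (dt * (n_samples - 1L))))
  cfg <- ensemble_config(n_strands = n_strands, seed = seed, dt = dt,
                         strands_per_um2 = strands_per_um2,
                         record_every = rec_every)
  tr <- ensemble_trace(proto, iso, unfold, cfg, seed = seed)
  tr <- tr[!duplicated(tr$time_s), ]
  if (nrow(tr) > n_samples) tr <- tr[seq_len(n_samples), ]
  turnaround <- tr$time_s[which.max(tr$sarcomere_um)]
  phase <- ifelse(tr$time_s <= turnaround, "stretch", "shorten")
  noise <- if (noise_sd > 0) 1 + noise_sd * stats::rnorm(nrow(tr)) else 1
  out <- data.frame(sarcomere_um = tr$sarcomere_um,
                    stress_nN_um2 = tr$titin_nN_um2 * noise,
                    phase = phase)
  structure(out,
            truth = list(folded_pl = iso$folded_ig$persistence_length,
                         unfolded_pl = iso$unfolded_ig$persistence_length,
                         pevk_pl = iso$pevk$persistence_length,
                         pevk_modulus = iso$pevk$elastic_modulus,
                         n_unfolded_final = utils::tail(tr$mean_unfolded, 1),
                         first_unfold_time =
                           tr$time_s[which(tr$mean_unfolded > 0)[1]],
                         strands_per_um2 = strands_per_um2),
            class = c("hysteresis_dataset", "data.frame"))
}

# Sequential detection of the first unfolding drop in a log-stress series.
# Unfolding events are step-like drops: each first difference is compared
# with the local trend (median of the preceding k differences), normalised
# by the running median absolute deviation of the trend-corrected
# differences, and accumulated in a one-sided CUSUM with drift 0.5. The
# change point is back-dated to the start of the triggering run, which
# locates the first unfolding event to within a sample or two even when a
# single drop is only a few noise standard deviations deep. Returns the
# index of the first post-event sample, or NA when no change is detected.
# (A curvature/second-derivative detector is nearly blind to steps, which
# is why the trend-corrected first difference is used.)
detect_drop_onset <- function(y, threshold = 5, k = 8L,
                              min_baseline = 10L) {
  n <- length(y)
  if (n < k + min_baseline + 2L) return(NA_integer_)
  d1 <- diff(y)
  dev <- rep(NA_real_, length(d1))
  cusum <- 0
  run_start <- NA_integer_
  base_frozen <- NA_real_
  h <- k %/% 2L
  c1 <- (1 + h) / 2; c2 <- (h + 1 + k) / 2
  for (j in (k + 1L):length(d1)) {
    # one-step-ahead robust-linear extrapolation of the local slope trend:
    # two half-window medians give a slope estimate that neither lags a
    # smoothly concave stress curve (which would accumulate spurious
    # drift) nor gets dragged by a single unfolding drop in the window
    win <- d1[(j - k):(j - 1L)]
    m1 <- stats::median(win[1:h]); m2 <- stats::median(win[(h + 1L):k])
    trend <- m2 + (m2 - m1) / (c2 - c1) * (k + 1 - c2)
    dev[j] <- d1[j] - trend
    if (j - k < min_baseline) next
    # noise scale from recent QUIESCENT samples only: while a CUSUM run is
    # active the deviations contain unfolding drops and would inflate the
    # scale, stalling detection. The scale is local (multiplicative noise
    # grows along the limb) with a floor at 2% of the typical step so that
    # noise-free data, whose deviations collapse to discretisation level,
    # do not self-trigger.
    if (cusum <= 0 || is.na(base_frozen)) {
      clean <- dev[max(k + 1L, j - 15L):(j - 1L)]
      base_frozen <- max(stats::mad(clean, na.rm = TRUE),
                         0.02 * stats::median(abs(d1[1:(j - 1L)])), 1e-12)
    }
    # two triggers: a single clear drop (isolated early events are sparse,
    # so a decaying CUSUM alone would walk past them), or a CUSUM of
    # several marginal drops in close succession
    if (dev[j] < -3.5 * base_frozen) return(j + 1L)
    inc <- -dev[j] / base_frozen - 0.5
    if (cusum <= 0 && inc > 0) run_start <- j
    cusum <- max(0, cusum + inc)
    if (cusum == 0) run_start <- NA_integer_
    if (cusum >= threshold) return(run_start + 1L)
  }
  NA_integer_
}

# Savitzky-Golay second-derivative filter weights (local quadratic fit,
# symmetric window); returns the filtered second difference of y
sg_second_deriv <- function(y, window = 11L) {
  if (window %% 2L == 0L) window <- window + 1L
  m <- (window - 1L) %/% 2L
  i <- -m:m
  w <- i^2 - mean(i^2)
  w <- 2 * w / sum(w * i^2)          # coefficients of the quadratic term x2
  n <- length(y)
  out <- rep(NA_real_, n)
  if (n < window) return(out)
  for (j in (m + 1L):(n - m)) out[j] <- sum(w * y[(j - m):(j + m)])
  out
}

# Model-based onset detection on the stretch limb: the pre-onset samples
# follow the zero-unfolding chain model exactly, so the model is fitted to
# an expanding front window and the onset is the first sample that falls
# clearly below the one-step model prediction (one-sided: unfolding only
# ever lowers the stress) and stays below it over a short confirmation
# window. Returns the index of the first post-onset sample or NA.
detect_onset_model <- function(sl, stress, iso_template, strands_per_um2,
                               m0 = 15L, refit_every = 8L) {
  n <- length(sl)
  if (n < m0 + 3L) return(NA_integer_)
  par <- c(iso_template$folded_ig$persistence_length,
           iso_template$pevk$persistence_length,
           iso_template$pevk$elastic_modulus)
  make_iso <- function(p) {
    iso <- iso_template
    iso$folded_ig$persistence_length <- p[1]
    iso$pevk$persistence_length <- p[2]
    iso$pevk$elastic_modulus <- p[3]
    iso
  }
  fit_window <- function(m, start) {
    sel <- seq_len(m)
    s0 <- 0.02 * max(stress[sel])
    fn <- function(p) {
      mdl <- passive_stress_curve(sl[sel], make_iso(p), 0L, strands_per_um2)
      (mdl - stress[sel]) / (abs(stress[sel]) + s0)
    }
    out <- tryCatch(lm_fit(fn, start, max_iter = 60L), error = function(e)
      NULL)
    if (is.null(out)) start else out$par
  }
  par <- fit_window(m0, par)
  model_at <- function(j) passive_stress_curve(sl[j], make_iso(par), 0L,
                                               strands_per_um2)
  rel_resid <- function(j) stress[j] / pmax(model_at(j), 1e-9) - 1
  sigma <- max(stats::sd(rel_resid(seq_len(m0))), 1e-4)
  last_fit <- m0
  for (j in (m0 + 1L):n) {
    r_j <- rel_resid(j)
    thr <- max(3.5 * sigma, 0.06)
    if (r_j < -thr) {
      confirm <- seq(j, min(j + 2L, n))
      if (mean(rel_resid(confirm)) < -max(2.5 * sigma, 0.04))
        return(j)
    }
    if (j - last_fit >= refit_every) {
      par <- fit_window(j, par)
      sigma <- max(stats::sd(rel_resid(seq_len(j))), 1e-4)
      last_fit <- j
    }
  }
  NA_integer_
}

#' Classify hysteresis samples into the four loop regions
#'
#' Region 1/2 boundary (the unfolding inflection on the stretch limb) is
#' placed just before the first smoothed-second-difference spike of the
#' stress signal (the signature of the first unfolding event); regions 3/4
#' are separated at the last unfolding-like spike of the shortening limb (second-difference magnitude above
#' `spike_mult` median absolute deviations), falling back to the first
#' quarter of the shortening limb when no spike is detected. A
#' user-supplied `breakpoint` (stretch-limb sample index) overrides the
#' automatic inflection.
#'
#' @param dataset a `hysteresis_dataset` (or data frame with the same
#'   columns).
#' @param window Savitzky-Golay window (samples).
#' @param spike_mult CUSUM detection threshold in noise-scale units.
#' @param breakpoint optional manual region-1/2 boundary index (within the
#'   stretch limb).
#' @param iso_template isoform providing structure and starting values for
#'   the model-based onset detector.
#' @param strands_per_um2 stress normalization of the data.
#' @return the dataset with an integer `region` column (1-4).
#' @export
classify_regions <- function(dataset, window = 11L, spike_mult = 5,
                             breakpoint = NULL,
                             iso_template = titin_isoform(),
                             strands_per_um2 = 500) {
  stopifnot(all(c("sarcomere_um", "stress_nN_um2", "phase") %in%
                  names(dataset)))
  stretch <- which(dataset$phase == "stretch")
  shorten <- which(dataset$phase == "shorten")
  if (!length(stretch) || any(diff(stretch) != 1L) ||
      (length(shorten) && min(shorten) < max(stretch)))
    stop("dataset must contain a contiguous stretch phase followed by a ",
         "shorten phase")
  region <- integer(nrow(dataset))
  # spike detection works on log stress: multiplicative measurement noise
  # becomes additive there, so unfolding drops stand out uniformly
  logy <- log(pmax(dataset$stress_nN_um2, 0) +
                0.02 * max(dataset$stress_nN_um2))

  if (is.null(breakpoint)) {
    if (length(stretch) < window + 10L) {
      warning("stretch limb too short for onset detection; ",
              "treating the whole limb as region 1")
      cut1 <- length(stretch)
    } else {
      if (length(stretch) >= 18L) {
        # primary: model-based detection (NA means "no unfolding", which
        # is trusted -- the zero-unfolding model covered the whole limb)
        j <- detect_onset_model(dataset$sarcomere_um[stretch],
                                dataset$stress_nN_um2[stretch],
                                iso_template, strands_per_um2)
      } else {
        j <- detect_drop_onset(logy[stretch], threshold = spike_mult)
      }
      # a monotone loop with no unfolding has no drop: region 2 is empty
      cut1 <- if (is.na(j)) length(stretch) else max(1L, j - 1L)
    }
  } else {
    cut1 <- as.integer(breakpoint)
  }
  cut1 <- max(1L, min(cut1, length(stretch)))
  region[stretch[seq_len(cut1)]] <- 1L
  if (cut1 < length(stretch))
    region[stretch[(cut1 + 1L):length(stretch)]] <- 2L

  if (length(shorten)) {
    # scan backwards: the clean late-shortening tail provides the baseline,
    # and in reversed time an unfolding drop appears as an upward jump
    jr <- detect_drop_onset(-rev(logy[shorten]), threshold = spike_mult)
    cut3 <- if (!is.na(jr)) min(length(shorten) - jr + 2L,
                                length(shorten) - 1L)
            else max(1L, length(shorten) %/% 4L)
    region[shorten[seq_len(cut3)]] <- 3L
    if (cut3 < length(shorten))
      region[shorten[(cut3 + 1L):length(shorten)]] <- 4L
  }
  dataset$region <- region
  dataset
}

# Levenberg-Marquardt least squares on log-transformed positive parameters.
# fn(theta) returns the residual vector; returns list(par, cost, grad_norm,
# converged, hessian).
lm_fit <- function(fn, start, max_iter = 100L, tol = 1e-10) {
  th <- log(start)
  r <- fn(exp(th))
  cost <- sum(r^2)
  lambda <- 1e-3
  conv <- FALSE
  J <- NULL
  for (it in seq_len(max_iter)) {
    # forward-difference Jacobian in log space
    J <- vapply(seq_along(th), function(k) {
      h <- 1e-6
      thk <- th; thk[k] <- thk[k] + h
      (fn(exp(thk)) - r) / h
    }, numeric(length(r)))
    g <- crossprod(J, r)
    if (sqrt(sum(g^2)) < 1e-8) { conv <- TRUE; break }
    A <- crossprod(J)
    repeat {
      step <- tryCatch(solve(A + lambda * diag(diag(A), nrow(A)), -g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        th_new <- th + drop(step)
        r_new <- fn(exp(th_new))
        cost_new <- sum(r_new^2)
        if (is.finite(cost_new) && cost_new <= cost) {
          improve <- cost - cost_new
          th <- th_new; r <- r_new; cost <- cost_new
          lambda <- max(lambda * 0.3, 1e-12)
          if (improve < tol * (1 + cost)) conv <- TRUE
          break
        }
      }
      lambda <- lambda * 4
      if (lambda > 1e12) { conv <- TRUE; break }
    }
    if (conv) break
  }
  list(par = exp(th), cost = cost, grad_norm = sqrt(sum(crossprod(J, r)^2)),
       converged = conv, jtj = crossprod(J), residuals = r)
}

region_residual_fn <- function(data_sl, data_stress, iso_template,
                               n_unfolded, strands_per_um2) {
  s0 <- 0.02 * max(abs(data_stress))
  function(theta_iso) {
    model <- passive_stress_curve(data_sl, theta_iso, n_unfolded,
                                  strands_per_um2)
    (model - data_stress) / (abs(data_stress) + s0)
  }
}

#' Fit region-1 parameters of a hysteresis loop
#'
#' Least-squares (Levenberg-Marquardt, multi-start, log-parameterised) fit
#' of the folded-IG persistence length and the PEVK persistence length and
#' stretch modulus to the pre-unfolding stretch samples, with the chain
#' model at zero unfolded domains. Residuals are relative (the measurement
#' noise is multiplicative).
#'
#' @param dataset a classified `hysteresis_dataset` (see
#'   [classify_regions()]).
#' @param iso_template a [titin_isoform()] providing structure and starting
#'   values; fitted parameters replace `folded_pl`, `pevk_pl`,
#'   `pevk_modulus`.
#' @param strands_per_um2 stress normalization used by the data.
#' @param n_starts number of jittered multi-starts.
#' @param jitter_sd log-space jitter of the starting values.
#' @param seed seed for the start jitter.
#' @return object of class `calibration_result` with elements `folded_pl`,
#'   `pevk_pl`, `pevk_modulus`, their approximate standard errors,
#'   `residual_norm`, `converged` and the fitted isoform `iso`.
#' @export
fit_region1 <- function(dataset, iso_template = titin_isoform(),
                        strands_per_um2 = 500, n_starts = 5L,
                        jitter_sd = 0.35, seed = 42L) {
  if (!"region" %in% names(dataset))
    stop("dataset must be classified first (classify_regions)")
  sel <- dataset$region == 1L & dataset$stress_nN_um2 >
    0.005 * max(dataset$stress_nN_um2[dataset$region == 1L])
  if (sum(sel) < 9L)
    stop("need at least 9 informative region-1 samples (3 per parameter), ",
         "got ", sum(sel))
  sl <- dataset$sarcomere_um[sel]
  stress <- dataset$stress_nN_um2[sel]
  make_iso <- function(p) {
    iso <- iso_template
    iso$folded_ig$persistence_length <- p[1]
    iso$pevk$persistence_length <- p[2]
    iso$pevk$elastic_modulus <- p[3]
    iso
  }
  rf <- region_residual_fn(sl, stress, iso_template, 0L, strands_per_um2)
  fn <- function(p) rf(make_iso(p))
  start0 <- c(iso_template$folded_ig$persistence_length,
              iso_template$pevk$persistence_length,
              iso_template$pevk$elastic_modulus)
  set.seed(as.integer(seed))
  starts <- c(list(start0), lapply(seq_len(n_starts - 1L), function(i)
    start0 * exp(stats::rnorm(3, sd = jitter_sd))))
  fits <- lapply(starts, function(s)
    tryCatch(lm_fit(fn, s), error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("region-1 fit failed from every start")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "cost"))]]
  if (!best$converged)
    stop("region-1 Levenberg-Marquardt did not converge (gradient norm ",
         format(best$grad_norm), ")")
  p <- best$par
  dof <- max(1L, length(best$residuals) - 3L)
  sigma2 <- best$cost / dof
  cov_log <- tryCatch(sigma2 * solve(best$jtj), error = function(e)
    matrix(NA_real_, 3, 3))
  se <- sqrt(pmax(diag(cov_log), 0)) * p   # delta method from log scale
  structure(list(folded_pl = p[1], pevk_pl = p[2], pevk_modulus = p[3],
                 se = stats::setNames(se, c("folded_pl", "pevk_pl",
                                            "pevk_modulus")),
                 residual_norm = sqrt(best$cost), converged = best$converged,
                 n_samples = length(sl), iso = make_iso(p)),
            class = "calibration_result")
}

#' Fit region-4 parameters of a hysteresis loop
#'
#' With region-1 parameters fixed, the late-shortening samples identify
#' the frozen number of unfolded proximal IG domains and their persistence
#' length: the integer count is scanned exhaustively over
#' `0..n_proximal_ig`, with an inner one-dimensional least-squares
#' optimisation of the unfolded persistence length per candidate.
#'
#' @param dataset a classified `hysteresis_dataset`.
#' @param region1 a `calibration_result` from [fit_region1()].
#' @param strands_per_um2 stress normalization used by the data.
#' @param pl_bounds search interval (nm) for the unfolded-IG persistence
#'   length.
#' @return a `calibration_result` extending `region1` with `n_unfolded`,
#'   `unfolded_pl`, and the exhaustive per-candidate objective
#'   (`scan_objective`).
#' @export
fit_region4 <- function(dataset, region1, strands_per_um2 = 500,
                        pl_bounds = c(0.05, 10)) {
  stopifnot(inherits(region1, "calibration_result"))
  if (!"region" %in% names(dataset))
    stop("dataset must be classified first (classify_regions)")
  sel <- dataset$region == 4L & dataset$stress_nN_um2 >
    0.005 * max(dataset$stress_nN_um2)
  if (sum(sel) < 3L) stop("need at least 3 informative region-4 samples")
  sl <- dataset$sarcomere_um[sel]
  stress <- dataset$stress_nN_um2[sel]
  iso0 <- region1$iso
  s0 <- 0.02 * max(abs(stress))
  objective <- function(nu, pl_u) {
    iso <- iso0
    iso$unfolded_ig$persistence_length <- pl_u
    m <- passive_stress_curve(sl, iso, nu, strands_per_um2)
    sum(((m - stress) / (abs(stress) + s0))^2)
  }
  n_max <- iso0$n_proximal_ig
  scan <- data.frame(n_unfolded = 0:n_max, objective = NA_real_,
                     unfolded_pl = NA_real_)
  for (k in seq_len(nrow(scan))) {
    nu <- scan$n_unfolded[k]
    if (nu == 0L) {
      scan$objective[k] <- objective(0L, iso0$unfolded_ig$persistence_length)
      scan$unfolded_pl[k] <- iso0$unfolded_ig$persistence_length
    } else {
      opt <- stats::optimize(function(p) objective(nu, p),
                             interval = pl_bounds, tol = 1e-5)
      scan$objective[k] <- opt$objective
      scan$unfolded_pl[k] <- opt$minimum
    }
  }
  best <- which.min(scan$objective)
  out <- region1
  out$n_unfolded <- scan$n_unfolded[best]
  out$unfolded_pl <- scan$unfolded_pl[best]
  out$region4_residual_norm <- sqrt(scan$objective[best])
  out$scan_objective <- scan
  out$iso$unfolded_ig$persistence_length <- out$unfolded_pl
  out
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("passive-hysteresis calibration\n")
  cat(sprintf("  folded IG pl  %.4g nm (se %.2g)\n", x$folded_pl,
              x$se[["folded_pl"]]))
  cat(sprintf("  PEVK pl       %.4g nm (se %.2g)\n", x$pevk_pl,
              x$se[["pevk_pl"]]))
  cat(sprintf("  PEVK K0       %.4g pN (se %.2g)\n", x$pevk_modulus,
              x$se[["pevk_modulus"]]))
  if (!is.null(x$n_unfolded)) {
    cat(sprintf("  unfolded count %d, unfolded IG pl %.4g nm\n",
                x$n_unfolded, x$unfolded_pl))
  }
  cat(sprintf("  region-1 residual norm %.3g (%d samples)\n",
              x$residual_norm, x$n_samples))
  invisible(x)
}
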