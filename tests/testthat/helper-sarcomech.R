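# shared fixtures: built once per test session

wlc300 <- wlc_params(1, 100, temperature = 300)
ewlc300 <- ewlc_params(1, 100, 1000, temperature = 300)

default_iso <- titin_isoform()
default_unfold <- unfolding_params()

# cross-bridge parameter construction runs a steady-state calibration;
# build once and share
shared_xb <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- crossbridge_params()
    cache
  }
})

# memoised expensive simulation runs shared between test blocks
run_cache <- new.env(parent = emptyenv())
cached_run <- function(key, expr) {
  if (!exists(key, envir = run_cache)) {
    assign(key, force(expr), envir = run_cache)
  }
  get(key, envir = run_cache)
}

# independent bisection oracle for the equal-force chain solve: brackets on
# the common force and sums the inverse force laws per compartment
chain_force_oracle <- function(hsl, iso, n_unfolded = 0L, frozen = NULL,
                               tol = 1e-12) {
  total_len <- function(f) {
    prox <- if (is.null(frozen)) {
      (iso$n_proximal_ig - n_unfolded) *
        wlc_extension(f, iso$folded_ig) +
        n_unfolded * wlc_extension(f, iso$unfolded_ig)
    } else frozen
    prox + ewlc_extension(f, iso$pevk) +
      iso$distal_end_filament_length + iso$half_a_band_length +
      f / iso$a_band_stiffness
  }
  if (total_len(1e-6) >= hsl) return(0)
  lo <- 0; hi <- 1
  while (total_len(hi) < hsl) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (total_len(mid) < hsl) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# independent bisection oracle for the implicit extensible-WLC equation
ewlc_force_oracle <- function(x, p) {
  kT <- 1.380649e-2 * p$temperature
  shape <- function(u) 1 / (4 * (1 - u)^2) - 0.25 + u
  g <- function(f) kT / p$persistence_length *
    shape(x / p$contour_length - f / p$elastic_modulus) - f
  lo <- 0; hi <- 1
  while (g(hi) > 0) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
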