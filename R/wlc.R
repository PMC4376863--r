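#' @keywords internal
"_PACKAGE"

#' Boltzmann constant in pN nm / K
#'
#' All mechanics in this package use single-molecule units: nanometres for
#' length, piconewtons for force, seconds for time and kelvin for
#' temperature. Stress is reported in nN/um^2 (numerically equal to kPa).
#'
#' @export
BOLTZMANN_PN_NM <- 1.380649e-2

#' Default absolute temperature (K)
#'
#' Room-temperature myofibril experiments; configurable in every parameter
#' constructor.
#'
#' @export
DEFAULT_TEMPERATURE <- 293.15

#' Worm-like-chain segment parameters
#'
#' Entropic-elasticity parameters of one polymer segment in the
#' interpolation form of the worm-like chain (WLC): the restoring force at
#' end-to-end extension `x` is
#' \deqn{f = \frac{k_B T}{p}\left(\frac{1}{4(1-x/L)^2} - \frac14 +
#'   \frac{x}{L}\right)}
#' with persistence length `p` and contour length `L`.
#'
#' @param persistence_length persistence length in nm (> 0); scales force.
#' @param contour_length contour length in nm (> 0); the extension at which
#'   force diverges.
#' @param temperature absolute temperature in K (> 0).
#' @return an object of class `wlc_params`.
#' @seealso [wlc_force()], [ewlc_params()]
#' @export
wlc_params <- function(persistence_length, contour_length,
                       temperature = DEFAULT_TEMPERATURE) {
  stopifnot(is.numeric(persistence_length), length(persistence_length) == 1L,
            is.numeric(contour_length), length(contour_length) == 1L,
            is.numeric(temperature), length(temperature) == 1L)
  if (!is.finite(persistence_length) || persistence_length <= 0)
    stop("persistence_length must be a positive finite number (nm)")
  if (!is.finite(contour_length) || contour_length <= 0)
    stop("contour_length must be a positive finite number (nm)")
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be a positive finite number (K)")
  structure(list(persistence_length = persistence_length,
                 contour_length = contour_length,
                 temperature = temperature),
            class = "wlc_params")
}

#' Extensible worm-like-chain parameters
#'
#' WLC augmented by an enthalpic stretch modulus `K0` (pN). The force `f` at
#' extension `x` solves the implicit equation obtained by replacing the
#' fractional extension `x/L` with `x/L - f/K0` in the WLC interpolation
#' formula. Extensions beyond the contour length are then admissible: the
#' backbone itself stretches. Used for titin's PEVK segment.
#'
#' @inheritParams wlc_params
#' @param elastic_modulus enthalpic (stretch) modulus K0 in pN (> 0).
#' @return an object of class `ewlc_params` (also inherits `wlc_params`).
#' @export
ewlc_params <- function(persistence_length, contour_length, elastic_modulus,
                        temperature = DEFAULT_TEMPERATURE) {
  base <- wlc_params(persistence_length, contour_length, temperature)
  if (!is.numeric(elastic_modulus) || length(elastic_modulus) != 1L ||
      !is.finite(elastic_modulus) || elastic_modulus <= 0)
    stop("elastic_modulus must be a positive finite number (pN)")
  base$elastic_modulus <- elastic_modulus
  class(base) <- c("ewlc_params", "wlc_params")
  base
}

# dimensionless WLC interpolation formula h(u) and derivative, u in [0, 1)
wlc_shape <- function(u) 1 / (4 * (1 - u)^2) - 0.25 + u
wlc_shape_deriv <- function(u) 1 / (2 * (1 - u)^3) + 1

# inverse of wlc_shape: unique u in [0, 1) with h(u) = phi, phi >= 0.
# Vectorised safeguarded Newton; h is strictly increasing and convex.
wlc_shape_inverse <- function(phi) {
  if (any(phi < 0)) stop("wlc_shape_inverse: phi must be non-negative")
  big <- phi > 1
  u <- (2 / 3) * phi
  if (any(big)) u[big] <- 1 - 1 / (2 * sqrt(phi[big]))
  for (i in 1:100) {
    om <- 1 - u
    r <- 1 / (4 * om * om) - 0.25 + u - phi
    u_new <- u - r / (1 / (2 * om * om * om) + 1)
    # keep iterates inside (0, 1); bisect towards the boundary on overshoot
    if (any(bad <- (u_new <= 0 | u_new >= 1)))
      u_new[bad] <- (u[bad] + (u_new[bad] >= 1)) / 2
    if (max(abs(u_new - u)) <= 1e-14) { u <- u_new; break }
    u <- u_new
  }
  u
}

#' WLC force at a given extension
#'
#' @param extension end-to-end extension in nm; must satisfy
#'   `0 <= extension < contour_length` (the entropic force diverges at the
#'   contour length, and the model is undefined beyond it).
#' @param params a [wlc_params()] object.
#' @return force in pN (vectorised over `extension`).
#' @examples
#' p <- wlc_params(1, 100, temperature = 300)
#' wlc_force(50, p)  # ~5.18 pN
#' @export
wlc_force <- function(extension, params) {
  stopifnot(inherits(params, "wlc_params"))
  if (any(!is.finite(extension)))
    stop("extension must be finite")
  if (any(extension < 0))
    stop("extension must be non-negative")
  if (any(extension >= params$contour_length))
    stop("extension must be strictly below the contour length (",
         params$contour_length, " nm)")
  kT <- BOLTZMANN_PN_NM * params$temperature
  kT / params$persistence_length * wlc_shape(extension / params$contour_length)
}

#' WLC extension at a given force (inverse force law)
#'
#' Solves the WLC interpolation formula for the unique extension in
#' `[0, contour_length)` producing the requested force.
#'
#' @param force force in pN, `>= 0` (vectorised).
#' @param params a [wlc_params()] object.
#' @return extension in nm.
#' @export
wlc_extension <- function(force, params) {
  stopifnot(inherits(params, "wlc_params"))
  if (any(!is.finite(force)) || any(force < 0))
    stop("force must be finite and non-negative")
  kT <- BOLTZMANN_PN_NM * params$temperature
  phi <- force * params$persistence_length / kT
  params$contour_length * wlc_shape_inverse(phi)
}

#' Extensible WLC force at a given extension
#'
#' Solves the implicit modified-WLC equation
#' `f = (kT/p) * h(x/L - f/K0)` for `f >= 0`. The left-hand side is
#' decreasing in the effective fractional extension argument through
#' `-f/K0`, so the equation has a unique root, found by safeguarded Newton
#' on the (strictly increasing) inverse map with geometric bracket growth.
#'
#' @param extension end-to-end extension in nm, `>= 0`; may exceed the
#'   contour length thanks to the enthalpic term.
#' @param params an [ewlc_params()] object.
#' @return force in pN (vectorised over `extension`).
#' @export
ewlc_force <- function(extension, params) {
  stopifnot(inherits(params, "ewlc_params"))
  if (any(!is.finite(extension)) || any(extension < 0))
    stop("extension must be finite and non-negative")
  vapply(extension, ewlc_force_scalar, numeric(1), params = params)
}

ewlc_force_scalar <- function(x, params) {
  if (x == 0) return(0)
  # g(f) = ewlc_extension(f) - x is strictly increasing from -x; bracket then
  # bisect/Newton via uniroot (Brent) for robustness.
  hi <- max(1, wlc_force(min(x, 0.99 * params$contour_length),
                         strip_ewlc(params)))
  it <- 0
  while (ewlc_extension(hi, params) < x) {
    hi <- hi * 2
    it <- it + 1
    if (it > 200)
      stop("ewlc_force: failed to bracket a root at extension ", x,
           " nm (grew force bound to ", hi, " pN)")
  }
  stats::uniroot(function(f) ewlc_extension(f, params) - x,
                 lower = 0, upper = hi, tol = 1e-12 * (1 + hi))$root
}

strip_ewlc <- function(params) {
  structure(list(persistence_length = params$persistence_length,
                 contour_length = params$contour_length,
                 temperature = params$temperature),
            class = "wlc_params")
}

#' Extensible WLC extension at a given force (inverse force law)
#'
#' Closed-form modulo the WLC shape inverse: for a given force the effective
#' fractional extension is `u = h^{-1}(f p / kT)` and the extension is
#' `x = L (u + f/K0)`.
#'
#' @param force force in pN, `>= 0` (vectorised).
#' @param params an [ewlc_params()] object.
#' @return extension in nm.
#' @export
ewlc_extension <- function(force, params) {
  stopifnot(inherits(params, "ewlc_params"))
  if (any(!is.finite(force)) || any(force < 0))
    stop("force must be finite and non-negative")
  kT <- BOLTZMANN_PN_NM * params$temperature
  u <- wlc_shape_inverse(force * params$persistence_length / kT)
  params$contour_length * (u + force / params$elastic_modulus)
}
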