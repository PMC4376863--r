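#' Titin isoform definition for one half-sarcomere strand
#'
#' Structural composition of the I-band region of a single titin molecule,
#' modelled as serial compartments: `n_proximal_ig` proximal immunoglobulin
#' (IG) domains (each a WLC, folded contour 4.5 nm, gaining 26 nm of contour
#' upon unfolding), the PEVK segment (extensible WLC, contour 0.36 nm per
#' residue), the distal IG domains aggregated into one non-compliant end
#' filament, and half of the A-band treated as a very stiff linear spring.
#' Defaults describe the 3,400-kD rabbit psoas isoform: 50 proximal IG
#' domains, 26 distal IG domains, 800 PEVK residues.
#'
#' Persistence lengths and the PEVK stretch modulus are not structurally
#' fixed; the defaults here are provisional single-molecule-scale values
#' intended to be replaced by [fit_region1()]/[fit_region4()] estimates
#' from passive hysteresis data.
#'
#' @param n_proximal_ig number of proximal IG domains.
#' @param n_distal_ig number of distal IG domains (non-compliant).
#' @param n_pevk_residues number of PEVK residues.
#' @param folded_pl,unfolded_pl,pevk_pl persistence lengths (nm) of folded
#'   IG, unfolded IG and PEVK compartments.
#' @param pevk_modulus PEVK enthalpic modulus K0 (pN).
#' @param folded_contour contour length of one folded IG domain (nm).
#' @param unfolding_gain contour length gained by one unfolding event (nm).
#' @param residue_contour PEVK contour length per residue (nm).
#' @param distal_end_filament_length length of the rigid distal end filament
#'   (nm); default treats the 26 distal domains at their folded contour.
#' @param half_a_band_length half the A-band length d (nm).
#' @param a_band_stiffness A-band spring stiffness (pN/nm); stiff but finite
#'   so the chain solve stays smooth.
#' @param temperature absolute temperature (K).
#' @param calcium_force_factor multiplicative increase of the titin force
#'   law under high calcium (see [apply_calcium()]).
#' @return object of class `titin_isoform`.
#' @export
titin_isoform <- function(n_proximal_ig = 50L,
                          n_distal_ig = 26L,
                          n_pevk_residues = 800L,
                          folded_pl = 10,
                          unfolded_pl = 0.65,
                          pevk_pl = 1.0,
                          pevk_modulus = 150,
                          folded_contour = 4.5,
                          unfolding_gain = 26,
                          residue_contour = 0.36,
                          distal_end_filament_length = NULL,
                          half_a_band_length = 800,
                          a_band_stiffness = 1e4,
                          temperature = DEFAULT_TEMPERATURE,
                          calcium_force_factor = 1.25) {
  n_proximal_ig <- as.integer(n_proximal_ig)
  n_distal_ig <- as.integer(n_distal_ig)
  n_pevk_residues <- as.integer(n_pevk_residues)
  if (n_proximal_ig <= 0L || n_distal_ig <= 0L || n_pevk_residues <= 0L)
    stop("all domain/residue counts must be positive")
  if (is.null(distal_end_filament_length))
    distal_end_filament_length <- n_distal_ig * folded_contour
  stopifnot(distal_end_filament_length >= 0, half_a_band_length > 0,
            a_band_stiffness > 0, calcium_force_factor > 1)
  iso <- structure(list(
    n_proximal_ig = n_proximal_ig,
    n_distal_ig = n_distal_ig,
    n_pevk_residues = n_pevk_residues,
    folded_ig = wlc_params(folded_pl, folded_contour, temperature),
    unfolded_ig = wlc_params(unfolded_pl, folded_contour + unfolding_gain,
                             temperature),
    pevk = ewlc_params(pevk_pl, residue_contour * n_pevk_residues,
                       pevk_modulus, temperature),
    unfolding_gain = unfolding_gain,
    distal_end_filament_length = distal_end_filament_length,
    half_a_band_length = half_a_band_length,
    a_band_stiffness = a_band_stiffness,
    temperature = temperature,
    calcium_force_factor = calcium_force_factor,
    calcium = FALSE
  ), class = "titin_isoform")
  validate_isoform(iso)
  iso
}

validate_isoform <- function(iso) {
  stopifnot(inherits(iso, "titin_isoform"))
  if (abs((iso$unfolded_ig$contour_length - iso$folded_ig$contour_length) -
          iso$unfolding_gain) > 1e-9)
    stop("unfolded minus folded IG contour length must equal the unfolding ",
         "gain (", iso$unfolding_gain, " nm)")
  invisible(iso)
}

#' @export
print.titin_isoform <- function(x, ...) {
  cat("titin isoform:", x$n_proximal_ig, "proximal IG /", x$n_distal_ig,
      "distal IG /", x$n_pevk_residues, "PEVK residues\n")
  cat(sprintf("  folded IG:   pl %.3g nm, cl %.3g nm\n",
              x$folded_ig$persistence_length, x$folded_ig$contour_length))
  cat(sprintf("  unfolded IG: pl %.3g nm, cl %.3g nm\n",
              x$unfolded_ig$persistence_length, x$unfolded_ig$contour_length))
  cat(sprintf("  PEVK:        pl %.3g nm, cl %.3g nm, K0 %.3g pN\n",
              x$pevk$persistence_length, x$pevk$contour_length,
              x$pevk$elastic_modulus))
  cat(sprintf("  distal end filament %.4g nm, half A-band %.4g nm (k = %.3g pN/nm)\n",
              x$distal_end_filament_length, x$half_a_band_length,
              x$a_band_stiffness))
  cat("  calcium state:", if (x$calcium) "high" else "low", "\n")
  invisible(x)
}

#' High-calcium titin parameter set
#'
#' Physiological calcium stiffens titin: passive force at a reference length
#' rises by about 25%. The high-calcium set scales the whole titin force law
#' uniformly by `calcium_force_factor` (persistence lengths divided by the
#' factor, PEVK modulus multiplied by it), so the force at any fixed
#' extension -- and hence the chain force at any half-sarcomere length above
#' slack -- increases by exactly that factor. Idempotent: applying twice is
#' a no-op (guarded by the `calcium` flag).
#'
#' @param iso a [titin_isoform()].
#' @return the high-calcium isoform.
#' @seealso [remove_calcium()]
#' @export
apply_calcium <- function(iso) {
  validate_isoform(iso)
  if (iso$calcium) return(iso)
  r <- iso$calcium_force_factor
  iso$folded_ig$persistence_length <- iso$folded_ig$persistence_length / r
  iso$unfolded_ig$persistence_length <- iso$unfolded_ig$persistence_length / r
  iso$pevk$persistence_length <- iso$pevk$persistence_length / r
  iso$pevk$elastic_modulus <- iso$pevk$elastic_modulus * r
  iso$calcium <- TRUE
  iso
}

#' Revert a high-calcium isoform to the low-calcium parameter set
#'
#' Exact inverse of [apply_calcium()]; used when a sarcomere is deactivated.
#'
#' @param iso a [titin_isoform()].
#' @return the low-calcium isoform.
#' @export
remove_calcium <- function(iso) {
  validate_isoform(iso)
  if (!iso$calcium) return(iso)
  r <- iso$calcium_force_factor
  iso$folded_ig$persistence_length <- iso$folded_ig$persistence_length * r
  iso$unfolded_ig$persistence_length <- iso$unfolded_ig$persistence_length * r
  iso$pevk$persistence_length <- iso$pevk$persistence_length * r
  iso$pevk$elastic_modulus <- iso$pevk$elastic_modulus / r
  iso$calcium <- FALSE
  iso
}

#' State of one titin strand
#'
#' Tracks the discrete unfolding count of the proximal IG region (never
#' decreasing: refolding does not occur while the sarcomere stays under
#' load), whether calcium-adjusted parameters apply, and whether the strand
#' is bound to actin. When bound, the proximal IG compartment is frozen at
#' `frozen_proximal_length` (the actin anchor does not move on the rigid
#' actin filament) and only PEVK plus the distal/A-band compartments remain
#' as the free spring.
#'
#' @param n_unfolded number of unfolded proximal IG domains.
#' @param calcium_bound logical; high-calcium parameters in effect.
#' @param actin_bound logical; titin bound to actin at the most proximal
#'   PEVK residue.
#' @param frozen_proximal_length summed end-to-end length (nm) of the
#'   proximal IG domains at the moment of binding; required iff
#'   `actin_bound`.
#' @return object of class `titin_state`.
#' @export
titin_state <- function(n_unfolded = 0L, calcium_bound = FALSE,
                        actin_bound = FALSE, frozen_proximal_length = NULL) {
  n_unfolded <- as.integer(n_unfolded)
  stopifnot(n_unfolded >= 0L)
  if (actin_bound) {
    if (is.null(frozen_proximal_length) || frozen_proximal_length < 0)
      stop("actin-bound state requires a non-negative frozen_proximal_length")
  } else if (!is.null(frozen_proximal_length)) {
    stop("frozen_proximal_length is only meaningful when actin_bound")
  }
  structure(list(n_unfolded = n_unfolded,
                 calcium_bound = isTRUE(calcium_bound),
                 actin_bound = isTRUE(actin_bound),
                 frozen_proximal_length = frozen_proximal_length),
            class = "titin_state")
}

#' Actin filament extension under load (rigid-actin check)
#'
#' Actin compliance is about 20 pm of stretch per um of filament length per
#' nN/um^2 of stress increase -- negligible against titin extensions, which
#' justifies treating actin as rigid so the titin-actin anchor never moves.
#'
#' @param filament_length_um filament length in um (>= 0).
#' @param stress_increase stress increase in nN/um^2 (>= 0).
#' @return extension in pm.
#' @export
actin_extension <- function(filament_length_um, stress_increase) {
  if (any(filament_length_um < 0) || any(stress_increase < 0))
    stop("inputs must be non-negative")
  20 * filament_length_um * stress_increase
}
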