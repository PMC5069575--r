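#' Guard-cell pair area from guard-cell dimensions
#'
#' Plan-view area of the two guard cells of one stoma, modelled as a pair of
#' half-ellipses over the guard-cell length and width:
#' a_gc = (pi / 2) * l_gc * w_gc.
#'
#' @param l_gc Guard-cell length, m. Strictly positive.
#' @param w_gc Guard-cell width, m. Strictly positive.
#' @return Guard-cell pair area, m^2.
#' @examples
#' guard_cell_pair_area(20e-6, 7.2e-6) # ~2.26e-10 m^2
#' @export
guard_cell_pair_area <- function(l_gc, w_gc) {
  check_positive(l_gc, "l_gc")
  check_positive(w_gc, "w_gc")
  (pi / 2) * l_gc * w_gc
}

#' Anatomical maximum pore area from pore length
#'
#' Pore area at full anatomical aperture: a fraction `f_lw` of the circle
#' with diameter equal to the pore length, a_max = (pi / 4) * f_lw * l_p^2.
#'
#' @param l_p Stomatal pore length, m. Strictly positive.
#' @param f_lw Pore-shape area fraction, in \[0.4, 1\] depending on
#'   morphology (see [flw_for_class()]).
#' @return Maximum pore area, m^2.
#' @export
max_pore_area <- function(l_p, f_lw) {
  check_positive(l_p, "l_p")
  if (any(f_lw < 0.4 | f_lw > 1)) {
    abort("f_lw must lie in [0.4, 1]")
  }
  (pi / 4) * f_lw * l_p^2
}

#' Pore depth implied by guard-cell pair area
#'
#' Pore depth is taken equal to the guard-cell width (the cross-sectional
#' diameter of an inflated guard cell). Given the pair area and the
#' width:length ratio r_wl, the implied depth is
#' d_p = sqrt(2 * a_gc * r_wl / pi), which recovers w_gc exactly when
#' a_gc = (pi/2) * l_gc * w_gc and w_gc = r_wl * l_gc.
#'
#' @param a_gc Guard-cell pair area, m^2. Strictly positive.
#' @param r_wl Guard-cell width:length ratio. Strictly positive.
#' @return Pore depth, m.
#' @export
pore_depth_from_agc <- function(a_gc, r_wl = stomatal_constants()$r_wl) {
  check_positive(a_gc, "a_gc")
  check_positive(r_wl, "r_wl")
  sqrt(2 * a_gc * r_wl / pi)
}

#' Fraction of the epidermis allocated to stomata
#'
#' The epidermal cover fraction f_gc = D_s * a_gc, the product of stomatal
#' density and guard-cell pair area. This is the "cost" proxy of the
#' allocation trade-off. Values above 1 are physically impossible covers and
#' raise a warning, not an error, since extreme synthetic parameter draws
#' may produce them.
#'
#' @param d_s Stomatal density, stomata m^-2. Non-negative.
#' @param a_gc Guard-cell pair area, m^2. Non-negative.
#' @return Epidermal cover fraction (dimensionless).
#' @examples
#' f_gc(1e8, 1e-10) # 0.01, i.e. 1 percent of the epidermis
#' @export
f_gc <- function(d_s, a_gc) {
  if (any(d_s < 0) || any(a_gc < 0)) {
    abort("d_s and a_gc must be non-negative")
  }
  out <- d_s * a_gc
  if (any(out > 1)) {
    warn("f_gc > 1: stomatal cover exceeds the epidermis; check units")
  }
  out
}

#' Anatomical maximum stomatal conductance
#'
#' Diffusion-based maximum conductance of the epidermis to water vapour:
#' \deqn{g_{smax} = \frac{d_{H2O}}{w_v} \cdot
#'   \frac{D_s \, a_{max}}{d_p + \frac{\pi}{2}\sqrt{a_{max}/\pi}}}
#' with pore depth d_p and an end-correction term equal to half the radius
#' of the circle-equivalent pore.
#'
#' @param d_s Stomatal density, m^-2. Non-negative.
#' @param a_max Maximum pore area, m^2. Strictly positive.
#' @param d_p Pore depth, m. Strictly positive.
#' @param constants A [stomatal_constants()] list.
#' @return Conductance, mol m^-2 s^-1. Linear in `d_s`.
#' @examples
#' g_smax(2e8, 2.7e-11, 7.2e-6) # ~0.465 mol m^-2 s^-1
#' @export
g_smax <- function(d_s, a_max, d_p, constants = stomatal_constants()) {
  if (any(d_s < 0)) abort("d_s must be non-negative")
  check_positive(a_max, "a_max")
  check_positive(d_p, "d_p")
  (constants$d_h2o / constants$w_v) * d_s * a_max /
    (d_p + (pi / 2) * sqrt(a_max / pi))
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(paste0(name, " must be finite and strictly positive"))
  }
  invisible(x)
}
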