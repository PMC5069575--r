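#' Physical constants for anatomical conductance calculations
#'
#' Bundles the physical and geometric constants entering the diffusion
#' formula for anatomical maximum stomatal conductance. Defaults are for
#' water vapour in air at 25 degrees C and 101.3 kPa, and the cross-species
#' mean guard-cell width:length ratio.
#'
#' @param d_h2o Diffusivity of water vapour in air, m^2 s^-1.
#' @param w_v Molar volume of air, m^3 mol^-1 (normalised to 25 degrees C).
#' @param r_wl Guard-cell width:length ratio w_gc / l_gc (dimensionless);
#'   about 0.36 across species.
#'
#' @return A list of class `stomatal_constants`.
#' @examples
#' stomatal_constants()
#' @export
stomatal_constants <- function(d_h2o = 2.49e-5, w_v = 2.45e-2, r_wl = 0.36) {
  if (d_h2o <= 0 || w_v <= 0 || r_wl <= 0) {
    abort("all physical constants must be strictly positive")
  }
  structure(list(d_h2o = d_h2o, w_v = w_v, r_wl = r_wl),
            class = "stomatal_constants")
}

#' @export
print.stomatal_constants <- function(x, ...) {
  cat("Stomatal physical constants:\n")
  cat("  d_H2O =", format(x$d_h2o), "m^2 s^-1\n")
  cat("  w_v   =", format(x$w_v), "m^3 mol^-1\n")
  cat("  r_wl  =", format(x$r_wl), "(w_gc / l_gc)\n")
  invisible(x)
}

# Pore-shape area fractions f_lw by basic stomatal morphology: the fraction
# of the circle over the pore length actually occupied by the fully open
# pore. Values span the documented [0.4, 1] range.
.flw_classes <- c(
  elliptical_pore  = 0.4,
  kidney_shaped    = 0.5,
  circular_pore    = 1.0,
  graminoid        = 0.7
)

#' Pore-shape area fraction for a stomatal morphology class
#'
#' Maps a basic stomatal morphology label to the fraction `f_lw` of a circle
#' with diameter equal to the pore length that is occupied by the pore at
#' full anatomical aperture. Known classes: `"elliptical_pore"` (0.4),
#' `"kidney_shaped"` (0.5), `"graminoid"` (0.7), `"circular_pore"` (1.0).
#' Unknown classes fall back to 0.5 (the mid-range value) with a warning so
#' the user can supply the correct class.
#'
#' @param morphology_class Character vector of class labels (NA allowed).
#' @return Numeric vector of f_lw values in \[0.4, 1\].
#' @export
flw_for_class <- function(morphology_class) {
  out <- unname(.flw_classes[as.character(morphology_class)])
  unknown <- is.na(out) & !is.na(morphology_class)
  if (any(unknown)) {
    warn(paste0("unknown morphology class(es) ",
                paste(unique(morphology_class[unknown]), collapse = ", "),
                "; using mid-range f_lw = 0.5"))
    out[unknown] <- 0.5
  }
  out[is.na(morphology_class)] <- 0.5
  out
}
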