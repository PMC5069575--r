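#' Scaling parameters of the composed conductance-cost model
#'
#' Bundles the offsets and exponents of the two fitted allometries —
#' guard-cell size against density, a_gc = b_s * D_s^S, and maximum pore
#' area against guard-cell size, a_max = b_p * a_gc^P — together with the
#' geometric and physical constants and the reference density at which
#' marginal derivatives are evaluated. All offsets are in SI units
#' (D_s in m^-2, areas in m^2).
#'
#' @param b_s,s Offset and exponent of the size-density scaling.
#' @param b_p,p Offset and exponent of the pore-size scaling.
#' @param d_ref Reference stomatal density (m^-2) at which derivatives are
#'   evaluated; typically the geometric mean density of the data.
#' @param r_wl Guard-cell width:length ratio.
#' @param constants A [stomatal_constants()] list.
#' @return A list of class `scaling_parameters`.
#' @export
scaling_parameters <- function(b_s, s, b_p, p, d_ref,
                               r_wl = stomatal_constants()$r_wl,
                               constants = stomatal_constants()) {
  if (b_s <= 0 || b_p <= 0 || d_ref <= 0) {
    abort("b_s, b_p and d_ref must be strictly positive")
  }
  structure(list(b_s = b_s, s = s, b_p = b_p, p = p, d_ref = d_ref,
                 r_wl = r_wl, constants = constants),
            class = "scaling_parameters")
}

#' @export
print.scaling_parameters <- function(x, ...) {
  cat(sprintf("Scaling parameters: a_gc = %.3g * D_s^%.3f; a_max = %.3g * a_gc^%.3f\n",
              x$b_s, x$s, x$b_p, x$p))
  cat(sprintf("  D_ref = %.3g m^-2, r_wl = %.2f\n", x$d_ref, x$r_wl))
  invisible(x)
}

# Coefficients of the composed model
# g(D) = A * D^(1 + S P) / (k D^(S/2) + m D^(S P / 2)).
composed_coefs <- function(params) {
  cc <- params$b_p * params$b_s^params$p
  list(
    A = (params$constants$d_h2o / params$constants$w_v) * cc,
    k = sqrt(2 * params$r_wl * params$b_s / pi),
    m = (sqrt(pi) / 2) * sqrt(cc),
    alpha = params$s / 2,
    beta = params$s * params$p / 2,
    sp = params$s * params$p
  )
}

#' Anatomical maximum conductance as a function of density alone
#'
#' Substitutes the two allometric relationships (and the pore-depth
#' geometry) into the diffusion formula, collapsing g_smax to a function of
#' stomatal density only:
#' g(D_s) = A D_s^(1+SP) / (k D_s^(S/2) + m D_s^(SP/2)),
#' with A = (d_H2O/w_v) b_p b_s^P, k = sqrt(2 r_wl b_s / pi) and
#' m = (sqrt(pi)/2) sqrt(b_p b_s^P). Identical, by construction, to piping
#' D_s through [guard_cell_pair_area()]-scale allometries into [g_smax()].
#'
#' @param d_s Stomatal density, m^-2 (vectorised).
#' @param params A [scaling_parameters()] object.
#' @return Conductance, mol m^-2 s^-1.
#' @export
gsmax_of_density <- function(d_s, params) {
  check_positive(d_s, "d_s")
  co <- composed_coefs(params)
  co$A * d_s^(1 + co$sp) /
    (co$k * d_s^co$alpha + co$m * d_s^co$beta)
}

#' Marginal change of g_smax with stomatal density (closed form)
#'
#' Analytic derivative of [gsmax_of_density()] with respect to density:
#' dg/dD = A D^(SP) \[k (1 + SP - S/2) D^(S/2) + m (1 + SP - SP/2) D^(SP/2)\]
#'         / (k D^(S/2) + m D^(SP/2))^2.
#' Verified against central finite differences in the test suite.
#'
#' @inheritParams gsmax_of_density
#' @return Derivative, (mol m^-2 s^-1) per (m^-2).
#' @export
dgsmax_dds <- function(d_s, params) {
  check_positive(d_s, "d_s")
  co <- composed_coefs(params)
  q <- co$k * d_s^co$alpha + co$m * d_s^co$beta
  co$A * d_s^co$sp *
    (co$k * (1 + co$sp - co$alpha) * d_s^co$alpha +
       co$m * (1 + co$sp - co$beta) * d_s^co$beta) / q^2
}

#' Marginal change of epidermal cover with stomatal density
#'
#' Along the fitted size-density allometry, f_gc = b_s D_s^(1+S), so
#' df/dD = b_s (1 + S) D_s^S. Exactly zero when S = -1 (area-preserving
#' scaling).
#'
#' @inheritParams gsmax_of_density
#' @return Derivative of the cover fraction per unit density.
#' @export
dfgc_dds <- function(d_s, params) {
  check_positive(d_s, "d_s")
  params$b_s * (1 + params$s) * d_s^params$s
}

#' The marginal benefit:cost ratio of adding stomata
#'
#' Evaluates the marginal ratio of the conductance benefit to the
#' epidermal-cover cost of a density increase under the fitted allometries,
#' Lambda = (dg_smax/dD_s) / (df_gc/dD_s), at the reference density, and
#' classifies its sign region in the (S, P) exponent plane:
#' \describe{
#'   \item{II}{cover falls while conductance rises (Lambda < 0) — the
#'     spatially optimal region;}
#'   \item{I}{both fall (Lambda > 0);}
#'   \item{III}{both rise (Lambda > 0);}
#'   \item{boundary}{S = -1 exactly (cover stationary; Lambda is signed
#'     infinity) or dg/dD = 0;}
#'   \item{unclassified}{cover rises while conductance falls.}
#' }
#'
#' Because the sign of dg/dD can in principle depend on where it is
#' evaluated, the sign is additionally checked at `d_check` densities
#' (e.g. the 5th/95th percentile of the data); disagreement sets
#' `sign_stable = FALSE`.
#'
#' @param params A [scaling_parameters()] object.
#' @param d_check Optional vector of additional densities at which the sign
#'   of dg/dD is verified.
#' @return An object of class `lambda_result` with elements `lambda_value`,
#'   `dg_dds`, `df_dds`, `region`, `d_ref`, `sign_stable`.
#' @export
marginal_ratio <- function(params, d_check = NULL) {
  dg <- dgsmax_dds(params$d_ref, params)
  df <- dfgc_dds(params$d_ref, params)
  if (params$s == -1 || df == 0) {
    lambda <- sign2(dg) * Inf
  } else {
    lambda <- dg / df
  }
  region <- classify_region(params)
  sign_stable <- TRUE
  if (!is.null(d_check) && length(d_check) > 0) {
    signs <- sign(dgsmax_dds(d_check, params))
    sign_stable <- all(signs == sign(dg))
    if (!sign_stable) {
      warn("sign of dg_smax/dD_s depends on the evaluation density; region label applies at d_ref only")
    }
  }
  structure(list(lambda_value = lambda, dg_dds = dg, df_dds = df,
                 region = region, d_ref = params$d_ref,
                 sign_stable = sign_stable),
            class = "lambda_result")
}

#' @export
print.lambda_result <- function(x, ...) {
  cat(sprintf("Marginal ratio Lambda = %.4g at D_ref = %.3g m^-2 (region %s)\n",
              x$lambda_value, x$d_ref, x$region))
  cat(sprintf("  dg_smax/dD_s = %.4g, df_gc/dD_s = %.4g%s\n",
              x$dg_dds, x$df_dds,
              if (x$sign_stable) "" else "  [sign-unstable over density range]"))
  invisible(x)
}

#' @describeIn marginal_ratio Tidy one-row summary of a `lambda_result`.
#' @param x A `lambda_result`.
#' @param ... Unused.
#' @method tidy lambda_result
#' @export
tidy.lambda_result <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda_value, dg_dds = x$dg_dds, df_dds = x$df_dds,
    region = x$region, d_ref = x$d_ref, sign_stable = x$sign_stable
  )
}

#' Sign-region of the exponent plane at the reference density
#'
#' @param params A [scaling_parameters()] object.
#' @return One of `"I"`, `"II"`, `"III"`, `"boundary"`, `"unclassified"`.
#' @export
classify_region <- function(params) {
  if (params$s == -1) return("boundary")
  dg <- dgsmax_dds(params$d_ref, params)
  df <- dfgc_dds(params$d_ref, params)
  if (dg == 0) return("boundary")
  if (df < 0 && dg > 0) return("II")
  if (df < 0 && dg < 0) return("I")
  if (df > 0 && dg > 0) return("III")
  "unclassified"
}

#' Sign-region map over a grid of scaling exponents
#'
#' Classifies every (S, P) combination of the supplied grids at fixed
#' offsets and reference density, reproducing the three-region partition of
#' the exponent plane (regions I and II left of the S = -1 boundary, where
#' cover does not increase with density; region III to its right).
#'
#' @param s_values,p_values Numeric grids of exponents.
#' @param params Template [scaling_parameters()] supplying offsets,
#'   constants and `d_ref`.
#' @return A tibble with columns `s`, `p`, `region`, `lambda`.
#' @export
region_map <- function(s_values, p_values, params) {
  grid <- tidyr::expand_grid(s = s_values, p = p_values)
  res <- purrr::pmap(grid, function(s, p) {
    pp <- scaling_parameters(params$b_s, s, params$b_p, p, params$d_ref,
                             r_wl = params$r_wl, constants = params$constants)
    lr <- marginal_ratio(pp)
    list(region = lr$region, lambda = lr$lambda_value)
  })
  grid$region <- purrr::map_chr(res, "region")
  grid$lambda <- purrr::map_dbl(res, "lambda")
  grid
}

#' Plot a sign-region map of the exponent plane
#'
#' @param grid A tibble from [region_map()].
#' @return A ggplot object (tile map of region labels with the S = -1
#'   boundary marked).
#' @export
plot_region_map <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$s, y = .data$p,
                                     fill = .data$region)) +
    ggplot2::geom_tile() +
    ggplot2::geom_vline(xintercept = -1, linetype = "dashed") +
    ggplot2::labs(x = "Exponent S (a_gc ~ D_s)", y = "Exponent P (a_max ~ a_gc)",
                  fill = "Region") +
    ggplot2::theme_minimal()
}

#' Build scaling parameters from two fitted allometries
#'
#' Combines a size-density SMA fit and a pore-size SMA fit into a
#' [scaling_parameters()] object, taking the reference density as the
#' geometric mean of the supplied densities unless overridden.
#'
#' @param fit_s `sma_fit` of a_gc against d_s.
#' @param fit_p `sma_fit` of a_max against a_gc.
#' @param d_s Vector of densities (m^-2) defining the reference density.
#' @param d_ref Optional explicit reference density.
#' @inheritParams scaling_parameters
#' @return A [scaling_parameters()] object.
#' @export
scaling_from_fits <- function(fit_s, fit_p, d_s, d_ref = NULL,
                              r_wl = stomatal_constants()$r_wl,
                              constants = stomatal_constants()) {
  if (is.null(d_ref)) d_ref <- geometric_mean(d_s)
  scaling_parameters(fit_s$offset_b, fit_s$exponent,
                     fit_p$offset_b, fit_p$exponent,
                     d_ref = d_ref, r_wl = r_wl, constants = constants)
}

geometric_mean <- function(x) {
  x <- x[!is.na(x)]
  exp(mean(log(x)))
}
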