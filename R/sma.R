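#' Standardized major axis (SMA) fit of an allometric relationship
#'
#' Fits y = b * x^E by standardized major axis regression on
#' log10-transformed values, the symmetric line-fitting method standard for
#' allometric exponents. On the log scale the slope is
#' sign(r) * sd(log10 y) / sd(log10 x), with a 95% confidence interval from
#' the classical F-statistic formula
#' slope * (sqrt(B + 1) +/- sqrt(B)), B = F(0.95; 1, n-2) (1 - r^2)/(n - 2).
#' The elevation (offset) is retained only when a t-test finds it
#' significantly different from 0 at `alpha`; otherwise the line is refit
#' through the origin. The fit is flagged invalid when the Pearson
#' correlation of the log10 values is not significant (p >= 0.05).
#'
#' @param data A data frame of species-average traits.
#' @param x,y Bare column names of the positive traits to relate.
#' @param with_offset Allow an offset term (tested for significance). Fits
#'   on independent contrasts should use [sma_fit_through_origin()] instead.
#' @param alpha Significance level for the offset test.
#' @return An object of class `sma_fit`; see [tidy.sma_fit()] and
#'   [glance.sma_fit()] for tibble summaries.
#' @examples
#' d <- tibble::tibble(x = 10^runif(30, 1, 3))
#' d$y <- 5 * d$x^-1.2 * 10^rnorm(30, 0, 0.05)
#' sma_fit(d, x, y)
#' @export
sma_fit <- function(data, x, y, with_offset = TRUE, alpha = 0.05) {
  x_name <- rlang::as_name(rlang::enquo(x))
  y_name <- rlang::as_name(rlang::enquo(y))
  xv <- data[[x_name]]
  yv <- data[[y_name]]
  keep <- !is.na(xv) & !is.na(yv)
  xv <- xv[keep]
  yv <- yv[keep]
  if (length(xv) < 3) abort("sma_fit needs at least 3 complete cases")
  if (any(xv <= 0) || any(yv <= 0)) {
    abort("sma_fit requires strictly positive trait values (log10 scale)")
  }
  fit <- sma_core(log10(xv), log10(yv), with_offset = with_offset,
                  alpha = alpha)
  fit$x_name <- x_name
  fit$y_name <- y_name
  fit
}

# Core estimator on already log10-transformed values.
sma_core <- function(lx, ly, with_offset = TRUE, alpha = 0.05) {
  n <- length(lx)
  sx <- sd(lx)
  sy <- sd(ly)
  if (sx == 0 || sy == 0) abort("degenerate fit: zero variance in x or y")
  r <- stats::cor(lx, ly)
  ct <- suppressWarnings(cor.test(lx, ly))
  slope <- sign2(r) * sy / sx
  B <- stats::qf(0.95, 1, n - 2) * (1 - r^2) / (n - 2)
  ci <- sort(c(slope * (sqrt(B + 1) - sqrt(B)),
               slope * (sqrt(B + 1) + sqrt(B))))

  offset_included <- FALSE
  intercept <- 0
  ci_int <- c(0, 0)
  if (with_offset) {
    intercept <- mean(ly) - slope * mean(lx)
    resid <- ly - slope * lx
    var_slope <- slope^2 * (1 - r^2) / (n - 2)
    se_int <- sqrt(var(resid) / n + mean(lx)^2 * var_slope)
    t_int <- intercept / se_int
    p_int <- 2 * pt(abs(t_int), df = n - 2, lower.tail = FALSE)
    if (p_int < alpha) {
      offset_included <- TRUE
      ci_int <- intercept + c(-1, 1) * qt(1 - alpha / 2, n - 2) * se_int
    } else {
      slope <- sign2(sum(lx * ly)) * sqrt(sum(ly^2) / sum(lx^2))
      intercept <- 0
      ci <- sort(c(slope * (sqrt(B + 1) - sqrt(B)),
                   slope * (sqrt(B + 1) + sqrt(B))))
    }
  }

  structure(list(
    x_name = "x", y_name = "y", n = n,
    exponent = slope, ci_exponent = ci,
    intercept = intercept, ci_intercept = ci_int,
    offset_b = 10^intercept, ci_offset = 10^ci_int,
    r2 = r^2, p_value = ct$p.value,
    valid = ct$p.value < 0.05,
    through_origin = FALSE, offset_included = offset_included
  ), class = "sma_fit")
}

#' SMA fit forced through the origin
#'
#' The through-origin SMA estimator used for fits on phylogenetically
#' independent contrasts: slope = sign(sum xy) * sqrt(sum y^2 / sum x^2),
#' with no offset term. Inputs are contrast vectors (already on the trait's
#' log scale), not raw traits.
#'
#' @param x_contrasts,y_contrasts Numeric vectors of paired contrasts.
#' @return An `sma_fit` object with `through_origin = TRUE`.
#' @export
sma_fit_through_origin <- function(x_contrasts, y_contrasts) {
  keep <- !is.na(x_contrasts) & !is.na(y_contrasts)
  x <- x_contrasts[keep]
  y <- y_contrasts[keep]
  n <- length(x)
  if (n < 2) abort("through-origin SMA needs at least 2 contrast pairs")
  sxx <- sum(x^2)
  syy <- sum(y^2)
  if (sxx == 0 || syy == 0) abort("degenerate fit: all-zero contrasts")
  sxy <- sum(x * y)
  slope <- sign2(sxy) * sqrt(syy / sxx)
  r2 <- if (sxy == 0) 0 else sxy^2 / (sxx * syy)
  B <- stats::qf(0.95, 1, n - 1) * (1 - r2) / (n - 1)
  ci <- sort(c(slope * (sqrt(B + 1) - sqrt(B)),
               slope * (sqrt(B + 1) + sqrt(B))))
  # correlation test without centring, df = n - 1
  tstat <- if (r2 >= 1) Inf else sqrt(r2 * (n - 1) / (1 - r2))
  p <- 2 * pt(tstat, df = n - 1, lower.tail = FALSE)
  structure(list(
    x_name = "x_contrasts", y_name = "y_contrasts", n = n,
    exponent = slope, ci_exponent = ci,
    intercept = 0, ci_intercept = c(0, 0),
    offset_b = 1, ci_offset = c(1, 1),
    r2 = r2, p_value = p, valid = p < 0.05,
    through_origin = TRUE, offset_included = FALSE
  ), class = "sma_fit")
}

sign2 <- function(x) if (x < 0) -1 else 1

#' @export
print.sma_fit <- function(x, ...) {
  cat("SMA fit:", x$y_name, "~", x$x_name,
      if (x$through_origin) "(through origin)" else "", "\n")
  cat(sprintf("  n = %d, exponent = %.4f [%.4f, %.4f]\n",
              x$n, x$exponent, x$ci_exponent[1], x$ci_exponent[2]))
  if (x$offset_included) {
    cat(sprintf("  offset (back-transformed) = %.4g [%.4g, %.4g]\n",
                x$offset_b, x$ci_offset[1], x$ci_offset[2]))
  }
  cat(sprintf("  r2 = %.3f, correlation p = %.3g%s\n", x$r2, x$p_value,
              if (x$valid) "" else "  [fit not valid: p >= 0.05]"))
  invisible(x)
}

#' Tidy an SMA fit into a coefficient tibble
#'
#' @param x An `sma_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per term (`exponent`, and `offset` if
#'   included), with estimate and 95% confidence bounds. The offset row is
#'   on the back-transformed (multiplicative) scale.
#' @method tidy sma_fit
#' @export
tidy.sma_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = "exponent", estimate = x$exponent,
    conf.low = x$ci_exponent[1], conf.high = x$ci_exponent[2]
  )
  if (x$offset_included) {
    out <- dplyr::bind_rows(tibble::tibble(
      term = "offset", estimate = x$offset_b,
      conf.low = x$ci_offset[1], conf.high = x$ci_offset[2]
    ), out)
  }
  out
}

#' One-row model summary of an SMA fit
#'
#' @param x An `sma_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: n, r2 (squared Pearson correlation of the
#'   log10 values), correlation p-value, validity flag, and whether the fit
#'   was through the origin / kept its offset.
#' @method glance sma_fit
#' @export
glance.sma_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, r2 = x$r2, p_value = x$p_value, valid = x$valid,
    through_origin = x$through_origin, offset_included = x$offset_included
  )
}

#' Built-in species selections for the allometry table
#'
#' The standard species selections analysed in the allocation study: all
#' species; each clade in isolation; and amphistomatous dicots and monocots
#' (phylogenetically and morphologically distinct groups).
#'
#' @return A named list of predicate functions on a species-average tibble.
#' @export
default_selections <- function() {
  list(
    all_species = function(d) rep(TRUE, nrow(d)),
    angiosperms = function(d) d$clade == "angiosperm",
    gymnosperms = function(d) d$clade == "gymnosperm",
    pteridophytes = function(d) d$clade == "pteridophyte",
    amphistomatous_dicot = function(d) {
      d$clade == "angiosperm" & d$amphistomatous &
        !is.na(d$subclade) & d$subclade == "dicot"
    },
    amphistomatous_monocot = function(d) {
      d$clade == "angiosperm" & d$amphistomatous &
        !is.na(d$subclade) & d$subclade == "monocot"
    }
  )
}

#' Fit the two allometric scaling relationships per species selection
#'
#' For each species selection, fits the size-density scaling
#' a_gc = b_s * D_s^S and, on the complete a_max cases, the pore-size
#' scaling a_max = b_p * a_gc^P, both by SMA on log10 values. The result is
#' a table shaped like the study's summary table: one row per
#' selection x relationship with offset, exponent, confidence bounds, r2
#' and validity.
#'
#' @param traits Species-average tibble (SI units) with columns `d_s`,
#'   `a_gc`, `a_max` and the selection metadata.
#' @param selections Named list of predicate functions; defaults to
#'   [default_selections()]. Selections with fewer than `min_n` complete
#'   cases for a relationship are reported with `NA` estimates.
#' @param min_n Minimum complete cases per fit (default 5).
#' @return A tibble with columns `selection`, `x`, `y`, `n`, `offset`,
#'   `ci_offset_lo`, `ci_offset_hi`, `exponent`, `ci_exponent_lo`,
#'   `ci_exponent_hi`, `r2`, `p_value`, `valid`.
#' @export
fit_allometries <- function(traits, selections = default_selections(),
                            min_n = 5) {
  pairs <- list(
    c(x = "d_s", y = "a_gc"),
    c(x = "a_gc", y = "a_max")
  )
  purrr::map_dfr(names(selections), function(sel_name) {
    sub <- traits[selections[[sel_name]](traits), ]
    purrr::map_dfr(pairs, function(p) {
      xv <- sub[[p[["x"]]]]
      yv <- sub[[p[["y"]]]]
      cc <- sum(!is.na(xv) & !is.na(yv))
      if (cc < min_n) {
        return(tibble::tibble(
          selection = sel_name, x = p[["x"]], y = p[["y"]], n = cc,
          offset = NA_real_, ci_offset_lo = NA_real_,
          ci_offset_hi = NA_real_, exponent = NA_real_,
          ci_exponent_lo = NA_real_, ci_exponent_hi = NA_real_,
          r2 = NA_real_, p_value = NA_real_, valid = FALSE
        ))
      }
      f <- sma_fit(sub, !!rlang::sym(p[["x"]]), !!rlang::sym(p[["y"]]))
      tibble::tibble(
        selection = sel_name, x = p[["x"]], y = p[["y"]], n = f$n,
        offset = f$offset_b, ci_offset_lo = f$ci_offset[1],
        ci_offset_hi = f$ci_offset[2], exponent = f$exponent,
        ci_exponent_lo = f$ci_exponent[1], ci_exponent_hi = f$ci_exponent[2],
        r2 = f$r2, p_value = f$p_value, valid = f$valid
      )
    })
  })
}
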