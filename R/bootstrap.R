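#' Percentile summary of bootstrap replicates
#'
#' Linear-interpolation percentiles (quantile type 7) of a replicate
#' vector. Infinite replicates — produced when a resampled size-density
#' exponent lands exactly on the S = -1 boundary — are counted separately
#' as `n_boundary` and excluded from interpolation.
#'
#' @param samples Numeric vector of replicate values (may contain +/-Inf).
#' @param levels Percentile levels.
#' @return A list: `n`, `n_boundary`, `median`, `q05`, `q95`, `ci95_lo`,
#'   `ci95_hi`, and `quantiles` (named vector at `levels`).
#' @export
percentile_summary <- function(samples,
                               levels = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  if (length(samples) == 0) abort("percentile_summary needs at least one sample")
  finite <- samples[is.finite(samples)]
  if (length(finite) == 0) abort("no finite samples to summarise")
  q <- quantile(finite, probs = levels, type = 7, names = TRUE)
  ci <- quantile(finite, probs = c(0.025, 0.975), type = 7, names = FALSE)
  list(
    n = length(finite),
    n_boundary = sum(is.infinite(samples)),
    median = unname(quantile(finite, 0.5, type = 7)),
    q05 = unname(quantile(finite, 0.05, type = 7)),
    q95 = unname(quantile(finite, 0.95, type = 7)),
    ci95_lo = ci[1], ci95_hi = ci[2],
    quantiles = q
  )
}

boot_distribution <- function(samples, name, n_dropped = 0) {
  s <- percentile_summary(samples)
  structure(list(
    statistic_name = name, samples = samples, n_reps = length(samples),
    n_dropped = n_dropped, n_boundary = s$n_boundary,
    median = s$median, q05 = s$q05, q95 = s$q95,
    ci95_lo = s$ci95_lo, ci95_hi = s$ci95_hi
  ), class = "boot_dist")
}

#' @export
print.boot_dist <- function(x, ...) {
  cat(sprintf("Bootstrap distribution of %s (%d replicates, %d dropped, %d at boundary)\n",
              x$statistic_name, x$n_reps, x$n_dropped, x$n_boundary))
  cat(sprintf("  median = %.4g, 5th-95th pct = [%.4g, %.4g], 95%% CI = [%.4g, %.4g]\n",
              x$median, x$q05, x$q95, x$ci95_lo, x$ci95_hi))
  invisible(x)
}

#' @method tidy boot_dist
#' @export
tidy.boot_dist <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic_name, n_reps = x$n_reps,
    n_dropped = x$n_dropped, n_boundary = x$n_boundary,
    median = x$median, q05 = x$q05, q95 = x$q95,
    ci95_lo = x$ci95_lo, ci95_hi = x$ci95_hi
  )
}

#' Paired bootstrap of the scaling fits and the marginal ratio
#'
#' Resamples species rows with replacement from the full species-average
#' table; each replicate refits the size-density allometry on its complete
#' (D_s, a_gc) cases and the pore-size allometry on its complete
#' (a_gc, a_max) cases, so the two fits stay paired through the shared
#' species resample. The marginal ratio Lambda is evaluated per replicate
#' at the replicate's geometric-mean density (or at a fixed `d_ref`).
#' Replicates whose fits are degenerate (zero variance or too few a_max
#' cases) are dropped and counted; replicates with a size-density exponent
#' exactly at -1 contribute signed-infinite Lambda, counted as boundary
#' replicates.
#'
#' @param traits Species-average tibble with `d_s`, `a_gc`, `a_max`.
#' @param n_reps Number of bootstrap replicates (study default 10000).
#' @param seed Integer seed; the run is deterministic given
#'   (`traits`, `n_reps`, `seed`).
#' @param d_ref Optional fixed reference density; default is each
#'   replicate's own geometric-mean density.
#' @param paired If `FALSE`, the two fits use independent species
#'   resamples (diagnostic alternative to the default paired scheme).
#' @param identity_resample Test hook: skip resampling so each replicate is
#'   the original data (Lambda then equals the point estimate).
#' @param p_traits Optional second species table on which the pore-size
#'   relationship is fit (resampled independently per replicate). Used to
#'   apply the generic all-species a_max scaling to a clade whose own
#'   pore-size fit is not significant.
#' @param r_wl,constants Geometry and physical constants.
#' @param min_amax Minimum complete a_max cases per replicate (default 5).
#' @return A list of three `boot_dist` objects: `lambda`, `exponent_s`,
#'   `exponent_p`, plus `n_dropped`.
#' @export
bootstrap_lambda <- function(traits, n_reps = 10000, seed,
                             d_ref = NULL, paired = TRUE,
                             identity_resample = FALSE,
                             p_traits = NULL,
                             r_wl = stomatal_constants()$r_wl,
                             constants = stomatal_constants(),
                             min_amax = 5) {
  if (missing(seed)) abort("an explicit integer seed is required")
  if (n_reps < 1) abort("n_reps must be >= 1")
  l_ds <- log10(traits$d_s)
  l_agc <- log10(traits$a_gc)
  p_tab <- if (is.null(p_traits)) traits else p_traits
  l_agc_p <- log10(p_tab$a_gc)
  l_amax <- log10(p_tab$a_max)
  n <- length(l_ds)
  n_p <- length(l_agc_p)
  has_amax <- !is.na(l_amax)
  if (sum(has_amax) < min_amax) abort("too few a_max cases for the pore-size fit")

  lam <- s_vec <- p_vec <- numeric(n_reps)
  dropped <- 0L
  with_preserved_seed(seed, {
    for (rep in seq_len(n_reps)) {
      idx <- if (identity_resample) seq_len(n) else
        sample.int(n, n, replace = TRUE)
      idx2 <- if (identity_resample) seq_len(n_p)
        else if (paired && is.null(p_traits)) idx
        else sample.int(n_p, n_p, replace = TRUE)
      ok <- tryCatch({
        fs <- sma_core(l_ds[idx], l_agc[idx])
        sub2 <- idx2[has_amax[idx2]]
        if (length(sub2) < min_amax) stop("too few a_max cases")
        fp <- sma_core(l_agc_p[sub2], l_amax[sub2])
        dref <- if (is.null(d_ref)) 10^mean(l_ds[idx]) else d_ref
        params <- scaling_parameters(fs$offset_b, fs$exponent,
                                     fp$offset_b, fp$exponent,
                                     d_ref = dref, r_wl = r_wl,
                                     constants = constants)
        lr <- marginal_ratio(params)
        lam[rep] <- lr$lambda_value
        s_vec[rep] <- fs$exponent
        p_vec[rep] <- fp$exponent
        TRUE
      }, error = function(e) FALSE)
      if (!ok) {
        dropped <- dropped + 1L
        lam[rep] <- NA_real_
        s_vec[rep] <- NA_real_
        p_vec[rep] <- NA_real_
      }
    }
  })
  keep <- !is.na(s_vec)
  if (dropped > 0.05 * n_reps) {
    warn(sprintf("%d of %d bootstrap replicates dropped (degenerate fits)",
                 dropped, n_reps))
  }
  list(
    lambda = boot_distribution(lam[keep], "lambda", dropped),
    exponent_s = boot_distribution(s_vec[keep], "exponent_S", dropped),
    exponent_p = boot_distribution(p_vec[keep], "exponent_P", dropped),
    n_dropped = dropped
  )
}

# Run code under a fixed seed, restoring the caller's RNG state after.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Box-and-whisker plot of bootstrap distributions
#'
#' @param dists A named list of `boot_dist` objects (e.g. the Lambda
#'   distributions of several species selections).
#' @return A ggplot object: boxes span the interquartile range, whiskers
#'   the 5th-95th percentiles, the crossbar the median.
#' @export
plot_boot_dists <- function(dists) {
  df <- purrr::imap_dfr(dists, function(d, nm) {
    fin <- d$samples[is.finite(d$samples)]
    q <- quantile(fin, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7)
    tibble::tibble(group = nm, q05 = q[1], q25 = q[2], med = q[3],
                   q75 = q[4], q95 = q[5])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$q05, ymax = .data$q95),
                           width = 0.2) +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$med, ymin = .data$q25,
                                        ymax = .data$q75), fill = "grey90") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "red") +
    ggplot2::labs(x = NULL, y = "Bootstrap replicate value") +
    ggplot2::theme_minimal()
}
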