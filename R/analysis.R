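#' Run the full allocation analysis on a species-average table
#'
#' The end-to-end driver: fits the allometry table over all species
#' selections, evaluates the marginal ratio Lambda (point estimate and
#' paired bootstrap) per Lambda selection, runs the phylogenetic controls
#' when a tree is supplied, compares clade group means of g_smax, f_gc and
#' a_gc, and collects an exclusion/validity log. Deterministic given
#' `seed`: stage k of the bootstrap uses seed + k.
#'
#' For a Lambda selection whose own pore-size fit is not significant (or
#' has too few a_max cases), the generic all-species pore-size scaling is
#' substituted and the result flagged `generic_p`.
#'
#' @param traits Species-average tibble (from [ingest_traits()],
#'   [read_trait_csv()] or [generate_traits()]).
#' @param seed Integer seed for all stochastic stages.
#' @param tree Optional `ape::phylo` tree with tips matching
#'   `traits$species`.
#' @param selections Named list of predicates for the allometry table;
#'   defaults to [default_selections()].
#' @param lambda_selections Names of selections for which Lambda is
#'   bootstrapped.
#' @param n_boot Bootstrap replicates per selection.
#' @param constants A [stomatal_constants()] list.
#' @return A list of class `stomalloc_report` with elements
#'   `allometry_table`, `lambda` (tibble), `boot` (list of boot_dist
#'   lists), `groups`, `phylo`, `log`.
#' @export
run_full_analysis <- function(traits, seed, tree = NULL,
                              selections = default_selections(),
                              lambda_selections = c("all_species",
                                                    "angiosperms",
                                                    "gymnosperms",
                                                    "pteridophytes"),
                              n_boot = 500,
                              constants = stomatal_constants()) {
  if (missing(seed)) abort("an explicit integer seed is required")
  log <- list(seed = seed, n_species = nrow(traits))
  rejected <- attr(traits, "rejected")
  log$n_rejected_rows <- if (is.null(rejected)) 0L else nrow(rejected)
  log$dropped_amax <- attr(traits, "dropped_amax") %||% character(0)

  allometry_table <- fit_allometries(traits, selections)

  # generic all-species pore-size fit
  fit_p_all <- sma_fit(traits, a_gc, a_max)

  lambda_rows <- list()
  boots <- list()
  k <- 0L
  for (sel in lambda_selections) {
    k <- k + 1L
    sub <- traits[selections[[sel]](traits), ]
    res <- tryCatch({
      fit_s <- sma_fit(sub, d_s, a_gc)
      n_amax <- sum(!is.na(sub$a_max) & !is.na(sub$a_gc))
      own_p <- if (n_amax >= 5) {
        tryCatch(sma_fit(sub, a_gc, a_max), error = function(e) NULL)
      } else NULL
      generic_p <- is.null(own_p) || !own_p$valid
      fit_p <- if (generic_p) fit_p_all else own_p
      params <- scaling_from_fits(fit_s, fit_p, sub$d_s,
                                  constants = constants)
      d_check <- quantile(sub$d_s, c(0.05, 0.95), type = 7)
      lr <- marginal_ratio(params, d_check = d_check)
      boot <- bootstrap_lambda(
        sub, n_reps = n_boot, seed = seed + k,
        p_traits = if (generic_p) traits else NULL,
        r_wl = constants$r_wl, constants = constants
      )
      boots[[sel]] <- boot
      tibble::tibble(
        selection = sel, n = nrow(sub),
        exponent_s = fit_s$exponent, exponent_p = fit_p$exponent,
        generic_p = generic_p,
        lambda = lr$lambda_value, region = lr$region,
        sign_stable = lr$sign_stable, d_ref = params$d_ref,
        lambda_median = boot$lambda$median,
        lambda_ci_lo = boot$lambda$ci95_lo,
        lambda_ci_hi = boot$lambda$ci95_hi,
        n_boundary = boot$lambda$n_boundary,
        n_dropped = boot$n_dropped
      )
    }, error = function(e) {
      log$stage_errors <<- c(log$stage_errors,
                             setNames(conditionMessage(e), sel))
      NULL
    })
    if (!is.null(res)) lambda_rows[[sel]] <- res
  }
  lambda_tbl <- dplyr::bind_rows(lambda_rows)

  derived <- add_derived_traits(traits, constants)
  groups <- list()
  for (tr in c("g_smax", "f_gc", "a_gc")) {
    groups[[tr]] <- tryCatch(
      compare_groups(derived, !!rlang::sym(tr), clade),
      error = function(e) {
        log$group_errors <<- c(log$group_errors,
                               setNames(conditionMessage(e), tr))
        NULL
      }
    )
  }

  phylo <- NULL
  if (!is.null(tree)) {
    phylo <- list(
      pic_size_density = pic_allometry(tree, traits, d_s, a_gc),
      signal = phylo_signal(tree, traits, c("d_s", "a_gc"))
    )
    if (sum(!is.na(traits$a_max)) >= 5) {
      phylo$pic_pore_size <- tryCatch(
        pic_allometry(tree, traits, a_gc, a_max), error = function(e) NULL)
    }
  }

  log$invalid_fits <- allometry_table$selection[!allometry_table$valid]
  structure(list(allometry_table = allometry_table, lambda = lambda_tbl,
                 boot = boots, groups = groups, phylo = phylo, log = log),
            class = "stomalloc_report")
}

#' @export
print.stomalloc_report <- function(x, ...) {
  cat("Stomatal allocation analysis report\n")
  cat("\nAllometric fits:\n")
  print(as.data.frame(x$allometry_table), row.names = FALSE, digits = 3)
  cat("\nMarginal ratio Lambda per selection:\n")
  print(as.data.frame(x$lambda), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Serialise a report to canonical JSON
#'
#' Deterministic JSON text for a report: identical inputs and seeds yield
#' byte-identical output. Bootstrap sample vectors are summarised, not
#' embedded.
#'
#' @param report A `stomalloc_report`.
#' @return A JSON string.
#' @export
report_json <- function(report) {
  boot_summaries <- purrr::map(report$boot, function(b) {
    list(lambda = tidy(b$lambda), exponent_s = tidy(b$exponent_s),
         exponent_p = tidy(b$exponent_p))
  })
  groups <- purrr::map(purrr::compact(report$groups), function(g) {
    list(trait = g$trait, transform = g$transform,
         anova_f = g$anova_f, anova_p = g$anova_p,
         groups = g$groups, pairwise = g$pairwise)
  })
  phylo <- NULL
  if (!is.null(report$phylo)) {
    phylo <- list(
      pic_size_density = glance(report$phylo$pic_size_density) |>
        dplyr::mutate(exponent = report$phylo$pic_size_density$exponent),
      signal = report$phylo$signal
    )
  }
  jsonlite::toJSON(list(
    allometry_table = report$allometry_table,
    lambda = report$lambda,
    boot = boot_summaries,
    groups = groups,
    phylo = phylo,
    log = report$log
  ), auto_unbox = TRUE, digits = NA, null = "null")
}

#' Write a report bundle to a directory
#'
#' Writes `allometry_table.csv` (the summary-table-shaped fits),
#' `lambda.csv`, `report.json` (full report including the log) and, when
#' present, `phylo_signal.csv`.
#'
#' @param report A `stomalloc_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(as.data.frame(report$allometry_table),
            file.path(dir, "allometry_table.csv"), row.names = FALSE)
  write.csv(as.data.frame(report$lambda),
            file.path(dir, "lambda.csv"), row.names = FALSE)
  writeLines(report_json(report), file.path(dir, "report.json"))
  if (!is.null(report$phylo)) {
    write.csv(as.data.frame(report$phylo$signal),
              file.path(dir, "phylo_signal.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Morphospace plot of the size-density allometry
#'
#' Log-log scatter of guard-cell pair area against stomatal density,
#' coloured by clade, with iso-cover lines (constant f_gc = D_s * a_gc,
#' slope -1 in log-log space) marking the area-preserving direction.
#'
#' @param traits Species-average tibble.
#' @param iso_fgc Cover fractions for the iso-lines.
#' @return A ggplot object.
#' @export
plot_morphospace <- function(traits, iso_fgc = c(0.01, 0.05, 0.2)) {
  iso <- tidyr::expand_grid(
    f = iso_fgc,
    log_d = seq(log10(min(traits$d_s)), log10(max(traits$d_s)),
                length.out = 20)
  ) |>
    dplyr::mutate(d_s = 10^.data$log_d, a_gc = .data$f / .data$d_s)
  ggplot2::ggplot(traits, ggplot2::aes(x = .data$d_s, y = .data$a_gc)) +
    ggplot2::geom_line(data = iso,
                       ggplot2::aes(group = .data$f),
                       linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$clade), alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(D[s] ~ (m^-2)),
                  y = expression(a[gc] ~ (m^2)), colour = "Clade") +
    ggplot2::theme_minimal()
}

#' Scatter-and-line plot of an SMA fit
#'
#' @param object An `sma_fit` from [sma_fit()].
#' @param data The data frame the fit was computed from.
#' @param ... Unused.
#' @return A ggplot object on log10-log10 axes with the fitted SMA line.
#' @method autoplot sma_fit
#' @export
autoplot.sma_fit <- function(object, data, ...) {
  if (object$through_origin) {
    abort("autoplot for through-origin (contrast) fits is not defined; plot the contrasts directly")
  }
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[object$x_name]],
                                     y = .data[[object$y_name]])) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = object$exponent,
                         intercept = object$intercept, colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = object$x_name, y = object$y_name) +
    ggplot2::theme_minimal()
}
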