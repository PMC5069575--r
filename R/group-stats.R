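#' Default variance-stabilising transforms per trait
#'
#' Group comparisons of conductance use square-root transformed values;
#' comparisons of cover fraction and guard-cell size use log10 values.
#'
#' @param trait_name One of the trait column names.
#' @return `"sqrt"`, `"log10"` or `"none"`.
#' @export
default_transform <- function(trait_name) {
  switch(trait_name,
         g_smax = "sqrt",
         f_gc = "log10",
         a_gc = "log10",
         "none")
}

#' Compare group means of a trait across clades or subclades
#'
#' Applies the trait's variance-stabilising transform, runs a one-way
#' ANOVA across the groups, then all pairwise Welch t-tests (unequal
#' sample sizes and variances, Welch-Satterthwaite degrees of freedom)
#' with a Bonferroni correction equal to the number of pairwise tests
#' (3 for three groups). Letter groupings are assigned greedily over the
#' graph of non-significant pairs: groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param data A tibble of species-level values.
#' @param trait Bare column name of the trait.
#' @param group Bare column name of the grouping factor (>= 2 levels,
#'   each with >= 2 observations).
#' @param transform `"sqrt"`, `"log10"`, `"none"`, or `NULL` to use
#'   [default_transform()] on the trait name.
#' @param alpha Significance level for the corrected pairwise tests.
#' @return An object of class `group_comparison`: `trait`, `transform`,
#'   `groups` (per-group n/mean/variance on the transformed scale, with
#'   letters), `anova_f`, `anova_p`, `pairwise` (tibble with raw and
#'   Bonferroni-corrected p-values).
#' @export
compare_groups <- function(data, trait, group, transform = NULL,
                           alpha = 0.05) {
  trait_name <- rlang::as_name(rlang::enquo(trait))
  group_name <- rlang::as_name(rlang::enquo(group))
  if (is.null(transform)) transform <- default_transform(trait_name)
  y <- data[[trait_name]]
  g <- as.character(data[[group_name]])
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]
  g <- g[keep]
  y <- switch(transform,
              sqrt = {
                if (any(y < 0)) abort("sqrt transform needs non-negative values")
                sqrt(y)
              },
              log10 = {
                if (any(y <= 0)) abort("log10 transform needs positive values")
                log10(y)
              },
              none = y,
              abort("unknown transform"))
  lv <- sort(unique(g))
  if (length(lv) < 2) abort("need at least 2 groups")
  sizes <- table(g)
  if (any(sizes < 2)) abort("each group needs at least 2 observations")
  zero_var <- lv[vapply(lv, function(l) var(y[g == l]) == 0, logical(1))]
  if (length(zero_var) > 0) {
    abort(paste0("zero variance in group(s): ",
                 paste(zero_var, collapse = ", ")))
  }

  fit <- aov(y ~ factor(g))
  at <- anova(fit)
  anova_f <- at$`F value`[1]
  anova_p <- at$`Pr(>F)`[1]

  pairs <- utils::combn(lv, 2, simplify = FALSE)
  n_tests <- length(pairs)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    yi <- y[g == pr[1]]
    yj <- y[g == pr[2]]
    tt <- stats::t.test(yi, yj, var.equal = FALSE)
    p_b <- min(1, n_tests * tt$p.value)
    tibble::tibble(group_i = pr[1], group_j = pr[2],
                   welch_t = unname(tt$statistic),
                   df = unname(tt$parameter),
                   p_raw = tt$p.value, p_bonferroni = p_b,
                   significant = p_b < alpha)
  })

  groups <- tibble::tibble(
    group = lv,
    n = as.integer(sizes[lv]),
    mean = unname(vapply(lv, function(l) mean(y[g == l]), numeric(1))),
    variance = unname(vapply(lv, function(l) var(y[g == l]), numeric(1)))
  )
  groups$letters <- assign_letters(lv, pairwise)

  structure(list(trait = trait_name, transform = transform,
                 groups = groups, anova_f = anova_f, anova_p = anova_p,
                 pairwise = pairwise),
            class = "group_comparison")
}

# Greedy letter assignment: groups not significantly different share a
# letter; every group gets at least one letter.
assign_letters <- function(lv, pairwise) {
  k <- length(lv)
  differs <- matrix(FALSE, k, k, dimnames = list(lv, lv))
  for (i in seq_len(nrow(pairwise))) {
    if (pairwise$significant[i]) {
      differs[pairwise$group_i[i], pairwise$group_j[i]] <- TRUE
      differs[pairwise$group_j[i], pairwise$group_i[i]] <- TRUE
    }
  }
  cliques <- list()
  for (gname in lv) {
    placed <- FALSE
    for (ci in seq_along(cliques)) {
      if (!any(differs[gname, cliques[[ci]]])) {
        cliques[[ci]] <- c(cliques[[ci]], gname)
        placed <- TRUE
      }
    }
    if (!placed) cliques <- c(cliques, list(gname))
  }
  labs <- vapply(lv, function(gname) {
    paste0(letters[which(vapply(cliques, function(cl) gname %in% cl,
                                logical(1)))], collapse = "")
  }, character(1))
  unname(labs)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison of %s (%s scale): ANOVA F = %.3f, p = %.3g\n",
              x$trait, x$transform, x$anova_f, x$anova_p))
  print(as.data.frame(x$groups), row.names = FALSE)
  cat("Pairwise Welch t-tests (Bonferroni x", nrow(x$pairwise), "):\n")
  print(as.data.frame(x$pairwise), row.names = FALSE)
  invisible(x)
}

#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  x$pairwise
}

#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(trait = x$trait, transform = x$transform,
                 anova_f = x$anova_f, anova_p = x$anova_p,
                 n_groups = nrow(x$groups),
                 n_significant_pairs = sum(x$pairwise$significant))
}
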