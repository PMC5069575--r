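#' Configuration for the synthetic trait generator
#'
#' Describes a clade-structured synthetic dataset with the statistical
#' structure the allometric analysis assumes: per clade, a latent log10
#' stomatal density drawn uniformly in a clade-specific window, guard-cell
#' size on the exact allometry a_gc = b_s * D_s^S and maximum pore area on
#' a_max = b_p * a_gc^P, with independent log-normal observation scatter
#' on every trait column.
#'
#' Scatter is placed on both axes of each relationship in the proportion
#' the symmetric (SMA) estimator assumes — column SDs
#' sigma/(sqrt(2)|S|) on log10 D_s, sigma/sqrt(2) on log10 a_gc and
#' |P| sigma/sqrt(2) on log10 a_max — so that the fitted SMA exponents are
#' consistent for the generating S and P. `scatter_sd_dex` (sigma) is the
#' vertical residual SD of the size-density relation in dex.
#'
#' The defaults emulate the published compilation conditions: three clades with
#' the fitted exponents and offsets of the size-density relationship
#' (angiosperms S = -1.05, b_s = 0.17, n = 927; gymnosperms S = -1.25,
#' b_s = 12, n = 38; pteridophytes S = -0.58, b_s = 3e-5, n = 67), the
#' generic pore-size relationship (P = 0.92, b_p = 0.05) in every clade,
#' scatter of 0.25 dex, a_max availability matching the observed
#' complete-case pattern (roughly a quarter of records), and density
#' windows placing pteridophytes at few large stomata and angiosperms
#' across a wide range.
#'
#' @param clades A tibble with one row per clade and columns `clade`,
#'   `n_species`, `log10_d_min`, `log10_d_max` (density window, log10
#'   m^-2), `s_true`, `b_s_true`, `p_true`, `b_p_true`, `scatter_sd_dex`,
#'   `fraction_with_amax`, `fraction_amphistomatous`.
#' @param seed Mandatory integer seed.
#' @param r_wl Width:length ratio used to back-fill guard-cell dimensions.
#' @param dimension_noise Multiplicative noise SD on back-filled l_gc and
#'   w_gc (default 5%).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(clades = NULL, seed, r_wl = 0.36,
                             dimension_noise = 0.05) {
  if (missing(seed)) abort("synthetic_config requires an explicit seed")
  if (is.null(clades)) {
    clades <- tibble::tibble(
      clade = c("angiosperm", "gymnosperm", "pteridophyte"),
      n_species = c(927L, 38L, 67L),
      log10_d_min = c(7.3, 7.0, 6.8),
      log10_d_max = c(9.3, 8.3, 8.0),
      s_true = c(-1.05, -1.25, -0.58),
      b_s_true = c(0.17, 12, 3.0e-5),
      p_true = c(0.92, 0.92, 0.92),
      b_p_true = c(0.05, 0.05, 0.05),
      scatter_sd_dex = c(0.25, 0.25, 0.25),
      fraction_with_amax = c(0.23, 0.60, 0.21),
      fraction_amphistomatous = c(0.12, 0, 0)
    )
  }
  clades <- tibble::as_tibble(clades)
  stopifnot(all(clades$fraction_with_amax >= 0 & clades$fraction_with_amax <= 1),
            all(clades$fraction_amphistomatous >= 0 &
                  clades$fraction_amphistomatous <= 1),
            all(clades$scatter_sd_dex >= 0), all(clades$s_true != 0))
  structure(list(clades = clades, seed = seed, r_wl = r_wl,
                 dimension_noise = dimension_noise),
            class = "synthetic_config")
}

#' Generate a synthetic species-average trait table
#'
#' Draws species records from the clade-structured model of
#' [synthetic_config()]. Maximum pore areas violating a_max < a_gc are
#' redrawn (mirroring the exclusion of such records from real
#' compilations, while keeping the log-linear model clean); a window in
#' which the violation cannot be avoided is an error. Guard-cell length
#' and width are back-filled from a_gc via the width:length ratio with 5%
#' multiplicative measurement noise. Deterministic given the config seed.
#'
#' @param config A [synthetic_config()] object.
#' @return A species-average tibble with the same columns as
#'   [ingest_traits()] output plus `l_gc`, `w_gc`, `morphology_class`,
#'   `source_id`.
#' @export
generate_traits <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_preserved_seed(config$seed, {
    out <- purrr::pmap_dfr(config$clades, function(clade, n_species,
                                                   log10_d_min, log10_d_max,
                                                   s_true, b_s_true, p_true,
                                                   b_p_true, scatter_sd_dex,
                                                   fraction_with_amax,
                                                   fraction_amphistomatous) {
      # latent exact allometries; observation noise split over the columns
      # in the SMA-consistent ratio (see synthetic_config)
      s_d <- scatter_sd_dex / (sqrt(2) * abs(s_true))
      s_a <- scatter_sd_dex / sqrt(2)
      s_m <- abs(p_true) * scatter_sd_dex / sqrt(2)
      l_d0 <- runif(n_species, log10_d_min, log10_d_max)
      l_agc0 <- log10(b_s_true) + s_true * l_d0
      l_amax0 <- log10(b_p_true) + p_true * l_agc0
      l_d <- l_d0 + rnorm(n_species, 0, s_d)
      l_agc <- l_agc0 + rnorm(n_species, 0, s_a)
      has_amax <- runif(n_species) < fraction_with_amax
      l_amax <- rep(NA_real_, n_species)
      for (i in which(has_amax)) {
        for (try in 1:1000) {
          cand <- l_amax0[i] + rnorm(1, 0, s_m)
          if (cand < l_agc[i]) break
          cand <- NA_real_
        }
        if (is.na(cand)) {
          abort("infeasible window: a_max >= a_gc cannot be avoided")
        }
        l_amax[i] <- cand
      }
      a_gc <- 10^l_agc
      w_gc <- sqrt(2 * a_gc * config$r_wl / pi) *
        (1 + rnorm(n_species, 0, config$dimension_noise))
      l_gc <- sqrt(2 * a_gc / (pi * config$r_wl)) *
        (1 + rnorm(n_species, 0, config$dimension_noise))
      subclade <- if (clade == "angiosperm") {
        ifelse(runif(n_species) < 0.3, "monocot", "dicot")
      } else {
        rep(NA_character_, n_species)
      }
      tibble::tibble(
        species = sprintf("%s_sp_%04d", clade, seq_len(n_species)),
        clade = clade,
        subclade = subclade,
        amphistomatous = runif(n_species) < fraction_amphistomatous,
        d_s = 10^l_d,
        a_gc = a_gc,
        a_max = 10^l_amax,
        l_gc = l_gc,
        w_gc = w_gc,
        morphology_class = dplyr::if_else(
          !is.na(subclade) & subclade == "monocot",
          "graminoid", "kidney_shaped"),
        n_sources = 1L,
        source_id = "synthetic"
      )
    })
    out
  })
}

#' True marginal-ratio parameters of a synthetic clade
#'
#' Convenience accessor: the generating parameters of one clade row as a
#' [scaling_parameters()] object, with `d_ref` at the geometric mean
#' (log-midpoint) of the clade's density window.
#'
#' @param config A [synthetic_config()] object.
#' @param clade Clade name.
#' @inheritParams scaling_parameters
#' @return A [scaling_parameters()] object.
#' @export
true_scaling <- function(config, clade,
                         constants = stomatal_constants()) {
  row <- config$clades[config$clades$clade == clade, ]
  if (nrow(row) != 1) abort(paste0("unknown clade: ", clade))
  d_ref <- 10^((row$log10_d_min + row$log10_d_max) / 2)
  scaling_parameters(row$b_s_true, row$s_true, row$b_p_true, row$p_true,
                     d_ref = d_ref, r_wl = config$r_wl,
                     constants = constants)
}

#' Simulate a pure-birth tree with a Brownian-motion trait
#'
#' Generates a Yule (pure-birth) tree with exactly `n_tips` tips and
#' simulates a trait along its branches by Brownian motion from a root
#' value of 0: each edge adds an independent normal increment with
#' variance `bm_rate` times the edge length. Deterministic given `seed`.
#'
#' @param n_tips Number of tips (>= 3).
#' @param birth_rate Speciation rate of the Yule process.
#' @param bm_rate Brownian-motion rate (variance per unit branch length).
#' @param seed Integer seed.
#' @return A list: `tree` (`ape::phylo`, ultrametric) and `traits`
#'   (named numeric tip vector).
#' @export
generate_tree_and_traits <- function(n_tips, birth_rate = 1, bm_rate = 1,
                                     seed) {
  if (missing(seed)) abort("an explicit seed is required")
  if (n_tips < 3) abort("n_tips must be >= 3")
  with_preserved_seed(seed, {
    tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
    traits <- simulate_bm(tree, bm_rate)
    list(tree = tree, traits = traits)
  })
}

#' Simulate a Brownian-motion trait on an existing tree
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param bm_rate Brownian-motion rate (variance per unit branch length).
#' @param seed Integer seed.
#' @return Named numeric vector of tip values (root value 0).
#' @export
simulate_bm_seeded <- function(tree, bm_rate, seed) {
  with_preserved_seed(seed, simulate_bm(tree, bm_rate))
}

# Brownian motion along the edges of a phylo tree; root value 0.
simulate_bm <- function(tree, bm_rate) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  val <- numeric(ntip + nnode)
  root <- ntip + 1
  # preorder: parents before children
  eo <- rev(ape::postorder(tree))
  for (e in eo) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    val[child] <- val[parent] +
      rnorm(1, 0, sqrt(bm_rate * tree$edge.length[e]))
  }
  setNames(val[seq_len(ntip)], tree$tip.label)
}
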