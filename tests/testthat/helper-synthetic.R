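# Small single-clade generator configs used across the suite.

one_clade_config <- function(seed, n = 300, s_true = -1.05, p_true = 0.92,
                             b_s = 0.17, b_p = 0.05, scatter = 0.25,
                             frac_amax = 0.3, dmin = 7.3, dmax = 9.3,
                             clade = "angiosperm", frac_amphi = 0) {
  synthetic_config(
    clades = tibble::tibble(
      clade = clade, n_species = as.integer(n), log10_d_min = dmin,
      log10_d_max = dmax, s_true = s_true, b_s_true = b_s,
      p_true = p_true, b_p_true = b_p, scatter_sd_dex = scatter,
      fraction_with_amax = frac_amax, fraction_amphistomatous = frac_amphi
    ),
    seed = seed
  )
}

random_scaling <- function() {
  scaling_parameters(
    b_s = 10^runif(1, -2, 1), s = runif(1, -2, 0.5),
    b_p = 10^runif(1, -3, 0), p = runif(1, 0.1, 2),
    d_ref = 10^runif(1, 7, 9)
  )
}

# Raw literature-style rows for ingest tests (conventional units:
# stomata mm^-2, um, um^2).
raw_rows <- function() {
  tibble::tibble(
    species = c("Hypo una", "Hypo una", "Amphi duo", "Badrow tres",
                "Eqn six", "Bigpore quat"),
    clade = c("angiosperm", "angiosperm", "angiosperm", "angiosperm",
              "gymnosperm", "angiosperm"),
    subclade = c("dicot", "dicot", "monocot", NA, NA, "dicot"),
    d_s_abaxial = c(100, 200, 100, NA, 80, 150),
    d_s_adaxial = c(NA, NA, 20, NA, NA, NA),
    a_gc = c(250, 250, 300, 200, NA, 100),
    l_gc = c(NA, NA, NA, NA, 20, NA),
    w_gc = c(NA, NA, NA, NA, 7.2, NA),
    l_p = c(NA, NA, NA, NA, NA, 40),
    morphology_class = c(NA, NA, "graminoid", NA, "kidney_shaped",
                         "circular_pore"),
    source_id = c("s1", "s2", "s1", "s1", "s3", "s4")
  )
}
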