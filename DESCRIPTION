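Package: stomalloc
Title: Spatially Optimal Allometry of Stomatal Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the allocation of leaf epidermal area to
    stomata. Computes anatomical maximum stomatal conductance (g_smax) and
    epidermal stomatal cover (f_gc) from morphological traits, fits the
    allometric scaling of guard-cell size against stomatal density and of
    maximum pore area against guard-cell size by standardized major axis
    (SMA) regression on log10-transformed species averages, evaluates the
    marginal benefit:cost ratio of adding stomata (Lambda) with its
    exponent-plane sign regions, bootstraps the paired scaling fits,
    and runs phylogenetic controls (independent contrasts, Blomberg's K,
    Pagel's lambda) and clade-level group comparisons. Includes a
    clade-structured synthetic trait and tree generator for parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
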