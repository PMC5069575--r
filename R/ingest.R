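#' Ingest raw stomatal-trait rows into a species-average table
#'
#' Applies the compilation rules used to build species-average trait tables
#' from heterogeneous literature rows:
#' \itemize{
#'   \item rows must carry at least `species`, `clade` and an abaxial
#'     density together with either `a_gc` or both guard-cell dimensions;
#'     offending rows are rejected, with reasons, in the `rejected`
#'     attribute;
#'   \item densities reported for both leaf surfaces with an
#'     adaxial:abaxial ratio above 0.05 flag the species amphistomatous,
#'     and its density is the mean of the two surfaces; otherwise the
#'     abaxial density is used;
#'   \item `a_gc` is taken as reported or computed from guard-cell length
#'     and width via [guard_cell_pair_area()];
#'   \item `a_max` is computed from pore length via [max_pore_area()] with
#'     the morphology-class shape fraction [flw_for_class()];
#'   \item observations are averaged arithmetically within each source and
#'     then across sources (grand mean) to one row per species;
#'   \item species for which the averaged `a_max` is not smaller than
#'     `a_gc` have `a_max` set missing (the record is retained) with a
#'     warning naming the species.
#' }
#'
#' @param raw A data frame with columns `species`, `clade` and any of
#'   `subclade`, `d_s_abaxial`, `d_s_adaxial`, `a_gc`, `l_gc`, `w_gc`,
#'   `l_p`, `morphology_class`, `source_id`.
#' @param density_unit Unit of the density columns: `"per_m2"` or
#'   `"per_mm2"` (converted by 1e6).
#' @param length_unit Unit of `l_gc`, `w_gc`, `l_p`: `"m"` or `"um"`.
#' @param area_unit Unit of `a_gc`: `"m2"` or `"um2"`.
#'
#' @return A tibble with one row per species and SI-unit columns `species`,
#'   `clade`, `subclade`, `amphistomatous`, `d_s` (m^-2), `a_gc` (m^2),
#'   `a_max` (m^2, `NA` when unavailable), `n_sources`. Attributes
#'   `rejected` (tibble of rejected rows and reasons) and `dropped_amax`
#'   (species whose a_max was excluded) carry the ingest log.
#' @examples
#' raw <- tibble::tibble(
#'   species = c("A sp", "A sp"), clade = "angiosperm",
#'   d_s_abaxial = c(100, 200), a_gc = c(250, 250), source_id = c("s1", "s2")
#' )
#' ingest_traits(raw, density_unit = "per_mm2", area_unit = "um2")
#' @export
ingest_traits <- function(raw,
                          density_unit = c("per_m2", "per_mm2"),
                          length_unit = c("m", "um"),
                          area_unit = c("m2", "um2")) {
  density_unit <- match.arg(density_unit)
  length_unit <- match.arg(length_unit)
  area_unit <- match.arg(area_unit)
  raw <- tibble::as_tibble(raw)

  optional <- c("subclade", "d_s_abaxial", "d_s_adaxial", "a_gc", "l_gc",
                "w_gc", "l_p", "morphology_class", "source_id")
  for (col in optional) {
    if (!col %in% names(raw)) raw[[col]] <- NA
  }
  if (!all(c("species", "clade") %in% names(raw))) {
    abort("raw table must have `species` and `clade` columns")
  }

  d_fac <- if (density_unit == "per_mm2") 1e6 else 1
  l_fac <- if (length_unit == "um") 1e-6 else 1
  a_fac <- if (area_unit == "um2") 1e-12 else 1
  raw <- dplyr::mutate(raw,
    d_s_abaxial = as.numeric(.data$d_s_abaxial) * d_fac,
    d_s_adaxial = as.numeric(.data$d_s_adaxial) * d_fac,
    a_gc = as.numeric(.data$a_gc) * a_fac,
    l_gc = as.numeric(.data$l_gc) * l_fac,
    w_gc = as.numeric(.data$w_gc) * l_fac,
    l_p = as.numeric(.data$l_p) * l_fac,
    source_id = dplyr::coalesce(as.character(.data$source_id), "unknown")
  )

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(raw$species) | raw$species == ""] <- "missing species"
  no_clade <- is.na(reason) & (is.na(raw$clade) | raw$clade == "")
  reason[no_clade] <- "missing clade"
  no_d <- is.na(reason) & (is.na(raw$d_s_abaxial) | raw$d_s_abaxial <= 0)
  reason[no_d] <- "missing or non-positive stomatal density"
  no_size <- is.na(reason) & is.na(raw$a_gc) &
    (is.na(raw$l_gc) | is.na(raw$w_gc))
  reason[no_size] <- "no guard-cell size (a_gc or l_gc + w_gc)"
  rejected <- dplyr::bind_cols(raw[!is.na(reason), ],
                               tibble::tibble(reason = reason[!is.na(reason)]))
  if (nrow(rejected) > 0) {
    inform(paste0(nrow(rejected), " row(s) rejected during ingest"))
  }
  rows <- raw[is.na(reason), ]

  rows <- dplyr::mutate(rows,
    a_gc = dplyr::if_else(is.na(.data$a_gc),
                          (pi / 2) * .data$l_gc * .data$w_gc, .data$a_gc),
    f_lw = flw_for_class(.data$morphology_class),
    a_max = dplyr::if_else(is.na(.data$l_p), NA_real_,
                           (pi / 4) * .data$f_lw * .data$l_p^2),
    amphistomatous = !is.na(.data$d_s_adaxial) &
      .data$d_s_adaxial / .data$d_s_abaxial > 0.05,
    d_s = dplyr::if_else(.data$amphistomatous,
                         (.data$d_s_abaxial + .data$d_s_adaxial) / 2,
                         .data$d_s_abaxial)
  )

  # arithmetic mean within source, then grand mean across sources
  per_source <- rows |>
    dplyr::group_by(.data$species, .data$source_id) |>
    dplyr::summarise(
      clade = dplyr::first(.data$clade),
      subclade = dplyr::first(.data$subclade),
      amphistomatous = any(.data$amphistomatous),
      d_s = mean(.data$d_s),
      a_gc = mean(.data$a_gc),
      a_max = mean_or_na(.data$a_max),
      .groups = "drop"
    )
  species <- per_source |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      clade = dplyr::first(.data$clade),
      subclade = dplyr::first(.data$subclade),
      amphistomatous = any(.data$amphistomatous),
      d_s = mean(.data$d_s),
      a_gc = mean(.data$a_gc),
      a_max = mean_or_na(.data$a_max),
      n_sources = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$species)

  bad_amax <- !is.na(species$a_max) & species$a_max >= species$a_gc
  if (any(bad_amax)) {
    warn(paste0("a_max >= a_gc deemed unrealistic; dropping a_max for: ",
                paste(species$species[bad_amax], collapse = ", ")))
    species$a_max[bad_amax] <- NA_real_
  }

  attr(species, "rejected") <- rejected
  attr(species, "dropped_amax") <- species$species[bad_amax]
  species
}

mean_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else mean(x)
}

#' Read a raw stomatal-trait CSV
#'
#' Thin wrapper around [ingest_traits()] for CSV input. The expected header
#' is the documented raw schema (`species`, `clade`, `subclade`,
#' `d_s_abaxial`, `d_s_adaxial`, `a_gc`, `l_gc`, `w_gc`, `l_p`,
#' `morphology_class`, `source_id`); conventional field units
#' (stomata mm^-2, um, um^2) are the default.
#'
#' @param path CSV file path.
#' @inheritParams ingest_traits
#' @return See [ingest_traits()].
#' @export
read_trait_csv <- function(path, density_unit = "per_mm2",
                           length_unit = "um", area_unit = "um2") {
  raw <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  ingest_traits(raw, density_unit = density_unit,
                length_unit = length_unit, area_unit = area_unit)
}

#' Write a normalized species-average table as CSV (SI units)
#'
#' @param traits Species-average tibble from [ingest_traits()] or
#'   [generate_traits()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trait_csv <- function(traits, path) {
  write.csv(as.data.frame(traits), path, row.names = FALSE)
  invisible(path)
}

#' Derived anatomical quantities for a species-average table
#'
#' Adds epidermal cover `f_gc`, pore depth `d_p` (recomputed from `a_gc`
#' via the width:length ratio) and anatomical maximum conductance `g_smax`
#' (where `a_max` is available) to a species-average trait table.
#'
#' @param traits Species-average tibble with SI columns `d_s`, `a_gc` and
#'   optionally `a_max`.
#' @param constants A [stomatal_constants()] list.
#' @return The input tibble with columns `f_gc`, `d_p` and `g_smax` added.
#' @export
add_derived_traits <- function(traits, constants = stomatal_constants()) {
  traits |>
    dplyr::mutate(
      f_gc = f_gc(.data$d_s, .data$a_gc),
      d_p = pore_depth_from_agc(.data$a_gc, constants$r_wl),
      g_smax = dplyr::if_else(
        is.na(.data$a_max), NA_real_,
        (constants$d_h2o / constants$w_v) * .data$d_s *
          dplyr::coalesce(.data$a_max, 0) /
          (.data$d_p + (pi / 2) * sqrt(dplyr::coalesce(.data$a_max, 1) / pi))
      )
    )
}
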