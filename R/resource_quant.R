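#' Density of a sucrose solution
#'
#' Converts a refractometer reading C (g sucrose per 100 g solution) into
#' solution density (g/mL) with the quadratic calibration polynomial
#' d = 0.0037921 C + 0.0000178 C^2 + 0.9988603, the standard conversion used
#' in floral nectar surveys.
#'
#' @param concentration Refractometer reading(s), g sucrose per 100 g
#'   solution.
#' @param max_concentration Upper bound of the refractometer's physical
#'   range (default 85).
#' @return Density in g/mL; strictly increasing in `concentration`.
#' @export
sucrose_density <- function(concentration, max_concentration = 85) {
  if (any(is.na(concentration)) ||
      any(concentration < 0 | concentration > max_concentration)) {
    stop_florivis(
      sprintf("concentration must lie in [0, %g]", max_concentration),
      "florivis_domain_error")
  }
  0.0037921 * concentration + 0.0000178 * concentration^2 + 0.9988603
}

#' Nectar sugar mass per flower
#'
#' Sugar mass s (ug) is s = 10 d v C, where v is the nectar volume (uL), C
#' the refractometer concentration (g/100 g) and d the solution density from
#' [sucrose_density()].  For flowers too small for direct microcapillary
#' extraction, nectar is instead rinsed out with distilled water (2 uL in the
#' original protocol) and the same formula is applied to the diluted
#' solution, with v the rinse volume and C the diluted reading.
#'
#' @param nectar A data frame of nectar measurements with columns
#'   `species_id`, `method` (`"direct"` or `"rinse"`), `nectar_volume_ul`,
#'   `concentration`, `rinse_volume_ul`.
#' @return The input tibble with a `sugar_ug` column appended.
#' @export
nectar_sugar_mass <- function(nectar) {
  nectar <- tibble::as_tibble(nectar)
  if (!all(nectar$method %in% c("direct", "rinse"))) {
    stop_florivis("nectar method must be 'direct' or 'rinse'",
                  "florivis_validation_error")
  }
  direct <- nectar$method == "direct"
  v <- ifelse(direct, nectar$nectar_volume_ul, nectar$rinse_volume_ul)
  if (anyNA(v)) {
    stop_florivis("missing nectar_volume_ul (direct) or rinse_volume_ul (rinse)",
                  "florivis_validation_error")
  }
  if (any(v < 0)) {
    stop_florivis("nectar volumes must be >= 0", "florivis_validation_error")
  }
  nectar$sugar_ug <-
    10 * sucrose_density(nectar$concentration) * v * nectar$concentration
  nectar
}

#' Total pollen grains per flower
#'
#' Stamens of one flower are suspended in U uL of sucrose solution and two
#' 10-uL aliquots are counted under the microscope; the per-flower grain
#' count is the aliquot mean scaled back to the full suspension:
#' N = mean(counts) * U / 10.
#'
#' @param aliquot_count_1,aliquot_count_2 Grain counts of the two 10-uL
#'   mounts.
#' @param suspension_volume_ul Initial suspension volume U (uL), > 0.
#' @return Estimated grains per flower (dimensionless).
#' @export
grains_per_flower <- function(aliquot_count_1, aliquot_count_2,
                              suspension_volume_ul) {
  if (any(suspension_volume_ul <= 0)) {
    stop_florivis("suspension_volume_ul must be > 0", "florivis_domain_error")
  }
  if (any(aliquot_count_1 < 0) || any(aliquot_count_2 < 0)) {
    stop_florivis("aliquot counts must be >= 0", "florivis_validation_error")
  }
  (aliquot_count_1 + aliquot_count_2) / 2 * suspension_volume_ul / 10
}

#' Volume of a pollen grain
#'
#' Grains are modelled as prolate spheroids: V = 4/3 pi A B^2 (um^3), where
#' A is half the major-axis length and B half the minor-axis length.
#'
#' @param major_axis_um,minor_axis_um Axis lengths (um), major >= minor > 0.
#' @return Grain volume in um^3.
#' @export
grain_volume <- function(major_axis_um, minor_axis_um) {
  if (any(minor_axis_um <= 0)) {
    stop_florivis("axis lengths must be > 0", "florivis_validation_error")
  }
  if (any(minor_axis_um > major_axis_um)) {
    stop_florivis("minor axis exceeds major axis", "florivis_validation_error")
  }
  (4 / 3) * pi * (major_axis_um / 2) * (minor_axis_um / 2)^2
}

#' Per-flower pollen volume
#'
#' Multiplies grains per flower by mean grain volume and converts um^3 to uL
#' (1 uL = 1e9 um^3).
#'
#' @param grains Grains per flower, >= 0.
#' @param grain_volume_um3 Mean grain volume (um^3), >= 0.
#' @return Pollen volume per flower in uL.
#' @export
pollen_volume_per_flower <- function(grains, grain_volume_um3) {
  grains * grain_volume_um3 / 1e9
}

#' Build per-species resource profiles
#'
#' Aggregates raw nectar and pollen measurements into species-level mean
#' resource values: mean nectar sugar mass (ug/flower) and mean pollen
#' volume (uL/flower, species-mean grain count times species-mean grain
#' volume — means are taken before multiplication).  Species with no
#' measurements for a resource are flagged unmeasured (`NA`), never zero;
#' the exception is sugar for species without nectaries, which is zero by
#' definition.
#'
#' @param nectar Nectar measurements (see [nectar_sugar_mass()]); may be
#'   `NULL`.
#' @param pollen_counts Pollen count measurements with columns `species_id`,
#'   `aliquot_count_1`, `aliquot_count_2`, `suspension_volume_ul`; may be
#'   `NULL`.
#' @param pollen_grains Grain-size measurements with columns `species_id`,
#'   `major_axis_um`, `minor_axis_um`; may be `NULL`.
#' @param species Species table; profiles cover exactly these species.
#' @return A tibble with one row per species: `species_id`,
#'   `mean_sugar_ug`, `mean_pollen_ul`, `n_nectar`, `n_pollen`.
#' @export
build_species_profiles <- function(nectar, pollen_counts, pollen_grains,
                                   species) {
  species <- validate_species_table(species)

  prof <- tibble::tibble(
    species_id = species$species_id,
    mean_sugar_ug = ifelse(species$has_nectaries, NA_real_, 0),
    mean_pollen_ul = NA_real_,
    n_nectar = 0L,
    n_pollen = 0L
  )

  if (!is.null(nectar) && nrow(nectar)) {
    check_known_species(nectar$species_id, species)
    nectarless <- species$species_id[!species$has_nectaries]
    if (any(nectar$species_id %in% nectarless)) {
      stop_florivis("nectar measurement recorded for a species without nectaries",
                    "florivis_validation_error")
    }
    s <- nectar_sugar_mass(nectar)
    agg <- dplyr::summarise(dplyr::group_by(s, .data$species_id),
                            mean_sugar_ug = mean(.data$sugar_ug),
                            n_nectar = dplyr::n(), .groups = "drop")
    i <- match(agg$species_id, prof$species_id)
    prof$mean_sugar_ug[i] <- agg$mean_sugar_ug
    prof$n_nectar[i] <- agg$n_nectar
  }

  if (!is.null(pollen_counts) && nrow(pollen_counts) &&
      !is.null(pollen_grains) && nrow(pollen_grains)) {
    check_known_species(pollen_counts$species_id, species)
    check_known_species(pollen_grains$species_id, species)
    counts <- dplyr::mutate(tibble::as_tibble(pollen_counts),
      grains = grains_per_flower(.data$aliquot_count_1, .data$aliquot_count_2,
                                 .data$suspension_volume_ul))
    mean_n <- dplyr::summarise(dplyr::group_by(counts, .data$species_id),
                               mean_grains = mean(.data$grains),
                               n_pollen = dplyr::n(), .groups = "drop")
    # species-mean grain volume from species-mean axis lengths
    axes <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(pollen_grains),
                                             .data$species_id),
                             major = mean(.data$major_axis_um),
                             minor = mean(.data$minor_axis_um),
                             .groups = "drop")
    axes$mean_volume_um3 <- grain_volume(axes$major, axes$minor)
    agg <- dplyr::inner_join(mean_n, axes[c("species_id", "mean_volume_um3")],
                             by = "species_id")
    agg$mean_pollen_ul <- pollen_volume_per_flower(agg$mean_grains,
                                                   agg$mean_volume_um3)
    i <- match(agg$species_id, prof$species_id)
    prof$mean_pollen_ul[i] <- agg$mean_pollen_ul
    prof$n_pollen[i] <- agg$n_pollen
  }

  prof
}

#' Measurement coverage of a profile set
#'
#' Fraction of species whose nectar (among species with nectaries) and
#' pollen were actually measured — the coverage statistics a field study
#' reports alongside its profiles.
#'
#' @param profiles Output of [build_species_profiles()].
#' @param species The species table used to build them.
#' @return A tibble with columns `resource`, `n_measured`, `n_species`,
#'   `pct` (percent, one decimal place as conventionally printed).
#' @export
profile_coverage <- function(profiles, species) {
  nectaried <- species$species_id[species$has_nectaries]
  n_nec <- sum(profiles$n_nectar > 0 & profiles$species_id %in% nectaried)
  n_pol <- sum(profiles$n_pollen > 0)
  tibble::tibble(
    resource = c("nectar", "pollen"),
    n_measured = c(n_nec, n_pol),
    n_species = c(length(nectaried), nrow(species)),
    pct = round(100 * .data$n_measured / .data$n_species, 1)
  )
}

#' Read raw resource-measurement tables
#'
#' @param path CSV path.
#' @return A tibble with the documented columns.
#' @name read_measurements
NULL

#' @rdname read_measurements
#' @export
read_nectar_samples <- function(path) {
  read_survey_csv(path, c("species_id", "method", "nectar_volume_ul",
                          "concentration", "rinse_volume_ul"))
}

#' @rdname read_measurements
#' @export
read_pollen_counts <- function(path) {
  read_survey_csv(path, c("species_id", "aliquot_count_1", "aliquot_count_2",
                          "suspension_volume_ul"))
}

#' @rdname read_measurements
#' @export
read_pollen_grains <- function(path) {
  read_survey_csv(path, c("species_id", "major_axis_um", "minor_axis_um"))
}
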