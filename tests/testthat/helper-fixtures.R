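# Small in-code fixtures shared across tests.

tiny_species <- function() {
  tibble::tibble(
    species_id = c("erigeron", "trifolium", "lamium", "carex_like"),
    origin = c("alien", "alien", "native", "native"),
    has_nectaries = c(TRUE, TRUE, TRUE, FALSE),
    floral_unit_type = c("head", "head", "flower", "flower")
  )
}

tiny_counts <- function() {
  tibble::tibble(
    site = "hanamuro",
    date = as.Date(c("2018-05-01", "2018-05-01", "2018-05-15")),
    plot_id = c("p1", "p2", "p1"),
    species_id = c("erigeron", "trifolium", "lamium"),
    floral_units = c(10L, 4L, 7L)
  )
}

tiny_visits <- function() {
  tibble::tibble(
    site = "hanamuro",
    date = as.Date("2018-05-01"),
    plot_id = "p1",
    species_id = c("erigeron", "erigeron", "lamium", "erigeron", "trifolium"),
    insect_group = c("bee_wasp", "honeybee", "hoverfly", "coleoptera",
                     "hemiptera"),
    count = c(3L, 5L, 2L, 1L, 4L)
  )
}

# nectar measurements engineered so that s = 10 d(C) v C hits given targets
nectar_rows_for <- function(species_id, sugar_targets, concentration = 20) {
  d <- florivis::sucrose_density(concentration)
  tibble::tibble(
    species_id = species_id,
    method = "direct",
    nectar_volume_ul = sugar_targets / (10 * d * concentration),
    concentration = concentration,
    rinse_volume_ul = NA_real_
  )
}

# profile table with given per-species means, bypassing raw measurements
profiles_of <- function(species_id, sugar = NULL, pollen = NULL) {
  n <- length(species_id)
  tibble::tibble(
    species_id = species_id,
    mean_sugar_ug = if (is.null(sugar)) rep(NA_real_, n) else sugar,
    mean_pollen_ul = if (is.null(pollen)) rep(NA_real_, n) else pollen,
    n_nectar = ifelse(is.null(sugar) | is.na(if (is.null(sugar)) rep(NA_real_, n) else sugar), 0L, 5L),
    n_pollen = ifelse(is.null(pollen) | is.na(if (is.null(pollen)) rep(NA_real_, n) else pollen), 0L, 5L)
  )
}

small_config <- function(seed = 1, ...) {
  florivis::simulation_config(n_sites = 1, n_plots = 3,
                              visits_per_site_year = 2000, seed = seed, ...)
}
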