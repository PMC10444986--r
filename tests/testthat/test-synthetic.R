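test_that("generation is seed-deterministic and seed-sensitive", {
  a <- generate_survey_data(small_config(seed = 1))
  b <- generate_survey_data(small_config(seed = 1))
  c <- generate_survey_data(small_config(seed = 2))
  expect_identical(a$tables, b$tables)
  expect_false(identical(a$tables$floral_counts, c$tables$floral_counts))
})

test_that("default config covers the study structure", {
  cfg <- simulation_config()
  ds <- generate_survey_data(cfg)
  expect_equal(dplyr::n_distinct(ds$tables$floral_counts$site), 4)
  expect_equal(dplyr::n_distinct(ds$tables$floral_counts$plot_id), 5)
  yrs <- assign_periods(unique(ds$tables$floral_counts$date))$study_year
  expect_setequal(unique(yrs), 1:2)
  expect_setequal(unique(ds$tables$species$origin), c("alien", "native"))
  # first year surveyed twice as often as the second
  d1 <- unique(ds$tables$floral_counts$date)
  expect_gt(sum(d1 < as.Date("2019-04-14")), 1.5 * sum(d1 >= as.Date("2019-04-14")))
})

test_that("counts are zero outside the flowering window", {
  arch <- default_archetypes()[1, ]
  arch$peak_day <- 60
  arch$duration_days <- 30
  cfg <- simulation_config(n_sites = 1, n_plots = 2, species = arch, seed = 3)
  set.seed(cfg$seed)
  counts <- simulate_phenology_counts(cfg)
  t <- as.numeric(counts$date - as.Date("2018-04-21")) %% 365
  expect_true(all(abs(t - 60) <= 15 | (365 - abs(t - 60)) <= 15))
})

test_that("counts at the flowering peak match the expectation", {
  arch <- default_archetypes()[1, ]
  arch$peak_day <- 56          # a survey day in the 14-day grid
  arch$duration_days <- 60
  arch$peak_units <- 50
  cfg <- simulation_config(n_sites = 1, n_plots = 200, species = arch,
                           count_theta = 50, seed = 9)
  set.seed(cfg$seed)
  counts <- simulate_phenology_counts(cfg)
  at_peak <- counts[as.numeric(counts$date - as.Date("2018-04-21")) == 56, ]
  expect_gt(nrow(at_peak), 150)
  expect_equal(mean(at_peak$floral_units), 50, tolerance = 0.1)
})

test_that("zero-variance nectar archetypes are recovered exactly", {
  arch <- default_archetypes()[1:2, ]
  arch$sugar_sigma <- 0
  arch$sugar_mean_ug <- c(120, 3)   # direct and rinse paths
  cfg <- simulation_config(species = arch, seed = 5)
  set.seed(cfg$seed)
  samples <- simulate_resource_samples(cfg)
  s <- nectar_sugar_mass(samples$nectar)
  m <- tapply(s$sugar_ug, s$species_id, mean)
  expect_equal(as.numeric(m[arch$species_id]), arch$sugar_mean_ug,
               tolerance = 1e-6)
})

test_that("pipeline recovers archetype means from simulated raw samples", {
  arch <- default_archetypes()
  set.seed(1)
  seeds <- sample.int(1e6, 20)
  ok <- vapply(seeds, function(seed) {
    cfg <- simulation_config(species = arch, n_nectar_samples = 50,
                             n_pollen_samples = 50, seed = seed)
    set.seed(cfg$seed)
    samples <- simulate_resource_samples(cfg)
    species <- tibble::tibble(species_id = arch$species_id,
                              origin = arch$origin,
                              has_nectaries = arch$has_nectaries,
                              floral_unit_type = arch$floral_unit_type)
    prof <- build_species_profiles(samples$nectar, samples$pollen_counts,
                                   samples$pollen_grains, species)
    sp <- "alien_01"
    truth_sugar <- arch$sugar_mean_ug[arch$species_id == sp]
    truth_pollen <- arch$grains_mean[arch$species_id == sp] *
      grain_volume(arch$grain_major_um[arch$species_id == sp],
                   arch$grain_minor_um[arch$species_id == sp]) / 1e9
    got <- prof[prof$species_id == sp, ]
    abs(got$mean_sugar_ug / truth_sugar - 1) < 0.15 &&
      abs(got$mean_pollen_ul / truth_pollen - 1) < 0.15
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("species flagged unmeasured emit no measurement rows", {
  cfg <- simulation_config(seed = 2)
  set.seed(cfg$seed)
  samples <- simulate_resource_samples(cfg)
  expect_false("native_07" %in% samples$nectar$species_id)
  expect_false("native_13" %in% samples$nectar$species_id)
  expect_false("native_13" %in% samples$pollen_counts$species_id)
  expect_true("native_07" %in% samples$pollen_counts$species_id)
})

two_species_visit_shares <- function(regime, seed = 17) {
  arch <- default_archetypes()[1:2, ]
  arch$peak_day <- 60
  arch$duration_days <- 365
  arch$peak_units <- 50
  arch$sugar_mean_ug <- c(90, 10)
  arch$grains_mean <- c(9e5, 1e5)
  arch$grain_major_um <- c(20, 20)
  arch$grain_minor_um <- c(20, 20)
  cfg <- simulation_config(n_sites = 1, n_plots = 2, species = arch,
                           visits_per_site_year = 10000, regime = regime,
                           count_theta = 1000, seed = seed)
  set.seed(cfg$seed)
  counts <- simulate_phenology_counts(cfg)
  visits <- simulate_visits(cfg, counts)
  visits <- visits[visits$insect_group %in% c("bee_wasp", "hoverfly",
                                              "butterfly"), ]
  shares <- tapply(visits$count, visits$species_id, sum)
  shares / sum(shares)
}

test_that("resource_proportional visits track resource shares", {
  sh <- two_species_visit_shares("resource_proportional")
  expect_gt(sh[["alien_01"]], 0.88)
  expect_lt(sh[["alien_01"]], 0.92)
})

test_that("even_preference splits visits evenly among flowering species", {
  sh <- two_species_visit_shares("even_preference")
  expect_gt(sh[["alien_01"]], 0.45)
  expect_lt(sh[["alien_01"]], 0.55)
})

test_that("native_biased inflates native visit shares", {
  arch <- default_archetypes()[c(1, 5), ]   # one alien, one native
  arch$peak_day <- 60; arch$duration_days <- 365; arch$peak_units <- 50
  cfg <- simulation_config(n_sites = 1, n_plots = 2, species = arch,
                           regime = "native_biased", native_bias = 3,
                           visits_per_site_year = 10000, seed = 23)
  set.seed(cfg$seed)
  counts <- simulate_phenology_counts(cfg)
  visits <- simulate_visits(cfg, counts)
  visits <- visits[visits$insect_group %in% c("bee_wasp", "hoverfly",
                                              "butterfly"), ]
  shares <- tapply(visits$count, visits$species_id, sum)
  shares <- shares / sum(shares)
  expect_gt(shares[[arch$species_id[2]]], 0.70)   # expectation 0.75
})

test_that("non-flowering species receive no visits", {
  ds <- generate_survey_data(small_config(seed = 6))
  flowering_keys <- with(ds$tables$floral_counts[ds$tables$floral_counts$floral_units > 0, ],
                         paste(site, date, plot_id, species_id))
  visit_keys <- with(ds$tables$visits, paste(site, date, plot_id, species_id))
  expect_true(all(visit_keys %in% flowering_keys))
})

test_that("generated tables pass validation and round-trip through disk", {
  ds <- generate_survey_data(small_config(seed = 8))
  species <- validate_species_table(ds$tables$species)
  expect_silent(validate_visit_records(ds$tables$visits, species))
  expect_message(validate_floral_counts(ds$tables$floral_counts, species))

  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  counts2 <- suppressMessages(
    read_floral_counts(file.path(dir, "floral_counts.csv"), species))
  expect_equal(as.data.frame(counts2),
               as.data.frame(ds$tables$floral_counts))
  visits2 <- read_visit_records(file.path(dir, "visits.csv"), species)
  expect_equal(as.data.frame(visits2), as.data.frame(ds$tables$visits))
})

test_that("generated visits include filterable non-wild records", {
  ds <- generate_survey_data(simulation_config(seed = 11))
  expect_true(any(ds$tables$visits$insect_group %in%
                    c("honeybee", "coleoptera", "hemiptera")))
  kept <- suppressMessages(filter_visits(ds$tables$visits))
  expect_true(all(kept$insect_group %in% c("bee_wasp", "hoverfly",
                                           "butterfly")))
})
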