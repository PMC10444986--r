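test_that("sucrose density follows the calibration polynomial", {
  expect_equal(sucrose_density(0), 0.9988603)
  expect_equal(sucrose_density(20), 1.0818223)
  expect_gt(sucrose_density(50), sucrose_density(20))
  expect_error(sucrose_density(-1), class = "florivis_domain_error")
  expect_error(sucrose_density(86), class = "florivis_domain_error")
  expect_equal(sucrose_density(90, max_concentration = 95),
               0.0037921 * 90 + 0.0000178 * 8100 + 0.9988603)
})

test_that("nectar sugar mass follows s = 10 d v C for both methods", {
  direct <- tibble::tibble(species_id = "sp", method = "direct",
                           nectar_volume_ul = c(0, 1),
                           concentration = c(30, 20),
                           rinse_volume_ul = NA_real_)
  s <- nectar_sugar_mass(direct)$sugar_ug
  expect_equal(s[1], 0)
  expect_equal(s[2], 216.36446)

  rinse <- tibble::tibble(species_id = "sp", method = "rinse",
                          nectar_volume_ul = NA_real_, concentration = 5,
                          rinse_volume_ul = 2)
  expect_equal(nectar_sugar_mass(rinse)$sugar_ug,
               10 * sucrose_density(5) * 2 * 5)

  missing <- direct
  missing$nectar_volume_ul <- NA_real_
  expect_error(nectar_sugar_mass(missing), class = "florivis_validation_error")
})

test_that("sugar mass is linear in nectar volume at fixed concentration", {
  v <- runif(50, 0, 5)
  base <- nectar_rows_for("sp", rep(1, 50))
  base$nectar_volume_ul <- v
  doubled <- base
  doubled$nectar_volume_ul <- 2 * v
  expect_equal(nectar_sugar_mass(doubled)$sugar_ug,
               2 * nectar_sugar_mass(base)$sugar_ug)
})

test_that("grain counts scale the aliquot mean to the suspension volume", {
  expect_equal(grains_per_flower(0, 0, 500), 0)
  expect_equal(grains_per_flower(40, 60, 100), 500)
  expect_equal(grains_per_flower(10, 10, 30), 30)
  expect_error(grains_per_flower(10, 10, 0), class = "florivis_domain_error")
})

test_that("grain volume is the spheroid 4/3 pi A B^2", {
  expect_equal(grain_volume(10, 10), 4 / 3 * pi * 125, tolerance = 1e-12)
  expect_equal(grain_volume(20, 10), 4 / 3 * pi * 10 * 25, tolerance = 1e-12)
  expect_error(grain_volume(10, 0), class = "florivis_validation_error")
  expect_error(grain_volume(10, 12), class = "florivis_validation_error")
})

test_that("per-flower pollen volume converts um^3 to uL", {
  expect_equal(pollen_volume_per_flower(0, 1000), 0)
  expect_equal(pollen_volume_per_flower(1e6, 1000), 1)
  expect_equal(pollen_volume_per_flower(500, 1047.1976), 5.2360e-4,
               tolerance = 1e-4)
})

test_that("pollen volume equals a per-grain brute-force oracle", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    vols <- runif(n, 100, 5000)   # individual grain volumes, um^3
    # pipeline path: grains per flower x mean grain volume
    pipeline <- pollen_volume_per_flower(n, mean(vols))
    # oracle: convert each grain individually and sum
    oracle <- sum(vols / 1e9)
    expect_equal(pipeline, oracle, tolerance = 1e-12)
  }
})

test_that("species profiles average samples and flag unmeasured species", {
  species <- tiny_species()
  nectar <- nectar_rows_for("erigeron", c(100, 200))
  pc <- tibble::tibble(species_id = "trifolium", aliquot_count_1 = 40,
                       aliquot_count_2 = 60, suspension_volume_ul = 100)
  pg <- tibble::tibble(species_id = "trifolium", major_axis_um = 20,
                       minor_axis_um = 10)
  prof <- build_species_profiles(nectar, pc, pg, species)

  expect_equal(prof$mean_sugar_ug[prof$species_id == "erigeron"], 150)
  expect_equal(prof$n_nectar[prof$species_id == "erigeron"], 2L)
  # pollen measured but no nectar: sugar flagged unmeasured, not zero
  tri <- prof[prof$species_id == "trifolium", ]
  expect_true(is.na(tri$mean_sugar_ug))
  expect_equal(tri$mean_pollen_ul, 500 * grain_volume(20, 10) / 1e9)
  # species without nectaries is known-zero, not unmeasured
  expect_equal(prof$mean_sugar_ug[prof$species_id == "carex_like"], 0)
  # unmeasured species carry NA, never zero rows
  expect_true(is.na(prof$mean_sugar_ug[prof$species_id == "lamium"]))
  expect_true(all(is.na(prof$mean_pollen_ul[prof$species_id != "trifolium"])))
})

test_that("empty measurement inputs give an all-unmeasured profile set", {
  prof <- build_species_profiles(NULL, NULL, NULL, tiny_species())
  expect_equal(nrow(prof), 4)
  expect_true(all(prof$n_nectar == 0L))
  expect_true(all(is.na(prof$mean_pollen_ul)))
})

test_that("profile coverage reports percent of species measured", {
  species <- tibble::tibble(
    species_id = sprintf("sp%02d", 1:10),
    origin = "native",
    has_nectaries = c(rep(TRUE, 8), FALSE, FALSE),
    floral_unit_type = "flower"
  )
  prof <- build_species_profiles(
    nectar_rows_for(rep(c("sp01", "sp02"), each = 2), rep(10, 4)),
    tibble::tibble(species_id = c("sp01", "sp03", "sp09"),
                   aliquot_count_1 = 10, aliquot_count_2 = 10,
                   suspension_volume_ul = 100),
    tibble::tibble(species_id = c("sp01", "sp03", "sp09"),
                   major_axis_um = 20, minor_axis_um = 15),
    species)
  cov <- profile_coverage(prof, species)
  expect_equal(cov$n_measured, c(2L, 3L))
  expect_equal(cov$n_species, c(8L, 10L))
  expect_equal(cov$pct, c(25.0, 30.0))
})
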