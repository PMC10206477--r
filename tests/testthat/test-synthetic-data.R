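test_that("generate_plants honours the study design and is deterministic", {
  cfg <- study_config(rng_seed = 3L)
  plants <- generate_plants(cfg)
  expect_equal(nrow(plants), 105)
  expect_equal(as.vector(table(plants$stand)[cfg$stand_labels]), rep(35L, 3))
  expect_true(all(plants$cover > 0))
  expect_true(all(plants$seeds_per_cone >= 1 & plants$seeds_per_cone <= 10))
  expect_true(all(plants$seed_viability >= 0 & plants$seed_viability <= 1))
  # nutrition fields all present or all absent per plant
  nutr <- plants[, c("pulp_ash", "pulp_protein", "pulp_fibre", "pulp_lipids")]
  n_missing <- rowSums(is.na(nutr))
  expect_true(all(n_missing %in% c(0L, 4L)))
  expect_equal(sum(n_missing == 0), 82)
  # identical seed, identical table
  expect_identical(plants, generate_plants(study_config(rng_seed = 3L)))
  # different seed differs
  expect_false(identical(plants, generate_plants(study_config(rng_seed = 4L))))
})

test_that("zero trait spread collapses each stand onto its mean", {
  sds <- default_trait_sds()
  sds[] <- 0
  cfg <- study_config(trait_sds = sds, founder_fraction = 0, rng_seed = 1L)
  plants <- generate_plants(cfg)
  for (s in seq_along(cfg$stand_labels)) {
    sub <- plants[plants$stand == cfg$stand_labels[s], ]
    expect_equal(unique(sub$cover), cfg$trait_means$cover[s])
    expect_equal(unique(sub$cone_diameter), cfg$trait_means$cone_diameter[s])
  }
})

test_that("invalid configurations are rejected", {
  expect_error(study_config(foraging_fraction = 1.5), "foraging_fraction")
  expect_error(study_config(id_success = -0.1), "id_success")
  sds <- default_trait_sds()
  sds["cover"] <- -1
  expect_error(study_config(trait_sds = sds), "nonnegative")
  sp <- default_species_params()
  sp$intensity_MAR[1] <- -5
  expect_error(study_config(species_params = sp), "intensities")
})

test_that("true visits follow the intensity design", {
  cfg <- study_config(rng_seed = 5L)
  plants <- generate_plants(cfg)
  # zero intensity for one species in one stand -> zero column there
  sp <- cfg$species_params
  sp$intensity_MAR[sp$species_id == "Erithacus_rubecula"] <- 0
  cfg0 <- study_config(species_params = sp, rng_seed = 5L)
  tv <- simulate_true_visits(plants, cfg0)
  mar_plants <- plants$plant_id[plants$stand == "MAR"]
  expect_true(all(tv$visits[mar_plants, "Erithacus_rubecula"] == 0))
  # ground-truth modules are the planted stand -> module map
  expect_equal(unname(tv$plant_modules[plants$plant_id]),
               unname(cfg0$stand_modules[plants$stand]))
  # determinism
  tv2 <- simulate_true_visits(plants, cfg0)
  expect_identical(tv$visits, tv2$visits)
})

test_that("Poisson limit of the visit model matches the configured mean", {
  # flat intensity 10, no attractiveness or module modulation: every cell is
  # an independent Poisson(10) draw; the mean over all cells must sit within
  # 3 Monte-Carlo standard errors of 10
  sp <- default_species_params()
  sp[paste0("intensity_", c("MAR", "OJI", "COL"))] <- 10
  cfg <- study_config(species_params = sp, dispersion = Inf,
                      attract_crop = 0, attract_cone = 0,
                      founder_fraction = 0, rng_seed = 7L)
  plants <- generate_plants(cfg)
  tv <- simulate_true_visits(plants, cfg)
  n <- length(tv$visits)
  se <- sqrt(10 / n)
  expect_lt(abs(mean(tv$visits) - 10), 3 * se)
})

test_that("camera thinning has the stated detection probability", {
  # fixed recording effort: coverage 0.6 (small plants), full-study recording
  # would be p = 0.6; here recorded days are fixed at 20% of the study so the
  # per-visit detection probability is 0.6 * 0.2 = 0.12
  sp <- default_species_params()
  sp[paste0("intensity_", c("MAR", "OJI", "COL"))] <- 50
  cfg <- study_config(species_params = sp, attract_crop = 0, attract_cone = 0,
                      founder_fraction = 0,
                      camera_days_mean = 0.2 * 434, camera_days_sd = 0,
                      foraging_fraction = 1, rng_seed = 9L)
  plants <- generate_plants(cfg)
  plants$cover <- 15 # all small: coverage fraction 0.6
  tv <- simulate_true_visits(plants, cfg)
  cam <- simulate_camera_survey(tv, plants, cfg)
  p_thin <- 0.6 * round(0.2 * 434) / 434
  n_true <- sum(tv$visits)
  n_det <- sum(cam$n_records[cam$behaviour == "foraging"])
  se <- sqrt(n_true * p_thin * (1 - p_thin))
  expect_lt(abs(n_det - n_true * p_thin), 3 * se)
  # no thinning at coverage 1 and full-length recording
  cfg_full <- study_config(species_params = sp, attract_crop = 0,
                           attract_cone = 0, founder_fraction = 0,
                           camera_coverage_breaks = numeric(0),
                           camera_coverage_fractions = 1,
                           camera_days_mean = 434, camera_days_sd = 0,
                           foraging_fraction = 1, rng_seed = 9L)
  cam_full <- simulate_camera_survey(tv, plants, cfg_full)
  expect_equal(sum(cam_full$n_records), sum(tv$visits))
})

test_that("behaviour filter generates non-foraging records at the design rate", {
  cfg <- study_config(rng_seed = 13L)
  plants <- generate_plants(cfg)
  tv <- simulate_true_visits(plants, cfg)
  cam <- simulate_camera_survey(tv, plants, cfg)
  frac_forage <- sum(cam$n_records[cam$behaviour == "foraging"]) / sum(cam$n_records)
  expect_lt(abs(frac_forage - 0.48), 0.02)
})

test_that("barcoding misses identifications at rate 1 - id_success", {
  cfg <- study_config(rng_seed = 21L)
  plants <- generate_plants(cfg)
  tv <- simulate_true_visits(plants, cfg)
  scats <- simulate_scat_survey(tv, plants, cfg)
  n_unid <- sum(scats$n_samples[scats$species_id == "UNIDENTIFIED"])
  n_all <- sum(scats$n_samples)
  expect_gt(n_all, 500)
  p <- 1 - 0.926
  se <- sqrt(n_all * p * (1 - p))
  expect_lt(abs(n_unid - n_all * p), 3 * se)
  # perfect identification leaves no UNIDENTIFIED rows
  cfg1 <- study_config(id_success = 1, rng_seed = 21L)
  scats1 <- simulate_scat_survey(tv, plants, cfg1)
  expect_false("UNIDENTIFIED" %in% scats1$species_id)
})

test_that("synthesize_study writes a consistent set of artifacts", {
  dir <- withr::local_tempdir()
  syn <- synthesize_study(study_config(plants_per_stand = 5, rng_seed = 2L), dir)
  expect_true(all(file.exists(file.path(dir, c(
    "plants.csv", "species.csv", "camera_records.csv", "scat_records.csv",
    "ground_truth.json")))))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(length(gt$plant_modules), nrow(syn$plants))
  expect_equal(length(gt$species_modules), nrow(syn$species))
})
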