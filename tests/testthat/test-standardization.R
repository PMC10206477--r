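test_that("coverage fraction follows the plant size classes", {
  expect_equal(coverage_fraction_for_cover(15), 0.60)
  expect_equal(coverage_fraction_for_cover(25), 0.40)
  expect_equal(coverage_fraction_for_cover(45), 0.20)
  # boundaries: middle class closed on both sides
  expect_equal(coverage_fraction_for_cover(20), 0.40)
  expect_equal(coverage_fraction_for_cover(40), 0.40)
  expect_error(coverage_fraction_for_cover(0), "positive")
  expect_error(coverage_fraction_for_cover(-3), "positive")
})

test_that("camera standardization reproduces the worked example", {
  # 4 foraging visits on a small plant (coverage 0.6) filmed for 20% of the
  # study: 4 / 0.6 = 6.7 whole-plant visits, / 0.2 = 33.3 whole-study visits
  rec <- one_camera_record(4, 0.6, 0.2 * 434)
  m <- standardize_camera(rec, 434)
  expect_equal(round(4 / 0.6, 1), 6.7)
  expect_equal(m["p1", "s1"], 4 / 0.6 / 0.2)
  expect_equal(round(m["p1", "s1"], 1), 33.3)
  # zero visits stay zero under any scaling
  m0 <- standardize_camera(one_camera_record(0, 0.2, 100), 434)
  expect_equal(unname(m0["p1", "s1"]), 0)
  # non-foraging rows are discarded by the behaviour filter
  rec2 <- rbind(rec, transform(rec, behaviour = "other", n_records = 50))
  expect_equal(standardize_camera(rec2, 434), m)
  # invalid effort is rejected
  expect_error(standardize_camera(one_camera_record(1, 0.6, 0), 434), "recorded_days")
  expect_error(standardize_camera(one_camera_record(1, 1.2, 10), 434), "coverage")
})

test_that("scat standardization scales by canopy fraction and active time", {
  rec <- data.frame(plant_id = "p1", species_id = "s1", n_samples = 10,
                    sampled_area = 0.5, canopy_area = 10, active_days = 217)
  m <- standardize_scats(rec, 434)
  expect_equal(m["p1", "s1"], 10 / 0.05 / 0.5) # = 400
  # identity scaling: full canopy sampled for the whole study
  rec_id <- data.frame(plant_id = "p1", species_id = "s1", n_samples = 7,
                       sampled_area = 3, canopy_area = 3, active_days = 434)
  expect_equal(unname(standardize_scats(rec_id, 434)["p1", "s1"]), 7)
  # area fraction is capped at 1
  rec_big <- transform(rec_id, sampled_area = 9)
  expect_equal(unname(standardize_scats(rec_big, 434)["p1", "s1"]), 7)
  # UNIDENTIFIED records are dropped; an all-UNIDENTIFIED survey gives zeros
  rec_u <- transform(rec, species_id = "UNIDENTIFIED")
  m_u <- standardize_scats(rec_u, 434, plant_ids = "p1", species_ids = "s1")
  expect_equal(sum(m_u), 0)
  expect_error(standardize_scats(transform(rec, canopy_area = 0), 434), "canopy")
})

test_that("standardized estimates never fall below raw counts", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(0:30, 1)
    cam <- one_camera_record(n, runif(1, 0.1, 1), runif(1, 1, 434))
    expect_gte(sum(standardize_camera(cam, 434)), n)
  }
})

test_that("merging is commutative, conserves totals and unions species", {
  a <- random_matrix(4, 3, seed = 1)
  b <- random_matrix(4, 2, seed = 2)
  colnames(b) <- c("s4", "s5")
  m <- merge_visit_matrices(a, b)
  expect_equal(sum(m), sum(a) + sum(b))
  expect_setequal(colnames(m), c(colnames(a), colnames(b)))
  expect_equal(m[rownames(a), colnames(a)], a[, colnames(a)])
  expect_equal(merge_visit_matrices(b, a), m)
  # zero matrix is the identity element
  z <- a * 0
  expect_equal(merge_visit_matrices(a, z)[rownames(a), colnames(a)], a)
  # overlapping cells add
  m2 <- merge_visit_matrices(a, a)
  expect_equal(m2[rownames(a), colnames(a)], 2 * a)
})

test_that("visit matrices round-trip through CSV", {
  m <- random_matrix(5, 4, seed = 9) + 0.25
  path <- withr::local_tempfile(fileext = ".csv")
  write_visit_matrix(m, path)
  expect_equal(read_visit_matrix(path), m)
})
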