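test_that("noiseless phantom reproduces tissue rates exactly", {
  anatomy <- small_anatomy()
  up <- uptake_params(background_rate = 12,
                      cancellous_head_rate_affected = 66.3,
                      cancellous_head_rate_unaffected = 201.3,
                      cortical_rate = 400, acetabular_rate = 319.1,
                      noise_model = "none")
  ph <- build_hip_phantom(anatomy, up, affected_side = "right")
  codes <- tissue_codes()
  lab <- ph$labels$labels
  cnt <- ph$counts$counts
  expect_identical(unique(cnt[lab == codes[["background"]]]), 12)
  expect_identical(unique(cnt[lab == codes[["cortical"]]]), 400)
  expect_identical(unique(cnt[lab == codes[["acetabular_dome"]]]), 319.1)
  expect_setequal(unique(cnt[lab == codes[["cancellous"]]]), c(66.3, 201.3))
  # every voxel carries exactly one class
  expect_true(all(lab %in% codes))
})

test_that("uniform phantom is a constant field", {
  up <- uptake_params(background_rate = 100,
                      cancellous_head_rate_affected = 100,
                      cancellous_head_rate_unaffected = 100,
                      cortical_rate = 100, acetabular_rate = 100,
                      noise_model = "none")
  ph <- build_hip_phantom(small_anatomy(), up)
  expect_identical(unique(as.vector(ph$counts$counts)), 100)
})

test_that("poisson phantom class means converge to their rates", {
  up <- uptake_params(cancellous_head_rate_unaffected = 100,
                      noise_model = "poisson", seed = 123)
  ph <- build_hip_phantom(small_anatomy(), up, affected_side = "right")
  # left (unaffected) cancellous core, rate R = 100
  mask <- ph$labels$labels == tissue_codes()[["cancellous"]] &
    hipspect:::voxel_dist2(ph$labels$shape, ph$labels$spacing,
                           c(60, 130, 100)) < 22^2
  n <- sum(mask)
  expect_gt(n, 50)
  expect_lt(abs(mean(ph$counts$counts[mask]) - 100), 4 * sqrt(100 / n))
  # identical seed reproduces identical counts
  ph2 <- build_hip_phantom(small_anatomy(), up, affected_side = "right")
  expect_identical(ph$counts$counts, ph2$counts$counts)
})

test_that("phantom geometry and parameter errors are caught", {
  expect_error(anatomy_model(femoral_head_center_left = c(5, 130, 100)),
               "outside the volume")
  expect_error(anatomy_model(cortical_shell_thickness = 30),
               "smaller than the head radius")
  expect_error(uptake_params(background_rate = -1), ">= 0")
  expect_error(uptake_params(noise_model = "poisson"), "seed")
})

test_that("simulate_cohort draws group sizes, bounds and is seed-pure", {
  spec <- cohort_spec(seed = 42)
  co <- simulate_cohort(spec)
  expect_identical(nrow(co), 30L)
  expect_identical(sum(co$outcome == "onfh"), 6L)
  expect_identical(sum(co$outcome == "union"), 24L)
  # truncation bounds respected
  expect_true(all(co$head_to_head_ratio[co$outcome == "onfh"] >= 0.18 &
                    co$head_to_head_ratio[co$outcome == "onfh"] <= 0.45))
  expect_true(all(co$head_to_head_ratio[co$outcome == "union"] >= 0.55 &
                    co$head_to_head_ratio[co$outcome == "union"] <= 2.50))
  # pure function of the seed
  expect_identical(co, simulate_cohort(cohort_spec(seed = 42)))
  expect_false(identical(co$head_to_head_ratio,
                         simulate_cohort(cohort_spec(seed = 43))$head_to_head_ratio))
  # requested fraction flagged incomparable
  expect_identical(sum(co$contralateral_status != "healthy"), 6L)
  expect_true(all(co$contralateral_status %in%
                    c("healthy", "implant", "onfh", "oa")))
})

test_that("degenerate sd = 0 cohort pins every ratio at the group mean", {
  spec <- cohort_spec(
    ratio_distribution_onfh = c(0.33, 0, 0.18, 0.45),
    ratio_distribution_union = c(1.30, 0, 0.55, 2.50),
    seed = 5)
  co <- simulate_cohort(spec)
  expect_identical(unique(co$head_to_head_ratio[co$outcome == "onfh"]), 0.33)
  expect_identical(unique(co$head_to_head_ratio[co$outcome == "union"]), 1.30)
})

test_that("cohort draws match the truncated-normal mean oracle", {
  # the generator calibrates the parent location so the truncated mean
  # equals the stated group mean; check both the calibration (against
  # numerical integration) and the Monte-Carlo sample mean
  sd_onfh <- 0.05 * sqrt(6) / 1.96
  mu0 <- hipspect:::tnorm_calibrate_location(0.33, sd_onfh, 0.18, 0.45)
  expect_equal(integrate_tnorm_mean(mu0, sd_onfh, 0.18, 0.45), 0.33,
               tolerance = 1e-8)
  spec <- cohort_spec(n_onfh = 10000L, n_union = 0L, seed = 99)
  co <- simulate_cohort(spec)
  expect_lt(abs(mean(co$head_to_head_ratio) - 0.33), 0.01)
  expect_true(all(co$head_to_head_ratio >= 0.18 &
                    co$head_to_head_ratio <= 0.45))
})

test_that("cohort_spec rejects invalid specifications", {
  expect_error(cohort_spec(n_onfh = 0, n_union = 0, seed = 1), "empty")
  expect_error(cohort_spec(seed = NULL), "seed")
  expect_error(cohort_spec(ratio_distribution_onfh = c(0.33, 0.06, 0.5, 0.4),
                           seed = 1), "lower < upper")
  expect_error(cohort_spec(fraction_incomparable_contralateral = 1.5,
                           seed = 1), "\\[0, 1\\]")
})

test_that("cohort manifest round-trips field for field", {
  co <- simulate_cohort(cohort_spec(seed = 7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_manifest(co, path)
  back <- read_cohort_manifest(path)
  for (col in names(co)) expect_identical(back[[col]], co[[col]], label = col)

  # empty cohort: header-only file reads back to zero rows
  write_cohort_manifest(co[0, ], path)
  expect_identical(nrow(read_cohort_manifest(path)), 0L)

  # malformed manifests fail naming the problem
  expect_error(write_cohort_manifest(co[, -4], path), "outcome")
  bad <- co
  bad$outcome[3] <- "necrosis"
  write_cohort_manifest(bad, path)
  expect_error(read_cohort_manifest(path), "row 3")
})
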