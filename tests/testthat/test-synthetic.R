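test_that("phantom generation is seed-deterministic and seed-sensitive", {
  a <- generate_phantom(small_phantom_spec(seed = 10))
  b <- generate_phantom(small_phantom_spec(seed = 10))
  c_ <- generate_phantom(small_phantom_spec(seed = 11))
  expect_identical(a$series$slices[[2]]$pixels, b$series$slices[[2]]$pixels)
  expect_identical(a$masks, b$masks)
  expect_false(identical(a$series$slices[[2]]$pixels, c_$series$slices[[2]]$pixels))
})

test_that("zero-noise phantom recovers configured HU means exactly", {
  ph <- generate_phantom(small_phantom_spec(seed = 1,
                                            hu_sd = c(sm = 0, vat = 0, sat = 0)))
  hu <- to_hounsfield(ph$series$slices[[1]])
  expect_equal(radiodensity_2d(ph$masks[[1]]$sm, hu), 40)
  expect_equal(radiodensity_2d(ph$masks[[1]]$vat, hu), -91)
  expect_equal(radiodensity_2d(ph$masks[[1]]$sat, hu), -104)
})

test_that("phantom geometry validation rejects impossible specs", {
  expect_error(phantom_spec(size = 64, row_spacing_mm = 1, vat_radius_mm = 15,
                            sm_outer_mm = 25, sat_outer_mm = 40),
               "exceeds raster")
  expect_error(small_phantom_spec(vat_radius_mm = 30, sm_inner_mm = 20),
               "nested")
})

test_that("rasterised areas converge to analytic areas as spacing shrinks", {
  rel_err <- function(spacing) {
    sp <- phantom_spec(size = round(96 / spacing), row_spacing_mm = spacing,
                       n_slices = 1L, vat_radius_mm = 15, sm_outer_mm = 25,
                       sat_outer_mm = 35, seed = 1)
    ph <- generate_phantom(sp)
    measured <- surface_area(ph$masks[[1]]$vat, spacing)
    abs(measured - ph$analytic$areas_cm2$vat[1]) / ph$analytic$areas_cm2$vat[1]
  }
  e_coarse <- rel_err(2); e_fine <- rel_err(0.5)
  expect_lt(e_fine, e_coarse)
  expect_lt(e_fine, 0.01)
})

test_that("the cylinder phantom volume matches the analytic value within 2%", {
  # VAT disc of radius 30 mm, 10 slices of 5 mm -> pi * 9 * 5 cm^3
  sp <- phantom_spec(size = 160L, row_spacing_mm = 1, n_slices = 10L,
                     thickness_mm = 5, vat_radius_mm = 30, sm_outer_mm = 45,
                     sat_outer_mm = 60, seed = 4)
  ph <- generate_phantom(sp)
  expect_equal(ph$analytic$volumes_cm3[["vat"]], pi * 9 * 5)
  masks <- segment_series(ph$series, seg_config())
  r <- measure_patient(ph$series, masks)
  expect_lt(abs(r$vat_volume_cm3 - pi * 9 * 5) / (pi * 9 * 5), 0.02)
  expect_lt(abs(r$sm_volume_cm3 - ph$analytic$volumes_cm3[["sm"]]) /
              ph$analytic$volumes_cm3[["sm"]], 0.02)
})

test_that("cohort generation is deterministic and respects prevalence", {
  spec <- cohort_sim_spec(seed = 6)
  a <- generate_cohort(spec); b <- generate_cohort(spec)
  expect_identical(a$cohort, b$cohort)
  # binomial bound on the toxicity count at the published prevalence
  one <- generate_cohort(cohort_sim_spec(n = c(F = 203L),
                                         prevalence = c(F = 0.591), seed = 8))
  k <- sum(one$cohort$dlt)
  expect_lt(abs(k - 203 * 0.591), 3 * sqrt(203 * 0.591 * 0.409) + 1)
})

test_that("empirical AUC converges to the closed-form binormal AUC", {
  # calibrated separation: pnorm(0.583 / sqrt(2)) = 0.66
  spec <- separation_cohort_spec(delta = c(sm_volume_cm3 = 0.583),
                                 n = c(F = 4000L), prevalence = c(F = 0.5),
                                 seed = 14)
  sim <- generate_cohort(spec)
  truth <- sim$true_auc
  expect_equal(truth$auc[truth$measurement == "sm_volume_cm3"],
               pnorm(0.583 / sqrt(2)))
  x <- sim$cohort
  auc <- roc_auc(x$sm_volume_cm3[x$dlt == 1], x$sm_volume_cm3[x$dlt == 0])$auc
  expect_lt(abs(auc - pnorm(0.583 / sqrt(2))), 0.01)
  # zero separation: AUC within the null sampling bound around one half
  n1 <- sum(x$dlt == 1); n0 <- sum(x$dlt == 0)
  auc0 <- roc_auc(x$vat_area_cm2[x$dlt == 1], x$vat_area_cm2[x$dlt == 0])$auc
  expect_lt(abs(auc0 - 0.5), 3 * sqrt((1 / 12) * (1 / n1 + 1 / n0)))
})

test_that("default parameters make skeletal muscle volume the strongest truth signal", {
  truth <- generate_cohort(cohort_sim_spec(seed = 1))$true_auc
  for (sx in c("F", "M")) {
    block <- truth[truth$sex == sx, ]
    expect_identical(block$measurement[which.max(block$auc)], "sm_volume_cm3")
  }
})

test_that("simulation specs validate their invariants", {
  expect_error(cohort_sim_spec(n = c(F = 1L)), "at least 2")
  expect_error(cohort_sim_spec(prevalence = c(F = 0, M = 0.5)), "prevalence")
  bad <- default_measurement_params()
  bad$sd_dlt[1] <- 0
  expect_error(cohort_sim_spec(params = bad), "SD")
})
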