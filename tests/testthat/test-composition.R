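test_that("surface area follows pixel count x spacing, in cm2", {
  m <- matrix(FALSE, 50, 40); m[seq_len(1000)] <- TRUE
  expect_equal(surface_area(m, 0.8, 0.8), 6.4)
  expect_equal(surface_area(matrix(FALSE, 4, 4), 1), 0)
  # rasterised disc against the analytic circle area
  n <- 128; centre <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - centre)^2, (seq_len(n) - centre)^2, `+`))
  disc <- d < 50
  expect_lt(abs(surface_area(disc, 1) - pi * 25),
            pixelation_bound_cm2(2 * pi * 50, 1))
})

test_that("areas and volumes scale correctly with spacing and thickness", {
  m <- matrix(FALSE, 20, 20); m[5:15, 5:15] <- TRUE
  expect_equal(surface_area(m, 1.6, 1.6), 4 * surface_area(m, 0.8, 0.8))
  a <- surface_area(m, 0.8)
  expect_equal(volume_3d(rep(a, 3), 10), 2 * volume_3d(rep(a, 3), 5))
})

test_that("2D radiodensity is the mean HU under the mask; empty mask is undefined", {
  hu <- matrix(40, 10, 10)
  all_mask <- matrix(TRUE, 10, 10)
  expect_equal(radiodensity_2d(all_mask, hu), 40)
  hu2 <- matrix(c(rep(-100, 50), rep(-80, 50)), 10, 10)
  expect_equal(radiodensity_2d(all_mask, hu2), -90)
  expect_true(is.na(radiodensity_2d(matrix(FALSE, 10, 10), hu)))
})

test_that("radiodensity of a noisy phantom ring stays within the sampling bound", {
  ph <- generate_phantom(small_phantom_spec(
    seed = 5, hu_mean = c(sm = 40, vat = -91, sat = -104),
    hu_sd = c(sm = 10, vat = 10, sat = 10)))
  hu <- to_hounsfield(ph$series$slices[[1]])
  m <- ph$masks[[1]]$sm
  n <- sum(m)
  expect_lt(abs(radiodensity_2d(m, hu) - 40), 3 * 10 / sqrt(n) + 0.5)
})

test_that("the height-normalised index is area over height squared", {
  expect_equal(tissue_index(100, 1.6), 39.0625)
  expect_equal(tissue_index(0, 1.7), 0)
  expect_equal(tissue_index(123.4, 1), 123.4)
  expect_error(tissue_index(100, 0), "positive")
  expect_error(tissue_index(100, -1.6), "positive")
})

test_that("volume integrates per-slice area x thickness", {
  expect_equal(volume_3d(rep(100, 4), 5), 200)
  expect_equal(volume_3d(6.4, 10), 6.4)
  # mixed thicknesses are respected slice by slice
  expect_equal(volume_3d(c(10, 10, 20), c(2, 4, 8)), 2 + 4 + 16)
})

test_that("3D radiodensity is the unweighted mean of slice means", {
  expect_equal(avg_radiodensity_3d(c(30, 40, 50)), 40)
  # areas differ, the plain formula still weights slices equally
  expect_equal(avg_radiodensity_3d(c(0, 100)), 50)
  expect_equal(avg_radiodensity_3d(c(0, 100), weights = c(3, 1), weighted = TRUE), 25)
  expect_equal(avg_radiodensity_3d(37.2), 37.2)
  expect_equal(avg_radiodensity_3d(c(10, NA, 20)), 15)
  expect_true(is.na(avg_radiodensity_3d(c(NA_real_, NA_real_))))
})

test_that("uniform stacks satisfy the exact 2D/3D consistency identities", {
  ph <- generate_phantom(small_phantom_spec(seed = 1, n_slices = 6L,
                                            thickness_mm = 3))
  rep_ <- measure_patient(ph$series, ph$masks, height_m = 1.6)
  # identical slices: volume = mid-slice area x total stack thickness
  for (comp in c("sm", "vat", "sat")) {
    expect_equal(rep_[[paste0(comp, "_volume_cm3")]],
                 rep_[[paste0(comp, "_area_cm2")]] * 6 * 3 / 10)
  }
  # zero-noise degenerate case: 3D mean equals 2D radiodensity exactly
  ph0 <- generate_phantom(small_phantom_spec(seed = 1, n_slices = 4L,
                                             hu_sd = c(sm = 0, vat = 0, sat = 0)))
  r0 <- measure_patient(ph0$series, ph0$masks)
  expect_equal(r0$sm_density_3d_hu, r0$sm_density_hu)
  expect_equal(r0$sm_density_hu, 40)
})

test_that("single-slice series: volume equals area x thickness / 10 per compartment", {
  ph <- generate_phantom(small_phantom_spec(seed = 3, n_slices = 1L,
                                            thickness_mm = 7))
  r <- measure_patient(ph$series, ph$masks)
  for (comp in c("sm", "vat", "sat")) {
    expect_equal(r[[paste0(comp, "_volume_cm3")]],
                 r[[paste0(comp, "_area_cm2")]] * 7 / 10)
  }
})

test_that("missing height flags the indices absent but computes everything else", {
  ph <- generate_phantom(small_phantom_spec(seed = 2, n_slices = 2L))
  r <- measure_patient(ph$series, ph$masks)
  expect_true(all(is.na(c(r$smi_cm2_m2, r$vfi_cm2_m2, r$sfi_cm2_m2))))
  expect_false(anyNA(r[c("sm_area_cm2", "sm_volume_cm3", "sat_density_3d_hu")]))
  r2 <- measure_patient(ph$series, ph$masks, height_m = 1.7)
  expect_equal(r2$smi_cm2_m2, r2$sm_area_cm2 / 1.7^2)
})

test_that("a segmented compartment's radiodensity stays inside its HU window", {
  ph <- generate_phantom(small_phantom_spec(seed = 8))
  cfg <- seg_config()
  hu <- to_hounsfield(ph$series$slices[[3]])
  m <- segment_slice(hu, cfg)
  rd <- radiodensity_2d(m$sm, hu)
  expect_gte(rd, cfg$sm_window[1]); expect_lte(rd, cfg$sm_window[2])
  rd_vat <- radiodensity_2d(m$vat, hu)
  expect_gte(rd_vat, cfg$vat_window[1]); expect_lte(rd_vat, cfg$vat_window[2])
})
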