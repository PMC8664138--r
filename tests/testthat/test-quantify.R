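# DER estimation, ROI protocol, concentration calibration and error
# metrics.

test_that("the DER is the OLS slope of low-on-high insert means", {
  pts <- tibble::tibble(hu_high = c(0, 10, 20), hu_low = c(0, 19.7, 39.4))
  fit <- estimate_der(pts)
  expect_equal(fit$der, 1.97)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n_points, 3L)

  two <- estimate_der(tibble::tibble(hu_high = c(0, 1), hu_low = c(0, 2.18)))
  expect_equal(two$der, 2.18)

  expect_error(estimate_der(tibble::tibble(hu_high = c(5, 5),
                                           hu_low = c(1, 2))),
               class = "vncsim_error_fit")
  expect_error(estimate_der(tibble::tibble(hu_high = 1, hu_low = 2)),
               class = "vncsim_error_fit")
})

test_that("the DER fit absorbs offsets in the intercept and scales linearly", {
  withr::local_seed(99)
  pts <- tibble::tibble(hu_high = c(40, 120, 260, 390),
                        hu_low = 1.52 * c(40, 120, 260, 390) + rnorm(4, 0, 5))
  base <- estimate_der(pts)

  shifted <- estimate_der(dplyr::mutate(pts, hu_low = hu_low + 500))
  expect_equal(shifted$der, base$der)
  expect_equal(shifted$intercept, base$intercept + 500)

  scaled <- estimate_der(dplyr::mutate(pts, hu_low = 3 * hu_low))
  expect_equal(scaled$der, 3 * base$der)
})

test_that("the estimator recovers the slope under noise across seeds", {
  # calcium-like design: 50-300 mg/ml at 2.6 HU/(mg/ml) high-beam slope
  x_true <- c(50, 100, 200, 300) * 2.6
  ders <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      pts <- tibble::tibble(hu_high = x_true + rnorm(4, 0, 2),
                            hu_low = 1.52 * x_true + rnorm(4, 0, 2))
      estimate_der(pts)$der
    })
  }, numeric(1))
  expect_lt(max(abs(ders - 1.52)), 0.03)
  expect_lt(abs(mean(ders) - 1.52), 0.01)
})

test_that("the ROI protocol samples 60% of the insert diameter", {
  vol <- array(55, dim = c(120, 120, 5))
  ins <- tibble::tibble(insert = "a", x_cm = 0, y_cm = 0, diameter_cm = 2.8)
  stats <- roi_stats(vol, ins, spacing_mm = 1)
  expect_equal(stats$mean, 55)
  expect_equal(stats$sd, 0)
  expect_equal(stats$n_slices, 5L)
  # per-slice voxel count vs analytic ROI area (0.6 * 2.8 cm diameter)
  per_slice <- stats$n_voxels / 5
  expect_lt(abs(per_slice - pi * 8.4^2) / (pi * 8.4^2), 0.05)
})

test_that("ROIs clipped by the volume edge raise geometry errors", {
  vol <- array(0, dim = c(40, 40, 5))
  corner <- tibble::tibble(insert = "c", x_cm = 1.9, y_cm = 0,
                           diameter_cm = 2.8)
  expect_error(roi_stats(vol, corner, spacing_mm = 1, fraction = 1),
               class = "vncsim_error_geometry")
  inside <- tibble::tibble(insert = "i", x_cm = 0, y_cm = 0,
                           diameter_cm = 2.8)
  expect_error(roi_stats(vol, inside, spacing_mm = 1, n_slices = 7),
               class = "vncsim_error_geometry")
})

test_that("calibration fits concentration on enhancement with intercept", {
  cal <- fit_calibration(tibble::tibble(conc_mg_ml = c(0, 5, 10),
                                        enh_hu = c(0, 100, 200)))
  expect_equal(cal$slope, 0.05)
  expect_equal(cal$intercept, 0)
  expect_equal(concentration_from_enhancement(cal, 200), 10)
  expect_equal(concentration_from_enhancement(cal, 0), cal$intercept)
  expect_equal(predict(cal, enh = 40), 2)

  expect_error(fit_calibration(tibble::tibble(conc_mg_ml = 5, enh_hu = 100)),
               class = "vncsim_error_fit")
})

test_that("noise-free calibration round-trips every concentration", {
  grid <- fixture_grid("DualSpiral", "iodine")
  wf5 <- dplyr::filter(tidy(grid), workflow == 5)
  cal <- fit_calibration(tibble::tibble(conc_mg_ml = wf5$conc_mg_ml,
                                        enh_hu = wf5$enh_mean))
  back <- concentration_from_enhancement(cal, wf5$enh_mean)
  expect_lt(max(abs(back - wf5$conc_mg_ml)), 1e-6)
})

test_that("bias and total error follow the signed/absolute-mean definitions", {
  exact <- error_metrics(tibble::tibble(measured = c(2, 5), truth = c(2, 5)))
  expect_equal(unlist(exact[1, 1:3]),
               c(bias = 0, total_error_mean = 0, total_error_sd = 0))

  m <- error_metrics(tibble::tibble(measured = c(1.9, 4.5, 9.5, 14.5),
                                    truth = c(2, 5, 10, 15)))
  expect_equal(m$bias, -0.4)
  expect_equal(m$total_error_mean, 0.4)
  expect_equal(m$total_error_sd, sd(c(0.1, 0.5, 0.5, 0.5)))

  shift <- error_metrics(tibble::tibble(measured = c(2, 5, 10) + 1.5,
                                        truth = c(2, 5, 10)))
  expect_equal(shift$bias, 1.5)
  expect_equal(shift$total_error_mean, 1.5)
  expect_equal(shift$total_error_sd, 0)
})

test_that("tidiers return the broom-shaped summaries", {
  fit <- estimate_der(tibble::tibble(hu_high = c(0, 10, 20),
                                     hu_low = c(0, 19.7, 39.4)))
  expect_named(tidy(fit), c("term", "estimate"))
  expect_equal(glance(fit)$der, 1.97)
  cal <- fit_calibration(tibble::tibble(conc_mg_ml = c(0, 5, 10),
                                        enh_hu = c(0, 100, 200)))
  expect_equal(tidy(cal)$estimate[2], 0.05)
  expect_equal(glance(cal)$n_points, 3L)
})
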