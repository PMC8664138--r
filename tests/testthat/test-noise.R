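# Noise model: seeded determinism, 1/sqrt(mAs) scaling, and the
# iterative-reconstruction emulation's SD multiplier and mean preservation.

noise_pair <- function(mas_fraction = 1, seed = 42L, sigma = NULL,
                       n_slices = 5) {
  pair <- fixture_pair("DualSpiral", "iodine", "head", n_slices = n_slices)
  acq <- acquisition_spec("DualSpiral", "head", mas_fraction = mas_fraction,
                          sigma_ref = sigma, seed = seed)
  apply_noise(pair, acq)
}

test_that("identical seeds give bit-identical noise, different seeds differ", {
  a <- noise_pair(seed = 7L)
  b <- noise_pair(seed = 7L)
  c <- noise_pair(seed = 8L)
  expect_identical(a$low, b$low)
  expect_identical(a$high, b$high)
  expect_false(identical(a$low, c$low))
})

test_that("noise SD scales as sigma_ref / sqrt(mas_fraction)", {
  clean <- fixture_pair("DualSpiral", "iodine", "head")
  noisy <- noise_pair(mas_fraction = 0.1)
  resid <- noisy$low - clean$low
  expect_gte(length(resid), 1e5)
  expect_equal(sd(resid), 10 / sqrt(0.1), tolerance = 0.03)
  # and the reference-dose arm sits at sigma_ref itself
  expect_equal(sd(noise_pair(mas_fraction = 1)$low - clean$low), 10,
               tolerance = 0.03)
})

test_that("zero reference noise returns the input unchanged", {
  clean <- fixture_pair("DualSpiral", "iodine", "head")
  out <- noise_pair(sigma = c(low = 0, high = 0))
  expect_equal(out$low, clean$low)
  expect_equal(out$high, clean$high)
})

test_that("non-positive mAs fractions are rejected", {
  pair <- fixture_pair("DualSpiral", "iodine", "head")
  acq <- acquisition_spec("DualSpiral", "head")
  acq$mas_fraction <- 0
  expect_error(apply_noise(pair, acq), class = "vncsim_error_validation")
  expect_error(acquisition_spec("DualSpiral", "head", mas_fraction = -1),
               class = "vncsim_error_validation")
})

test_that("strength 0 is the identity and out-of-range strengths error", {
  noisy <- noise_pair()
  expect_identical(apply_admire(noisy, 0L)$low, noisy$low)
  expect_error(apply_admire(noisy, 6), class = "vncsim_error_validation")
  expect_error(apply_admire(noisy, -1), class = "vncsim_error_validation")
})

test_that("strength 5 cuts uniform-region noise SD by 40-50% and preserves means", {
  clean <- fixture_pair("DualSpiral", "iodine", "head")
  noisy <- noise_pair(seed = 13L)
  smoothed <- apply_admire(noisy, 5L)

  # uniform water region at the phantom center (inserts sit on a 5 cm ring)
  roi <- tibble::tibble(insert = "uniform", x_cm = 0, y_cm = 0,
                        diameter_cm = 5)
  spacing <- clean$meta$pixel_spacing_mm
  sd_before <- roi_stats(noisy$low, roi, spacing, fraction = 1)$sd
  sd_after <- roi_stats(smoothed$low, roi, spacing, fraction = 1)$sd
  reduction <- 1 - sd_after / sd_before
  expect_gte(reduction, 0.40)
  expect_lte(reduction, 0.50)

  mean_before <- roi_stats(noisy$low, roi, spacing, fraction = 1)$mean
  mean_after <- roi_stats(smoothed$low, roi, spacing, fraction = 1)$mean
  expect_lt(abs(mean_after - mean_before), 0.5)
})

test_that("the SD multiplier decreases monotonically with strength", {
  f <- vapply(0:5, vncsim:::admire_factor, numeric(1))
  expect_equal(f[1], 1)
  expect_equal(f[6], 0.55)
  expect_true(all(diff(f) < 0))
})

test_that("noise-free constant regions pass through the smoother unchanged", {
  clean <- fixture_pair("DualSpiral", "iodine", "head")
  smoothed <- apply_admire(clean, 5L)
  # interior of the uniform water center is constant; edges are excluded
  roi <- tibble::tibble(insert = "uniform", x_cm = 0, y_cm = 0,
                        diameter_cm = 5)
  idx <- vncsim:::roi_mask(dim(clean$low)[1:2], clean$meta$pixel_spacing_mm,
                           0, 0, 2.5)
  expect_lt(max(abs(smoothed$low[, , 3][idx] - clean$low[, , 3][idx])), 1e-6)
})
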