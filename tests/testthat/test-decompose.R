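# The projection decomposition: water-equivalent diameter, the emulated
# size correction, the exact 2x2 solve against a brute-force oracle, and
# the conservation / matched-DER identities.

test_that("water-equivalent diameter matches closed forms on uniform discs", {
  # discs built by voxel-center membership (no anti-aliasing) so the
  # closed forms apply up to pixel quantization
  disc_volume <- function(hu, diameter_cm, spacing_mm = 1, n = 260L) {
    xy <- (seq_len(n) - (n + 1) / 2) * spacing_mm / 10
    inside <- outer(xy^2, xy^2, `+`) <= (diameter_cm / 2)^2
    vol <- matrix(-1000, n, n)
    vol[inside] <- hu
    array(vol, dim = c(n, n, 1))
  }
  expect_equal(water_equivalent_diameter(disc_volume(0, 20), 1), 20,
               tolerance = 1e-3)
  expect_equal(water_equivalent_diameter(disc_volume(100, 20), 1),
               20 * sqrt(1.1), tolerance = 1e-3)
  expect_error(
    water_equivalent_diameter(array(-1000, dim = c(10, 10, 1)), 1),
    class = "vncsim_error_validation")
})

test_that("the size correction interpolates iodine DER anchors and clamps", {
  model <- bhc_model(tibble::tibble(diameter_cm = c(20, 35),
                                    der = c(1.97, 2.18)))
  expect_equal(bhc_adjust(1.97, 20, model), 1.97)      # reference: no-op
  expect_equal(bhc_adjust(1.97, 35, model), 2.18)      # body anchor
  # iodine ratio corrupts a calcium DER
  expect_equal(bhc_adjust(1.52, 35, model), 1.52 * 2.18 / 1.97)
  # midpoint interpolation and clamping outside the anchor range
  expect_equal(bhc_adjust(1, 27.5, model), (1.97 + 2.18) / 2 / 1.97)
  expect_equal(bhc_adjust(1.97, 50, model), 2.18)
  expect_equal(bhc_adjust(1.97, 5, model), 1.97)
  expect_error(bhc_model(tibble::tibble(diameter_cm = 20, der = 1.97)),
               class = "vncsim_error_validation")
})

test_that("the projection solve is exact and flags degenerate geometry", {
  on_line <- solve_projection(50, 50, c(0, 0), c(100, 100), der = 2)
  expect_equal(on_line$t, 0.5)
  expect_equal(on_line$c, 0)

  # hand-solved: 100 t + 2 c = 60, 100 t + c = 70  =>  t = 0.8, c = -10
  off <- solve_projection(60, 70, c(0, 0), c(100, 100), der = 2)
  expect_equal(off$t, 0.8)
  expect_equal(off$c, -10)
  oracle <- oracle_projection(60, 70, c(0, 0), c(100, 100), 2)
  expect_equal(off$t, oracle$t, tolerance = 1e-9)
  expect_equal(off$c, oracle$c, tolerance = 1e-9)
  expect_true(brute_force_confirms(oracle, 60, 70, c(0, 0), c(100, 100), 2))

  expect_error(solve_projection(60, 70, c(0, 0), c(100, 100), der = 1),
               class = "vncsim_error_degenerate")
})

test_that("per-voxel solutions match the brute-force grid-search oracle", {
  withr::local_seed(421)
  b1 <- c(55, 50); b2 <- c(-110, -100); d <- 1.97
  low <- matrix(runif(64, -150, 400), 8, 8)
  high <- matrix(runif(64, -150, 300), 8, 8)
  sol <- solve_projection(low, high, b1, b2, d)
  for (i in sample.int(64, 12)) {
    oracle <- oracle_projection(low[i], high[i], b1, b2, d)
    expect_equal(sol$t[i], oracle$t, tolerance = 1e-9)
    expect_equal(sol$c[i], oracle$c, tolerance = 1e-9)
    expect_true(brute_force_confirms(oracle, low[i], high[i], b1, b2, d))
  }
})

test_that("vnc + enhancement reconstructs the mixed image to 1e-6 HU", {
  pair <- fixture_pair("DualSpiral", "iodine", "head")
  cfg <- workflow_config(default_material_table("DualSpiral"), "iodine",
                         der = 1.97)
  dec <- decompose(pair, cfg)
  expect_lt(max(abs(dec$vnc_mixed + dec$enhancement_mixed - dec$mixed)), 1e-6)
  # and the enhancement identity in terms of the contrast map
  expect_lt(max(abs(dec$enhancement_mixed -
                      dec$c_map * (0.5 * dec$applied_der + 0.5))), 1e-6)

  noisy <- apply_noise(pair, acquisition_spec("DualSpiral", "head", seed = 3L))
  dec_n <- decompose(noisy, cfg)
  expect_lt(max(abs(dec_n$vnc_mixed + dec_n$enhancement_mixed - dec_n$mixed)),
            1e-6)
})

test_that("an active BHC at the reference diameter is a voxelwise no-op", {
  pair <- fixture_pair("DualSpiral", "iodine", "head")
  bhc <- default_bhc_model("DualSpiral")
  materials <- default_material_table("DualSpiral")
  on <- decompose(pair, workflow_config(materials, "iodine", der = 1.97,
                                        bhc_active = TRUE, bhc = bhc,
                                        water_equiv_diameter_cm = 20))
  off <- decompose(pair, workflow_config(materials, "iodine", der = 1.97,
                                         water_equiv_diameter_cm = 20))
  expect_identical(on$vnc_mixed, off$vnc_mixed)
  expect_identical(on$c_map, off$c_map)
  expect_equal(on$applied_der, 1.97)
})

test_that("a matched DER removes the contrast exactly, leaving the base HU", {
  for (material in c("iodine", "calcium")) {
    pair <- fixture_pair("DualSpiral", material, "head")
    materials <- default_material_table("DualSpiral")
    der <- implied_der(materials, material, "head")
    dec <- decompose(pair, workflow_config(materials, material, der = der))
    stats <- roi_stats(dec$vnc_mixed, pair$meta$inserts,
                       pair$meta$pixel_spacing_mm)
    baseline <- switch(material, iodine = 0, calcium = 55)
    expect_lt(max(abs(stats$mean - baseline)), 1e-6)
  }
})

test_that("VNC errors from a DER mismatch grow strictly with concentration", {
  pair <- fixture_pair("DualSpiral", "iodine", "body")
  materials <- default_material_table("DualSpiral")
  # head DER applied to the body phantom (the workflow-6 mismatch)
  dec <- decompose(pair, workflow_config(materials, "iodine", der = 1.97))
  stats <- roi_stats(dec$vnc_mixed, pair$meta$inserts,
                     pair$meta$pixel_spacing_mm)
  err <- abs(stats$mean - 0)[order(pair$meta$inserts$conc_mg_ml)]
  expect_true(all(diff(err) > 0))
})

test_that("zero-mean noise leaves decomposed ROI means unbiased", {
  pair <- fixture_pair("DualSpiral", "iodine", "head", n_slices = 3)
  materials <- default_material_table("DualSpiral")
  cfg <- workflow_config(materials, "iodine", der = 1.97,
                         water_equiv_diameter_cm = 20)
  clean_mean <- roi_stats(decompose(pair, cfg)$vnc_mixed,
                          pair$meta$inserts[1, ],
                          pair$meta$pixel_spacing_mm, n_slices = 3)$mean
  n_seeds <- 24
  means <- vapply(seq_len(n_seeds), function(s) {
    noisy <- apply_noise(pair, acquisition_spec("DualSpiral", "head",
                                                seed = 1000L + s))
    roi_stats(decompose(noisy, cfg)$vnc_mixed, pair$meta$inserts[1, ],
              pair$meta$pixel_spacing_mm, n_slices = 3)$mean
  }, numeric(1))
  sem <- sd(means) / sqrt(n_seeds)
  expect_lt(abs(mean(means) - clean_mean), 3 * sem)
})

test_that("invalid configurations are rejected", {
  expect_error(decomp_config(c(0, 0), c(0, 0), der = 2),
               class = "vncsim_error_validation")
  expect_error(decomp_config(c(0, 0), c(100, 100), der = 2,
                             bhc_active = TRUE),
               class = "vncsim_error_config")
})
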