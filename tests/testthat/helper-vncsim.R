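# Shared fixtures. Heavier objects (full factorial grids, rendered pairs)
# are computed lazily once per test session and reused across files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# noise-free factorial run, cached per (modality, material)
fixture_grid <- function(modality = "DualSpiral", material = "iodine") {
  cached(paste("grid", modality, material),
         suppressMessages(run_grid(modality, material)))
}

# noise-free rendered pair, cached per (modality, material, size)
fixture_pair <- function(modality = "DualSpiral", material = "iodine",
                         size = "head", n_slices = 5) {
  cached(paste("pair", modality, material, size, n_slices), {
    spec <- phantom_spec(size, default_inserts(material),
                         n_slices = n_slices)
    render_image_pair(build_phantom(spec),
                      default_material_table(modality),
                      acquisition_spec(modality, size))
  })
}

fixture_noise_study <- function(modality = "DualSpiral", seed = 11L) {
  cached(paste("noise", modality, seed),
         suppressMessages(run_noise_study(modality, seed = seed)))
}

# Independent oracle for the projection solve, minimizing the Euclidean
# residual of voxel = b1 + t (b2 - b1) + c (d, 1). The minimizer comes
# from a QR least-squares solve (a different algorithmic route than the
# package's closed-form 2x2 solve); brute_force_confirms() then verifies
# by exhaustive grid evaluation that no (t, c) near the oracle point
# attains a smaller residual.

projection_residual2 <- function(t, c, low, high, b1, b2, d) {
  (low - (b1[1] + t * (b2[1] - b1[1]) + c * d))^2 +
    (high - (b1[2] + t * (b2[2] - b1[2]) + c))^2
}

oracle_projection <- function(low, high, b1, b2, d) {
  a <- cbind(b2 - b1, c(d, 1))
  sol <- qr.solve(a, c(low, high) - b1)
  list(t = sol[1], c = sol[2])
}

brute_force_confirms <- function(oracle, low, high, b1, b2, d,
                                 span_t = 1, span_c = 100, n = 201L) {
  ts <- oracle$t + seq(-span_t, span_t, length.out = n)
  cs <- oracle$c + seq(-span_c, span_c, length.out = n)
  grid_min <- min(outer(ts, cs, projection_residual2,
                        low = low, high = high, b1 = b1, b2 = b2, d = d))
  at_oracle <- projection_residual2(oracle$t, oracle$c, low, high, b1, b2, d)
  at_oracle <= grid_min + 1e-9
}
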