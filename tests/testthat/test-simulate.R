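test_that("noise-free cubes reproduce the generator spectra exactly", {
  layout <- small_layout()
  g <- small_grid()
  nz <- noise_model(additive_sigma = 0, drift_amplitude = 0)
  cube <- simulate_cube(layout, membrane_state(0.9), noise = nz, grid = g,
                        seed = 5, block_px = 3)
  expected <- design_reflectance_matrix(layout$designs, membrane_state(0.9),
                                        molecular_model(), g)
  spectra <- extract_metapixel_spectra(cube, layout)
  for (s in seq_len(nrow(layout$slots))) {
    expect_equal(spectra$values[s, ],
                 unname(expected[as.character(layout$slots$design_id[s]), ]),
                 tolerance = 1e-12)
  }
})

test_that("cube simulation is a pure function of its seed", {
  layout <- small_layout()
  g <- small_grid()
  c1 <- simulate_cube(layout, membrane_state(0.5), grid = g, seed = 11,
                      block_px = 2)
  c2 <- simulate_cube(layout, membrane_state(0.5), grid = g, seed = 11,
                      block_px = 2)
  expect_identical(c1$values, c2$values)
  c3 <- simulate_cube(layout, membrane_state(0.5), grid = g, seed = 12,
                      block_px = 2)
  expect_false(identical(c1$values, c3$values))
  expect_true(all(c1$values >= 0 & c1$values <= 1.5))
})

test_that("block-mean standard error scales as sigma over sqrt(n)", {
  layout <- small_layout()
  g <- spectral_grid(1400, 1408, 2)
  sigma <- 0.05
  block_px <- 2                       # n = 4 imaging pixels per block
  nz <- noise_model(additive_sigma = sigma, drift_amplitude = 0)
  means <- vapply(1:120, function(s) {
    cube <- simulate_cube(layout, membrane_state(0), model = NULL,
                          noise = nz, grid = g, seed = s,
                          block_px = block_px)
    mean(cube$values[1:block_px, 1:block_px, 3])
  }, numeric(1))
  se <- sd(means)
  expect_equal(se, sigma / sqrt(block_px^2), tolerance = 0.3)
})

test_that("labeled datasets are balanced, reproducible and contrast-controlled", {
  bc <- small_barcode()
  g <- small_grid()
  ds <- generate_labeled_dataset(10, barcode = bc, grid = g, seed = 4,
                                 block_px = 4)
  expect_equal(dim(ds$x), c(20, 7, length(g$values)))
  expect_equal(as.vector(table(ds$labels)), c(10, 10))
  expect_true(all(ds$x >= 0))
  # at full contrast the label matches the cis_fraction >= 0.5 rule
  expect_equal(label_state(ds$cis_fraction), ds$labels)

  ds2 <- generate_labeled_dataset(10, barcode = bc, grid = g, seed = 4,
                                  block_px = 4)
  expect_identical(ds$x, ds2$x)
  expect_identical(ds$labels, ds2$labels)

  # null construction: identical generative distributions -> class means
  # agree within Monte-Carlo error of the per-item variability
  dsn <- generate_labeled_dataset(60, contrast = 0, barcode = bc, grid = g,
                                  seed = 9, block_px = 4)
  m_cis <- colMeans(dsn$x[dsn$labels == "cis", 4, ])
  m_trans <- colMeans(dsn$x[dsn$labels == "trans", 4, ])
  pooled_se <- sqrt(apply(dsn$x[, 4, ], 2, var) * 2 / 60)
  expect_true(all(abs(m_cis - m_trans) < 5 * pooled_se))
  expect_error(generate_labeled_dataset(0), "n_per_class")
  expect_error(generate_labeled_dataset(5, contrast = 2), "contrast")
})

test_that("dataset size matches the study protocol", {
  # 247 per class -> 494 items of 49 averaged spectra x 251 wavenumbers
  ds <- generate_labeled_dataset(247, seed = 1)
  expect_equal(dim(ds$x), c(494, 49, 251))
  expect_equal(as.vector(table(ds$labels)), c(247, 247))
})

test_that("cube series applies one shared drift path and saves/loads", {
  layout <- small_layout()
  g <- spectral_grid(1400, 1404, 2)
  prot <- switch_protocol(lead_in_s = 128, n_cycles = 1, on_s = 64,
                          off_s = 64, frame_period_s = 64)
  traj <- switching_trajectory(prot, kinetics_params(),
                               t_end_s = 256)
  cubes <- simulate_cube_series(layout, traj, grid = g, seed = 2,
                                block_px = 2)
  expect_length(cubes, nrow(traj))
  expect_equal(vapply(cubes, function(cb) cb$timestamp_s, numeric(1)),
               traj$time_s)
  path <- tempfile(fileext = ".rds")
  save_cube(cubes[[1]], path)
  expect_equal(load_cube(path)$values, cubes[[1]]$values)
})
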