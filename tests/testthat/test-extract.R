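test_that("block averaging is exact arithmetic over imaging pixels", {
  layout <- small_layout()
  g <- spectral_grid(1400, 1408, 2)
  nz <- noise_model(additive_sigma = 0, drift_amplitude = 0)
  cube <- simulate_cube(layout, membrane_state(0), noise = nz, grid = g,
                        seed = 1, block_px = 2)
  base <- extract_metapixel_spectra(cube, layout)

  # one hot pixel doubled -> block mean shifts by value / n at that channel
  n_px <- 2 * 2
  v <- cube$values[1, 1, 3]
  cube$values[1, 1, 3] <- 2 * v
  shifted <- extract_metapixel_spectra(cube, layout)
  slot0 <- which(layout$slots$row == 0 & layout$slots$col == 0)
  expect_equal(shifted$values[slot0, 3] - base$values[slot0, 3], v / n_px,
               tolerance = 1e-12)
  other <- setdiff(seq_len(nrow(base$values)), slot0)
  expect_equal(shifted$values[other, ], base$values[other, ])

  # slot count equals layout slot count
  expect_equal(nrow(base$values), nrow(layout$slots))

  # extraction commutes with scalar scaling of the cube
  cube2 <- cube
  cube2$values <- cube$values * 0.5
  expect_equal(extract_metapixel_spectra(cube2, layout)$values,
               shifted$values * 0.5, tolerance = 1e-12)
})

test_that("duplicate averaging returns one spectrum per target design", {
  layout <- small_layout()
  g <- small_grid()
  nz <- noise_model(additive_sigma = 0.02, drift_amplitude = 0)
  cube <- simulate_cube(layout, membrane_state(0.9), noise = nz, grid = g,
                        seed = 3, block_px = 2)
  spectra <- extract_metapixel_spectra(cube, layout)
  avg <- average_doubled(spectra, layout)
  expect_equal(nrow(avg$values), 7)
  expect_equal(avg$design_id, 1:7)

  # averaged value is the arithmetic mean of the two duplicates
  rows <- which(spectra$design_id == 4)
  expect_equal(avg$values[4, ], colMeans(spectra$values[rows, ]))

  # idempotence: identical duplicates average to themselves
  spectra$values[rows[2], ] <- spectra$values[rows[1], ]
  avg2 <- average_doubled(spectra, layout)
  expect_equal(avg2$values[4, ], spectra$values[rows[1], ])

  # duplicate-averaged spectra are less noisy than single-pixel spectra
  layoutN <- small_layout()
  vars_single <- vars_avg <- numeric(100)
  for (s in 1:100) {
    cb <- simulate_cube(layoutN, membrane_state(0.9), noise = nz, grid = g,
                        seed = 100 + s, block_px = 2)
    sp <- extract_metapixel_spectra(cb, layoutN)
    av <- average_doubled(sp, layoutN)
    r <- which(sp$design_id == 2)
    vars_single[s] <- sp$values[r[1], 5]
    vars_avg[s] <- av$values[2, 5]
  }
  expect_lt(var(vars_avg), var(vars_single))
})

test_that("absorbance follows the base-10 log-ratio convention", {
  g <- spectral_grid()
  ref <- rep(0.8, 251)
  expect_equal(absorbance_at_resonance(ref, ref, 1600, grid = g), 0)
  samp <- ref * 0.1
  expect_equal(absorbance_at_resonance(samp, ref, 1600, grid = g), 1)
  expect_error(absorbance_at_resonance(rep(0, 251), ref, 1600, grid = g),
               "positive")

  # a loss band at the resonance makes the absorbance strictly positive
  d <- metapixel_design(1, 1511, Q = 100)
  loss <- molecular_loss(molecular_model(), membrane_state(1, 0.9), g)
  r_ref <- metapixel_reflectance(d, grid = g)
  r_smp <- metapixel_reflectance(d, loss = loss, grid = g)
  expect_gt(absorbance_at_resonance(r_smp, r_ref, 1511), 0)
})

test_that("per-pixel absorbances are non-negative for loss-free references", {
  bc <- build_target_barcode(49, c(1400, 1800))
  g <- spectral_grid()
  st <- membrane_state(1, 0.9)
  sample_m <- design_reflectance_matrix(bc$designs, st, molecular_model(), g)
  ref_m <- design_reflectance_matrix(bc$designs, st, NULL, g)
  mk_set <- function(m) structure(list(values = unname(m), design_id = 1:49,
                                       grid = g), class = "spectra_set")
  pts <- per_pixel_absorbance(mk_set(sample_m), mk_set(ref_m), bc$designs)
  expect_length(pts$values, 49)
  expect_true(all(pts$values >= 0))
})

test_that("absorbance reconstruction preserves cubics and recovers band positions", {
  g <- spectral_grid()
  nu <- seq(1400, 1800, length.out = 49)

  # order-3 Savitzky-Golay preserves an exact cubic
  f <- function(x) 1e-9 * (x - 1600)^3 + 2e-6 * (x - 1600)^2 + 0.05
  pts <- structure(list(nu0 = nu, values = f(nu), design_id = 1:49),
                   class = "absorbance_points")
  rec <- reconstruct_absorbance_spectrum(pts, g, window = 11, polyorder = 3)
  interior <- g$values >= 1410 & g$values <= 1790
  # residual error is the linear-interpolation error, small on this scale
  expect_lt(max(abs(rec$values[interior] - f(g$values[interior]))), 2e-4)

  # constants pass through unchanged
  ptsC <- structure(list(nu0 = nu, values = rep(0.07, 49), design_id = 1:49),
                    class = "absorbance_points")
  recC <- reconstruct_absorbance_spectrum(ptsC, g)
  expect_equal(recC$values, rep(0.07, 251), tolerance = 1e-12)

  expect_error(reconstruct_absorbance_spectrum(pts, g, window = 3, polyorder = 3),
               "window")

  # end-to-end: a single injected band at 1511 is recovered within 2 steps
  bc <- build_target_barcode(49, c(1400, 1800))
  m1511 <- molecular_model("explicit",
                           trans_bands = list(),
                           cis_bands = list(absorption_band(1511, 15, 0.6)),
                           density_scale_cis = 1)
  st <- membrane_state(1, 0.9)
  sample_m <- design_reflectance_matrix(bc$designs, st, m1511, g)
  ref_m <- design_reflectance_matrix(bc$designs, st, NULL, g)
  mk_set <- function(m) structure(list(values = unname(m), design_id = 1:49,
                                       grid = g), class = "spectra_set")
  ppts <- per_pixel_absorbance(mk_set(sample_m), mk_set(ref_m), bc$designs)
  recB <- reconstruct_absorbance_spectrum(ppts, g)
  expect_lte(abs(g$values[which.max(recB$values)] - 1511), 2 * g$step)
})

test_that("barcode maps are design-ordered and round-trip", {
  vals <- seq(0.01, 0.49, length.out = 49)
  map <- render_barcode_map(vals)
  expect_equal(dim(map), c(7, 7))
  expect_equal(flatten_barcode_map(map), vals)
  expect_equal(unclass(map)[1, ], vals[1:7])      # row-major design order
  mapC <- render_barcode_map(rep(0.3, 49))
  expect_true(all(unclass(mapC) == 0.3))
  expect_error(render_barcode_map(vals[1:48]), "49")

  # cis membrane: high-absorbance regions sit at the band-rich top and
  # bottom rows of the barcode (1470-1511 and 1735 bands)
  bc <- build_target_barcode(49, c(1400, 1800))
  g <- spectral_grid()
  st <- membrane_state(1, 0.9)
  sm <- design_reflectance_matrix(bc$designs, st, molecular_model(), g)
  rm <- design_reflectance_matrix(bc$designs, st, NULL, g)
  mk_set <- function(m) structure(list(values = unname(m), design_id = 1:49,
                                       grid = g), class = "spectra_set")
  pts <- per_pixel_absorbance(mk_set(sm), mk_set(rm), bc$designs)
  cis_map <- render_barcode_map(pts)
  top5 <- order(pts$values, decreasing = TRUE)[1:5]
  nu_top <- pts$nu0[top5]
  expect_true(all(nu_top > 1450 & nu_top < 1530 | nu_top > 1700))
})

test_that("time-series absorbance applies the exclusion rules", {
  # first LED at 70 min: frames in [56, 70) min are excluded, as are LED-on
  # frames inside each 4.5-min window
  prot <- switch_protocol(lead_in_s = 70 * 60, n_cycles = 3)
  t_frames <- seq(0, 70 * 60 + 3 * 1170 + 900, by = 64)
  excl <- excluded_frames(t_frames, prot)
  in_pre <- t_frames >= 56 * 60 & t_frames < 70 * 60
  expect_true(all(excl[in_pre]))
  expect_false(any(excl[t_frames < 56 * 60]))
  for (i in seq_len(3)) {
    ev <- prot$events[i, ]
    on <- t_frames >= ev$start_s & t_frames < ev$start_s + ev$duration_s
    expect_true(all(excl[on]))
  }
  off_after <- t_frames >= prot$events$start_s[1] + 270 &
    t_frames < prot$events$start_s[2]
  expect_false(any(excl[off_after]))

  # identical analyte and reference frames give zero absorbance throughout
  layout <- small_layout()
  g <- small_grid()
  nz <- noise_model(additive_sigma = 0, drift_amplitude = 0)
  cubes <- lapply(1:6, function(i) {
    cb <- simulate_cube(layout, membrane_state(0), model = NULL, noise = nz,
                        grid = g, seed = 1, block_px = 2,
                        timestamp_s = (i - 1) * 64)
    cb
  })
  ts <- timeseries_absorbance(cubes, layout, reference_frames = 1:3,
                              design_id = 2)
  expect_equal(ts$absorbance, rep(0, 6), tolerance = 1e-12)
  expect_error(timeseries_absorbance(cubes, layout, integer(0), 2), "empty")
})
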