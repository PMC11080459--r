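#' Extract per-metapixel spectra from a hyperspectral cube
#'
#' Averages the imaging pixels of each slot's spatial block, per wavenumber,
#' giving one reflectance spectrum per physical metapixel (100 for the full
#' barcode layout).
#'
#' @param cube A `hyperspectral_cube`.
#' @param layout The [double_and_randomize()] layout used to pattern the
#'   cube.
#' @return A `spectra_set`: list with `values` (n_slots x n_wavenumbers
#'   matrix), `design_id` (per slot), `slot`, `grid`.
#' @export
extract_metapixel_spectra <- function(cube, layout) {
  stopifnot(inherits(cube, "hyperspectral_cube"),
            inherits(layout, "physical_layout"))
  block_x <- cube$nx / layout$shape[1]
  block_y <- cube$ny / layout$shape[2]
  if (block_x != round(block_x) || block_y != round(block_y) ||
      block_x < 1 || block_y < 1) {
    stop("extract_metapixel_spectra: cube extent does not cover the layout blocks")
  }
  L <- length(cube$grid$values)
  n_slots <- nrow(layout$slots)
  values <- matrix(NA_real_, n_slots, L)
  for (s in seq_len(n_slots)) {
    ix <- layout$slots$row[s] * block_x + seq_len(block_x)
    iy <- layout$slots$col[s] * block_y + seq_len(block_y)
    block <- cube$values[ix, iy, , drop = FALSE]
    values[s, ] <- apply(block, 3, mean)
  }
  structure(list(values = values, design_id = layout$slots$design_id,
                 slot = layout$slots$slot, grid = cube$grid),
            class = "spectra_set")
}

#' Average doubled metapixels
#'
#' Element-wise mean of the two duplicates of every doubled design; the two
#' extra metapixels are excluded. Returns exactly one spectrum per target
#' design, ordered by design id.
#'
#' @param spectra A `spectra_set` from [extract_metapixel_spectra()].
#' @param layout The corresponding layout.
#' @return A `spectra_set` with one row per target design (`design_id`
#'   ascending).
#' @export
average_doubled <- function(spectra, layout) {
  stopifnot(inherits(spectra, "spectra_set"),
            inherits(layout, "physical_layout"))
  target_ids <- sort(setdiff(unique(layout$slots$design_id), layout$extras))
  values <- matrix(NA_real_, length(target_ids), ncol(spectra$values))
  for (i in seq_along(target_ids)) {
    rows <- which(spectra$design_id == target_ids[i])
    if (length(rows) != 2) {
      stop(sprintf("average_doubled: design %d has %d spectra (expected 2)",
                   target_ids[i], length(rows)))
    }
    values[i, ] <- colMeans(spectra$values[rows, , drop = FALSE])
  }
  structure(list(values = values, design_id = target_ids,
                 slot = NULL, grid = spectra$grid),
            class = "spectra_set")
}

#' Absorbance at a resonance position
#'
#' The absorbance read out at a metapixel's resonance:
#' `A = -log10(R_sample(nu0) / R_reference(nu0))`, with `nu0` snapped to the
#' nearest grid point. The reference is the D2O-only measurement of the same
#' metapixel.
#'
#' @param sample,reference `reflectance_spectrum` objects (or numeric
#'   vectors on `grid`).
#' @param nu0 Resonance wavenumber (cm^-1).
#' @param grid Grid of the spectra (taken from `sample` if it is a
#'   `reflectance_spectrum`).
#' @return Absorbance (dimensionless, base-10 log).
#' @export
absorbance_at_resonance <- function(sample, reference, nu0, grid = NULL) {
  if (inherits(sample, "reflectance_spectrum")) {
    grid <- sample$grid
    sample <- sample$values
  }
  if (inherits(reference, "reflectance_spectrum")) reference <- reference$values
  assert_grid(grid)
  i <- grid_snap(grid, nu0)
  rs <- sample[i]
  rr <- reference[i]
  if (!is.finite(rs) || !is.finite(rr) || rs <= 0 || rr <= 0) {
    stop("absorbance_at_resonance: sample and reference must be positive at nu0")
  }
  -log10(rs / rr)
}

#' Per-metapixel absorbance of an averaged spectra set
#'
#' Applies [absorbance_at_resonance()] at every design's resonance position.
#'
#' @param sample,reference `spectra_set`s of averaged spectra (same design
#'   order).
#' @param designs List of the target [metapixel_design()]s (supplies `nu0`).
#' @return An `absorbance_points` object: list with `nu0`, `values`,
#'   `design_id`.
#' @export
per_pixel_absorbance <- function(sample, reference, designs) {
  stopifnot(inherits(sample, "spectra_set"), inherits(reference, "spectra_set"))
  ids <- vapply(designs, function(d) d$design_id, integer(1))
  if (!identical(as.integer(sample$design_id), as.integer(ids)) ||
      !identical(as.integer(reference$design_id), as.integer(ids))) {
    stop("per_pixel_absorbance: design order mismatch")
  }
  a <- vapply(seq_along(designs), function(i) {
    absorbance_at_resonance(sample$values[i, ], reference$values[i, ],
                            designs[[i]]$nu0, grid = sample$grid)
  }, numeric(1))
  structure(list(nu0 = vapply(designs, function(d) d$nu0, numeric(1)),
                 values = a, design_id = ids),
            class = "absorbance_points")
}

#' Reconstruct a dense absorbance spectrum
#'
#' Linearly interpolates the scattered per-metapixel absorbances onto the
#' model grid and smooths once with a third-order Savitzky-Golay filter
#' (endpoints handled by the filter's edge polynomial fits). Outside the
#' span of the resonance positions the interpolation is extended as a
#' constant.
#'
#' @param points An `absorbance_points` object (>= 4 points).
#' @param grid Target [spectral_grid()].
#' @param window Savitzky-Golay window length (odd, > `polyorder`).
#' @param polyorder Savitzky-Golay polynomial order (3 per the protocol).
#' @return An `absorbance_spectrum`: list with `grid`, `values`,
#'   `provenance = "reconstructed"`.
#' @export
reconstruct_absorbance_spectrum <- function(points, grid = spectral_grid(),
                                            window = 11, polyorder = 3) {
  stopifnot(inherits(points, "absorbance_points"))
  assert_grid(grid)
  if (length(points$values) < 4) {
    stop("reconstruct_absorbance_spectrum: at least 4 points required")
  }
  if (window %% 2 != 1 || window <= polyorder) {
    stop("reconstruct_absorbance_spectrum: window must be odd and exceed polyorder")
  }
  interp <- stats::approx(points$nu0, points$values, xout = grid$values,
                          rule = 2)$y
  smooth <- signal::sgolayfilt(interp, p = polyorder, n = window)
  structure(list(grid = grid, values = smooth, provenance = "reconstructed"),
            class = "absorbance_spectrum")
}

#' Render the 2D molecular barcode map
#'
#' Places the 49 per-metapixel absorbances into the 7 x 7 target-barcode
#' arrangement (design order, row-major) — the reduced barcode scheme in
#' which absorption bands appear as high-intensity regions.
#'
#' @param points An `absorbance_points` with exactly
#'   `prod(shape)` values, ordered by design.
#' @param shape Barcode shape (rows, cols).
#' @return A `barcode_map`: matrix `shape[1] x shape[2]`.
#' @export
render_barcode_map <- function(points, shape = c(7, 7)) {
  values <- if (inherits(points, "absorbance_points")) points$values else points
  if (length(values) != prod(shape)) {
    stop(sprintf("render_barcode_map: expected %d values, got %d",
                 prod(shape), length(values)))
  }
  m <- matrix(values, nrow = shape[1], ncol = shape[2], byrow = TRUE)
  class(m) <- c("barcode_map", class(m))
  m
}

#' @export
plot.barcode_map <- function(x, main = "molecular barcode", ...) {
  m <- unclass(x)
  graphics::image(t(m[rev(seq_len(nrow(m))), ]), axes = FALSE, main = main,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Flatten a barcode map back to design order
#' @param map A `barcode_map`.
#' @return Numeric vector in design order (row-major).
#' @export
flatten_barcode_map <- function(map) {
  as.vector(t(unclass(map)))
}

#' Frame exclusion rule for time-series data
#'
#' Flags frames that the absorbance/training protocol discards: all frames
#' within 14 min before the first LED illumination, and all frames with a
#' switching LED turned on.
#'
#' @param time_s Frame time stamps (s).
#' @param protocol A [switch_protocol()].
#' @param pre_window_s Exclusion window before the first LED event (s).
#' @return Logical vector, `TRUE` = excluded.
#' @export
excluded_frames <- function(time_s, protocol, pre_window_s = 14 * 60) {
  stopifnot(inherits(protocol, "switch_protocol"))
  ev <- protocol$events
  excl <- rep(FALSE, length(time_s))
  if (nrow(ev) == 0) return(excl)
  t1 <- min(ev$start_s)
  excl[time_s >= t1 - pre_window_s & time_s < t1] <- TRUE
  for (i in seq_len(nrow(ev))) {
    excl[time_s >= ev$start_s[i] &
           time_s < ev$start_s[i] + ev$duration_s[i]] <- TRUE
  }
  excl
}

#' Absorbance time series of one metapixel
#'
#' Builds the D2O reference spectrum as the mean over the designated
#' reference frames, then evaluates the absorbance of the chosen design at
#' its resonance position in every frame. Frames inside LED-on windows or
#' within 14 min before the first LED event are flagged excluded (but still
#' reported).
#'
#' @param cubes Ordered list of `hyperspectral_cube` (one per frame), or a
#'   list of `spectra_set`s already extracted.
#' @param layout The layout.
#' @param reference_frames Indices of the D2O-only reference frames; must
#'   precede all analyte frames.
#' @param design_id The design to read out.
#' @param protocol Optional [switch_protocol()] used for the exclusion
#'   flags.
#' @return Data.frame with `frame`, `time_s`, `absorbance`, `excluded`.
#' @export
timeseries_absorbance <- function(cubes, layout, reference_frames, design_id,
                                  protocol = NULL) {
  if (length(reference_frames) == 0) {
    stop("timeseries_absorbance: reference frame set must not be empty")
  }
  n <- length(cubes)
  if (max(reference_frames) >= min(setdiff(seq_len(n), reference_frames))) {
    stop("timeseries_absorbance: reference frames must precede analyte frames")
  }
  sets <- lapply(cubes, function(cb) {
    if (inherits(cb, "hyperspectral_cube")) {
      extract_metapixel_spectra(cb, layout)
    } else cb
  })
  times <- vapply(seq_len(n), function(i) {
    if (inherits(cubes[[i]], "hyperspectral_cube")) cubes[[i]]$timestamp_s
    else (i - 1) * 64
  }, numeric(1))
  rows <- which(sets[[1]]$design_id == design_id)
  if (length(rows) == 0) stop("timeseries_absorbance: design not in layout")
  grid <- sets[[1]]$grid
  nu0 <- layout$designs[[as.character(design_id)]]$nu0
  pixel_spec <- function(s) colMeans(s$values[rows, , drop = FALSE])
  reference <- colMeans(do.call(rbind, lapply(sets[reference_frames], pixel_spec)))
  a <- vapply(seq_len(n), function(i) {
    absorbance_at_resonance(pixel_spec(sets[[i]]), reference, nu0, grid = grid)
  }, numeric(1))
  excl <- if (is.null(protocol)) rep(FALSE, n) else excluded_frames(times, protocol)
  data.frame(frame = seq_len(n), time_s = times, absorbance = a,
             excluded = excl)
}

#' Write spectra / absorbance tables as CSV
#'
#' Wide-format spectra table: one row per metapixel, a `design_id` column,
#' then one column per wavenumber.
#'
#' @param spectra A `spectra_set`.
#' @param path Output file.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectra_set"))
  df <- data.frame(design_id = spectra$design_id, spectra$values)
  names(df)[-1] <- sprintf("wn_%g", spectra$grid$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
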