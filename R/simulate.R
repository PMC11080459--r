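#' Measurement noise model
#'
#' Additive per-voxel Gaussian noise plus a slow multiplicative drift shared
#' by all pixels of a frame, emulating illumination variations and
#' evaporation-related drifts of the optofluidic measurement. Across frames
#' the drift follows an Ornstein-Uhlenbeck process with stationary standard
#' deviation `drift_amplitude` and correlation time `drift_timescale_s`.
#'
#' @param additive_sigma Per-imaging-pixel Gaussian noise sd (reflectance
#'   units).
#' @param drift_amplitude Stationary sd of the multiplicative drift.
#' @param drift_timescale_s Drift correlation time (s).
#' @return A `noise_model` object.
#' @export
noise_model <- function(additive_sigma = 0.01, drift_amplitude = 0.02,
                        drift_timescale_s = 600) {
  if (additive_sigma < 0) stop("noise_model: additive_sigma must be >= 0")
  if (drift_amplitude < 0) stop("noise_model: drift_amplitude must be >= 0")
  if (drift_timescale_s <= 0) stop("noise_model: drift_timescale_s must be > 0")
  structure(list(additive_sigma = additive_sigma,
                 drift_amplitude = drift_amplitude,
                 drift_timescale_s = drift_timescale_s),
            class = "noise_model")
}

## Ornstein-Uhlenbeck path (stationary initial condition), given an active RNG
ou_path <- function(n, dt, tau, sd) {
  if (sd == 0 || n == 0) return(numeric(n))
  rho <- exp(-dt / tau)
  x <- numeric(n)
  x[1] <- sd * stats::rnorm(1)
  if (n > 1) {
    innov <- sd * sqrt(1 - rho^2) * stats::rnorm(n - 1)
    for (i in 2:n) x[i] <- rho * x[i - 1] + innov[i - 1]
  }
  x
}

## noise-free reflectance of every design in `designs` (rows) over the grid,
## for a single membrane state; vectorized over designs x wavenumbers
design_reflectance_matrix <- function(designs, state, model, grid,
                                      background = NULL, r_bg = 0.05) {
  assert_grid(grid)
  nu <- grid$values
  L <- length(nu)
  D <- length(designs)
  loss <- if (is.null(model)) numeric(L) else molecular_loss(model, state, grid)
  if (is.null(background)) background <- rep(1, L)
  nu0 <- vapply(designs, function(d) d$nu0, numeric(1))
  Q <- vapply(designs, function(d) d$Q, numeric(1))
  amp <- vapply(designs, function(d) d$amplitude, numeric(1))
  gamma_tot <- nu0 / (2 * Q)
  gamma_r <- gamma_tot / 2                     # default radiative/non-radiative split
  a <- (sqrt(amp) - r_bg) * gamma_tot / gamma_r
  # D x L complex denominator
  re <- outer(gamma_tot, loss, `+`)
  im <- outer(-nu0, nu, `+`)
  denom <- matrix(complex(real = re, imaginary = im), nrow = D)
  resp <- r_bg + (a * gamma_r) / denom
  out <- Mod(resp)^2 * rep(background, each = D)
  rownames(out) <- vapply(designs, function(d) as.character(d$design_id), "")
  out
}

#' Simulate one hyperspectral cube
#'
#' Forward-models a single acquisition frame: every slot of the physical
#' layout occupies a contiguous `block_px` x `block_px` block of imaging
#' pixels, each carrying that metapixel's reflectance spectrum plus additive
#' Gaussian noise; a multiplicative drift factor is shared by the whole
#' frame. Fully reproducible from the seed.
#'
#' @param layout A [double_and_randomize()] layout (carries the designs).
#' @param state A [membrane_state()].
#' @param model A [molecular_model()] or `NULL` for a bare metasurface.
#' @param noise A [noise_model()].
#' @param grid A [spectral_grid()].
#' @param seed Integer seed.
#' @param block_px Imaging pixels per metapixel side (default 16, i.e. a
#'   160 x 160 cube for the 10 x 10 layout).
#' @param background Attenuation vector (e.g. [d2o_background()]) or `NULL`.
#' @param drift_factor Optional fixed multiplicative drift; by default drawn
#'   from the stationary drift distribution.
#' @param timestamp_s Acquisition time stamp (s).
#' @return A `hyperspectral_cube`: list with `grid`, `nx`, `ny`, `values`
#'   (array nx x ny x n_wavenumbers, clipped to `[0, 1.5]`), `timestamp_s`,
#'   `drift_factor`, `seed`.
#' @export
simulate_cube <- function(layout, state, model = molecular_model(),
                          noise = noise_model(), grid = spectral_grid(),
                          seed = 1, block_px = 16, background = NULL,
                          drift_factor = NULL, timestamp_s = 0) {
  stopifnot(inherits(layout, "physical_layout"))
  assert_grid(grid)
  L <- length(grid$values)
  refl <- design_reflectance_matrix(layout$designs, state, model, grid,
                                    background = background)
  nrow_b <- layout$shape[1]
  ncol_b <- layout$shape[2]
  nx <- nrow_b * block_px
  ny <- ncol_b * block_px
  values <- array(0, dim = c(nx, ny, L))
  for (s in seq_len(nrow(layout$slots))) {
    r <- layout$slots$row[s]
    cc <- layout$slots$col[s]
    spec <- refl[as.character(layout$slots$design_id[s]), ]
    ix <- r * block_px + seq_len(block_px)
    iy <- cc * block_px + seq_len(block_px)
    values[ix, iy, ] <- rep(spec, each = block_px * block_px)
  }
  with_local_seed(seed, {
    if (is.null(drift_factor)) {
      drift_factor <- 1 + noise$drift_amplitude * stats::rnorm(1)
    }
    values <- values * drift_factor
    if (noise$additive_sigma > 0) {
      values <- values + stats::rnorm(length(values), sd = noise$additive_sigma)
    }
  })
  values <- pmin(pmax(values, 0), 1.5)
  structure(list(grid = grid, nx = nx, ny = ny, values = values,
                 timestamp_s = timestamp_s, drift_factor = drift_factor,
                 seed = seed),
            class = "hyperspectral_cube")
}

#' Simulate a time series of cubes along a switching trajectory
#'
#' One cube per trajectory frame, with the multiplicative drift following a
#' single Ornstein-Uhlenbeck path across frames and independent additive
#' noise per cube.
#'
#' @inheritParams simulate_cube
#' @param trajectory Output of [switching_trajectory()].
#' @param coverage Membrane coverage used for all frames.
#' @return List of `hyperspectral_cube`, one per frame.
#' @export
simulate_cube_series <- function(layout, trajectory,
                                 model = molecular_model(),
                                 noise = noise_model(),
                                 grid = spectral_grid(), seed = 1,
                                 block_px = 16, background = NULL,
                                 coverage = 0.9) {
  n <- nrow(trajectory)
  dt <- if (n > 1) diff(trajectory$time_s[1:2]) else 64
  drift <- with_local_seed(seed, {
    1 + ou_path(n, dt, noise$drift_timescale_s, noise$drift_amplitude)
  })
  lapply(seq_len(n), function(i) {
    simulate_cube(layout,
                  membrane_state(trajectory$cis_fraction[i], coverage),
                  model = model, noise = noise, grid = grid,
                  seed = seed + i, block_px = block_px,
                  background = background, drift_factor = drift[i],
                  timestamp_s = trajectory$time_s[i])
  })
}

#' Membrane-state class label
#'
#' The class label of a generating membrane state: cis when the cis fraction
#' is at least 0.5, trans otherwise.
#'
#' @param cis_fraction Numeric vector of cis fractions.
#' @return Factor with levels `c("trans", "cis")`.
#' @export
label_state <- function(cis_fraction) {
  factor(ifelse(cis_fraction >= 0.5, "cis", "trans"),
         levels = c("trans", "cis"))
}

#' Generate a labeled dataset of averaged metapixel spectra
#'
#' Draws balanced cis/trans measurement sets as they come out of the
#' extraction stage: each item is the full set of averaged metapixel
#' reflectance spectra of the target barcode on the model grid. Per item,
#' the cis fraction is placed at the photostationary value of its class
#' (interpolated toward the trans value by `contrast`; `contrast = 0` makes
#' the two class distributions identical, the null construction of the
#' bare-substrate control), with small item-to-item jitter in cis fraction
#' and coverage, a per-item multiplicative drift, and additive spectral
#' noise at the level left after block-and-duplicate averaging
#' (`additive_sigma / sqrt(2 * block_px^2)`).
#'
#' At default contrast the class label coincides with the
#' `cis_fraction >= 0.5` rule (see [label_state()]); at reduced contrast the
#' label records the generating class.
#'
#' @param n_per_class Items per class (the study dataset uses 247, i.e. 494
#'   spectra in total).
#' @param contrast Class contrast in `[0, 1]`; 1 = full photostationary
#'   separation, 0 = identical generative distributions.
#' @param barcode A [build_target_barcode()] (49 designs by default).
#' @param model A [molecular_model()].
#' @param noise A [noise_model()].
#' @param grid A [spectral_grid()].
#' @param kinetics A [kinetics_params()] supplying the photostationary
#'   cis fractions of the two classes.
#' @param seed Integer seed.
#' @param block_px Imaging pixels per metapixel side used to set the
#'   effective spectral noise after averaging.
#' @param coverage_mean,coverage_sd,cis_jitter_sd Item-to-item variability.
#' @param background Attenuation vector or `NULL`.
#' @return A `labeled_dataset`: list with `x` (array n_items x n_designs x
#'   n_wavenumbers), `labels` (factor, levels trans/cis), `cis_fraction`,
#'   `nu0` (design resonance positions), `grid`, `seed`.
#' @export
generate_labeled_dataset <- function(n_per_class = 247, contrast = 1,
                                     barcode = build_target_barcode(),
                                     model = molecular_model(),
                                     noise = noise_model(),
                                     grid = spectral_grid(),
                                     kinetics = kinetics_params(),
                                     seed = 1, block_px = 16,
                                     coverage_mean = 0.9, coverage_sd = 0.03,
                                     cis_jitter_sd = 0.02,
                                     background = NULL) {
  if (n_per_class < 1) stop("generate_labeled_dataset: n_per_class must be >= 1")
  if (contrast < 0 || contrast > 1) {
    stop("generate_labeled_dataset: contrast must lie in [0, 1]")
  }
  designs <- barcode$designs
  D <- length(designs)
  L <- length(grid$values)
  n <- 2L * n_per_class
  labels <- factor(rep(c("trans", "cis"), each = n_per_class),
                   levels = c("trans", "cis"))
  cf_target <- ifelse(labels == "cis",
                      kinetics$pss_vis + contrast * (kinetics$pss_uv - kinetics$pss_vis),
                      kinetics$pss_vis)
  sigma_eff <- noise$additive_sigma / sqrt(2 * block_px^2)
  x <- array(NA_real_, dim = c(n, D, L))
  cf <- numeric(n)
  with_local_seed(seed, {
    cf <- pmin(pmax(cf_target + stats::rnorm(n, sd = cis_jitter_sd), 0), 1)
    cov <- pmin(pmax(stats::rnorm(n, coverage_mean, coverage_sd), 0), 1)
    drift <- 1 + noise$drift_amplitude * stats::rnorm(n)
    for (i in seq_len(n)) {
      refl <- design_reflectance_matrix(designs,
                                        membrane_state(cf[i], cov[i]),
                                        model, grid, background = background)
      eps <- if (sigma_eff > 0) stats::rnorm(D * L, sd = sigma_eff) else 0
      x[i, , ] <- pmax(drift[i] * refl + eps, 0)
    }
  })
  # shuffle item order so class is not encoded in position
  ord <- with_local_seed(seed + 1L, sample.int(n))
  structure(
    list(x = x[ord, , , drop = FALSE], labels = labels[ord],
         cis_fraction = cf[ord],
         nu0 = vapply(designs, function(d) d$nu0, numeric(1)),
         grid = grid, seed = seed),
    class = "labeled_dataset"
  )
}

#' Per-frame spectra of selected designs along a trajectory
#'
#' Generates the averaged-metapixel reflectance spectra the extraction stage
#' would deliver for each trajectory frame, without materializing full
#' cubes. Used for time-series classification.
#'
#' @inheritParams generate_labeled_dataset
#' @param trajectory Output of [switching_trajectory()].
#' @param designs List of [metapixel_design()] (e.g. the selected metapixel).
#' @param coverage Coverage for all frames.
#' @return Array n_frames x n_designs x n_wavenumbers.
#' @export
generate_frame_spectra <- function(trajectory, designs,
                                   model = molecular_model(),
                                   noise = noise_model(),
                                   grid = spectral_grid(), seed = 1,
                                   block_px = 16, coverage = 0.9,
                                   background = NULL) {
  n <- nrow(trajectory)
  D <- length(designs)
  L <- length(grid$values)
  sigma_eff <- noise$additive_sigma / sqrt(2 * block_px^2)
  dt <- if (n > 1) diff(trajectory$time_s[1:2]) else 64
  x <- array(NA_real_, dim = c(n, D, L))
  with_local_seed(seed, {
    drift <- 1 + ou_path(n, dt, noise$drift_timescale_s, noise$drift_amplitude)
    for (i in seq_len(n)) {
      refl <- design_reflectance_matrix(
        designs, membrane_state(trajectory$cis_fraction[i], coverage),
        model, grid, background = background)
      eps <- if (sigma_eff > 0) stats::rnorm(D * L, sd = sigma_eff) else 0
      x[i, , ] <- pmax(drift[i] * refl + eps, 0)
    }
  })
  x
}

#' Save / load a hyperspectral cube
#'
#' Runtime serialization of cubes (RDS container holding the reflectance
#' array, wavenumber grid, timestamp and seed).
#'
#' @param cube A `hyperspectral_cube`.
#' @param path File path.
#' @export
save_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hyperspectral_cube"))
  saveRDS(cube, path)
  invisible(path)
}

#' @rdname save_cube
#' @export
load_cube <- function(path) {
  cube <- readRDS(path)
  stopifnot(inherits(cube, "hyperspectral_cube"))
  cube
}
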