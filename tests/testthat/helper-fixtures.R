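# Small fixtures shared across test files. All synthetic, built in code.

# a 16-slot physical layout (7 doubled designs + 2 extras) over a short grid:
# cheap enough for Monte-Carlo loops
small_grid <- function() spectral_grid(1400, 1460, 2)

small_layout <- function(seed = 0) {
  bc <- build_target_barcode(n_pixels = 7, resonance_range = c(1410, 1450),
                             Q = 60, amplitude = 0.8)
  double_and_randomize(bc, seed = seed)
}

small_barcode <- function() {
  build_target_barcode(n_pixels = 7, resonance_range = c(1410, 1450),
                       Q = 60, amplitude = 0.8)
}

# tiny single-channel CNN that trains in well under a second
tiny_spec <- function(input_length = 16) {
  sp <- cnn_spec("pruned", input_length = input_length)
  sp$layers <- cbind(filters = c(4L, 4L), kernel = c(3L, 3L),
                     stride = c(1L, 1L))
  sp
}

# linearly separable single-channel two-class data
separable_data <- function(n_per_class = 20, len = 16, seed = 1) {
  x <- with_seed_local(seed, {
    base <- matrix(stats::rnorm(2 * n_per_class * len, sd = 0.05),
                   2 * n_per_class, len)
    base[seq_len(n_per_class), 4:8] <- base[seq_len(n_per_class), 4:8] + 1
    base + 0.5
  })
  list(x = x,
       labels = factor(rep(c("cis", "trans"), each = n_per_class),
                       levels = c("trans", "cis")))
}

# run expr under a seed without clobbering the session RNG
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# unit-peak Lorentzian used to build independent loss channels in tests
lorentz_test <- function(nu, center, fwhm) {
  (fwhm / 2)^2 / ((nu - center)^2 + (fwhm / 2)^2)
}

# molecular model whose classes differ only in a single band at 1742 cm^-1
contrast_1742_model <- function(strength = 0.5) {
  base <- list(absorption_band(1470, 15, 0.40),
               absorption_band(1496, 15, 0.35),
               absorption_band(1735, 15, 0.80))
  molecular_model("explicit", trans_bands = base,
                  cis_bands = c(base, list(absorption_band(1742, 15, strength))),
                  density_scale_cis = 1)
}
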