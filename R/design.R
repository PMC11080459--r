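#' Metapixel unit-cell design
#'
#' One metapixel of the barcode: a sub-array of identical tilted-ellipse-pair
#' unit cells supporting a single quasi-BIC resonance. Only the resonance
#' parameters (`nu0`, `Q`, `amplitude`) enter any spectral computation; the
#' geometry record (ellipse axes, pitches, tilt, film thickness, scaled by
#' `scale_S` from the reference S = 1 design with A = 2000 nm, B = 480 nm,
#' Px = 2100 nm, Py = 2050 nm, theta = 20 deg, t = 700 nm) is carried as
#' metadata only.
#'
#' @param design_id Integer identifier.
#' @param nu0 Resonance wavenumber (cm^-1), positive.
#' @param Q Quality factor, positive (the fabricated designs reach Q > 80).
#' @param amplitude Peak reflectance contribution in `[0, 1]`.
#' @param scale_S Lateral scaling factor of the unit cell (metadata).
#' @return A `metapixel_design` object.
#' @export
metapixel_design <- function(design_id, nu0, Q = 100, amplitude = 0.85,
                             scale_S = NULL) {
  if (!is.numeric(nu0) || nu0 < 0) stop("metapixel_design: nu0 must be non-negative")
  if (!is.numeric(Q) || Q <= 0) stop("metapixel_design: Q must be positive")
  if (!is.numeric(amplitude) || amplitude < 0 || amplitude > 1) {
    stop("metapixel_design: amplitude must be in [0, 1]")
  }
  if (is.null(scale_S)) {
    scale_S <- if (nu0 > 0) 1600 / nu0 else NA_real_  # resonance ~ 1/size
  }
  structure(
    list(
      design_id = as.integer(design_id), nu0 = nu0, Q = Q,
      amplitude = amplitude, scale_S = scale_S,
      geometry = list(
        A_nm = 2000 * scale_S, B_nm = 480 * scale_S,
        Px_nm = 2100 * scale_S, Py_nm = 2050 * scale_S,
        theta_deg = 20, thickness_nm = 700
      )
    ),
    class = "metapixel_design"
  )
}

new_reflectance_spectrum <- function(grid, values, design_id = NA_integer_,
                                     role = "sample") {
  stopifnot(length(values) == length(grid$values), all(values >= 0))
  structure(list(grid = grid, values = values,
                 design_id = design_id, role = role),
            class = "reflectance_spectrum")
}

#' @export
print.reflectance_spectrum <- function(x, ...) {
  cat(sprintf("<reflectance_spectrum> design %s, %d points, role %s\n",
              x$design_id, length(x$values), x$role))
  invisible(x)
}

#' Metapixel reflectance from a coupled-mode Fano lineshape
#'
#' Computes the reflectance spectrum of a single metapixel using a one-mode
#' temporal coupled-mode (Fano) model:
#' \deqn{R(\nu) = B(\nu)\,\left| r_{bg} + \frac{a\,\gamma_r}
#'   {i(\nu-\nu_0) + \gamma_r + \gamma_{nr} + \ell(\nu)} \right|^2}
#' where \eqn{\gamma_r + \gamma_{nr} = \nu_0 / (2Q)} is the half width of the
#' resonance, \eqn{\ell(\nu)} is the molecular loss channel (added linewidth)
#' and \eqn{B(\nu)} the medium attenuation. A non-negative loss can only pull
#' the on-resonance reflectance down, which is how the membrane absorption
#' signature imprints itself on the resonance envelope.
#'
#' With a real `r_bg` this lineshape is exactly a Lorentzian peak on a flat
#' baseline, so an independent Lorentzian fit recovers `nu0` and `Q` (see
#' [fit_resonance()]).
#'
#' @param design A [metapixel_design()].
#' @param loss Numeric vector of per-wavenumber losses (cm^-1) or `NULL` for
#'   a bare resonator.
#' @param background Numeric vector of attenuation factors or `NULL` for 1.
#' @param grid A [spectral_grid()].
#' @param r_bg Background (direct) reflection amplitude, real.
#' @param a Resonant amplitude coefficient; by default chosen so that the
#'   loss-free on-resonance reflectance equals `design$amplitude`.
#' @param gamma_nr Non-radiative half width (cm^-1); default half of the
#'   total width `nu0/(2Q)`.
#' @return A `reflectance_spectrum`.
#' @examples
#' g <- spectral_grid()
#' d <- metapixel_design(1, 1600, Q = 80)
#' r <- metapixel_reflectance(d, grid = g)
#' @export
metapixel_reflectance <- function(design, loss = NULL, background = NULL,
                                  grid, r_bg = 0.05, a = NULL,
                                  gamma_nr = NULL) {
  if (!inherits(design, "metapixel_design")) {
    stop("metapixel_reflectance: design must be a metapixel_design")
  }
  assert_grid(grid)
  if (design$Q <= 0) stop("metapixel_reflectance: Q must be positive")
  if (design$nu0 <= 0) stop("metapixel_reflectance: nu0 must be positive")
  nu <- grid$values
  n <- length(nu)
  if (is.null(loss)) loss <- numeric(n)
  if (length(loss) == 1) loss <- rep(loss, n)
  if (length(loss) != n) stop("metapixel_reflectance: loss length must match grid")
  if (any(loss < 0)) stop("metapixel_reflectance: loss must be non-negative")
  if (is.null(background)) background <- rep(1, n)
  if (length(background) == 1) background <- rep(background, n)
  if (length(background) != n) stop("metapixel_reflectance: background length must match grid")

  gamma_tot <- design$nu0 / (2 * design$Q)
  if (is.null(gamma_nr)) gamma_nr <- 0.5 * gamma_tot
  if (gamma_nr < 0 || gamma_nr > gamma_tot) {
    stop("metapixel_reflectance: gamma_nr must lie in [0, nu0/(2Q)]")
  }
  gamma_r <- gamma_tot - gamma_nr
  if (is.null(a)) {
    # loss-free peak |r_bg + a*gamma_r/gamma_tot|^2 == amplitude
    a <- (sqrt(design$amplitude) - r_bg) * gamma_tot / gamma_r
  }
  denom <- complex(real = gamma_r + gamma_nr + loss, imaginary = nu - design$nu0)
  r <- r_bg + a * gamma_r / denom
  new_reflectance_spectrum(grid, background * Mod(r)^2,
                           design_id = design$design_id)
}

#' Fit a Lorentzian to a resonance spectrum
#'
#' Independent check of the forward model: fits
#' `R(nu) = c0 + A * hw^2 / ((nu - nu0)^2 + hw^2)` by Levenberg-Marquardt
#' least squares and reports the resonance position and quality factor
#' `Q = nu0 / (2 * hw)`.
#'
#' @param spectrum A `reflectance_spectrum` containing one resonance peak.
#' @return List with `nu0`, `Q`, `fwhm`, `peak` and the `fit` object.
#' @export
fit_resonance <- function(spectrum) {
  stopifnot(inherits(spectrum, "reflectance_spectrum"))
  nu <- spectrum$grid$values
  y <- spectrum$values
  i0 <- which.max(y)
  base <- stats::quantile(y, 0.1)
  half <- base + (y[i0] - base) / 2
  above <- which(y > half)
  hw0 <- max(diff(range(nu[above])) / 2, spectrum$grid$step)
  fit <- minpack.lm::nlsLM(
    y ~ c0 + A * hw^2 / ((nu - nu0)^2 + hw^2),
    start = list(c0 = base, A = y[i0] - base, nu0 = nu[i0], hw = hw0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- stats::coef(fit)
  list(nu0 = unname(p["nu0"]), Q = unname(p["nu0"] / (2 * p["hw"])),
       fwhm = unname(2 * p["hw"]), peak = unname(p["c0"] + p["A"]), fit = fit)
}
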