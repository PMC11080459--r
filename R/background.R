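#' D2O medium attenuation profile
#'
#' Multiplicative attenuation of the reflectance caused by absorption in the
#' deuterium-oxide medium along the optical path. The quantitative profile of
#' the medium is not tabulated here; a smooth Beer-Lambert profile with a
#' broad Gaussian absorbance band (defaults: center 1555 cm^-1, sd 150 cm^-1,
#' peak absorbance 0.3) stands in for the D2O/HDO association-band absorption
#' that attenuates the upper half of the 1400-1800 cm^-1 window. The
#' attenuation is `10^(-scale * A_med(nu))`, so doubling `absorbance_scale`
#' squares the attenuation pointwise (Beer-Lambert composition).
#'
#' @param grid A [spectral_grid()].
#' @param absorbance_scale Multiplier on the medium absorbance; `0` disables
#'   the medium entirely (attenuation identically 1).
#' @param center,sd,peak Shape parameters of the Gaussian absorbance band.
#' @param enabled Set `FALSE` to disable medium absorption.
#' @return Numeric vector of attenuation factors in (0, 1], one per grid point.
#' @export
d2o_background <- function(grid, absorbance_scale = 1,
                           center = 1555, sd = 150, peak = 0.3,
                           enabled = TRUE) {
  assert_grid(grid)
  if (!enabled || absorbance_scale == 0) {
    return(rep(1, length(grid$values)))
  }
  if (absorbance_scale < 0) stop("d2o_background: absorbance_scale must be >= 0")
  a_med <- peak * exp(-0.5 * ((grid$values - center) / sd)^2)
  10^(-absorbance_scale * a_med)
}
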