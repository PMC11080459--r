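#' Vibrational absorption band
#'
#' A single molecular absorption band, modelled as a unit-peak Lorentzian in
#' the loss channel of the resonator. `strength` is the loss the band
#' contributes at its center (cm^-1 of added linewidth at full coverage);
#' typical SEIRA-scale values here are a few tenths of a cm^-1, which against
#' a resonance half-width of ~8-10 cm^-1 produces absorbances of order
#' 1e-2 to 1e-1.
#'
#' @param center Band center (cm^-1).
#' @param fwhm Full width at half maximum (cm^-1), positive.
#' @param strength Oscillator amplitude (cm^-1 of linewidth at band center),
#'   non-negative.
#' @return An `absorption_band` object.
#' @export
absorption_band <- function(center, fwhm = 15, strength = 0.5) {
  if (!is.numeric(center) || center <= 0) stop("absorption_band: center must be positive")
  if (!is.numeric(fwhm) || fwhm <= 0) stop("absorption_band: fwhm must be positive")
  if (!is.numeric(strength) || strength < 0) stop("absorption_band: strength must be >= 0")
  structure(list(center = center, fwhm = fwhm, strength = strength),
            class = "absorption_band")
}

#' Molecular model of the photoswitchable lipid membrane
#'
#' Holds the vibrational band sets of the trans and cis states of the AzoPC
#' photolipid. The default preset carries the bands resolved on the
#' metasurface: CH2 scissoring (1470 cm^-1), azobenzene ring breathing
#' (1496 cm^-1), and ester C=O stretching (1735 cm^-1) in both states, plus
#' the N=N stretch at 1511 cm^-1 present only in the cis state. Because
#' photoisomerization to cis increases the lipid footprint by roughly 20%,
#' the areal lipid density drops; this is modelled by scaling all cis band
#' strengths by `density_scale_cis` (default 0.83 ~ 1/1.2).
#'
#' @param preset `"azopc"` for the default band sets, or `"explicit"` to
#'   supply `trans_bands`/`cis_bands` directly (empty lists are allowed and
#'   give a membrane with no molecular absorption).
#' @param trans_bands,cis_bands Lists of [absorption_band()] (used when
#'   `preset = "explicit"`).
#' @param density_scale_cis Factor in (0, 1] applied to cis band strengths.
#' @return A `molecular_model` object with elements `trans_bands`,
#'   `cis_bands`, `density_scale_cis`.
#' @examples
#' m <- molecular_model()
#' vapply(m$cis_bands, function(b) b$center, numeric(1))
#' @export
molecular_model <- function(preset = c("azopc", "explicit"),
                            trans_bands = NULL, cis_bands = NULL,
                            density_scale_cis = 0.83) {
  preset <- match.arg(preset)
  if (!is.numeric(density_scale_cis) ||
      density_scale_cis <= 0 || density_scale_cis > 1) {
    stop("molecular_model: density_scale_cis must be in (0, 1]")
  }
  if (preset == "azopc") {
    trans_bands <- list(
      absorption_band(1470, 15, 0.40),
      absorption_band(1496, 15, 0.35),
      absorption_band(1735, 15, 0.80)
    )
    cis_raw <- list(
      absorption_band(1470, 15, 0.40),
      absorption_band(1496, 15, 0.35),
      absorption_band(1511, 15, 0.50),
      absorption_band(1735, 15, 0.80)
    )
  } else {
    if (is.null(trans_bands) || is.null(cis_bands)) {
      stop("molecular_model: explicit preset requires trans_bands and cis_bands")
    }
    check_bands <- function(b, nm) {
      if (!is.list(b)) stop(sprintf("molecular_model: %s must be a list", nm))
      for (x in b) {
        if (!inherits(x, "absorption_band")) {
          stop(sprintf("molecular_model: %s entries must be absorption_band objects", nm))
        }
      }
    }
    check_bands(trans_bands, "trans_bands")
    check_bands(cis_bands, "cis_bands")
    cis_raw <- cis_bands
  }
  # areal-density reduction of the cis membrane enters the band strengths here
  cis_scaled <- lapply(cis_raw, function(b) {
    absorption_band(b$center, b$fwhm, b$strength * density_scale_cis)
  })
  structure(
    list(trans_bands = trans_bands, cis_bands = cis_scaled,
         density_scale_cis = density_scale_cis),
    class = "molecular_model"
  )
}

#' Membrane state
#'
#' @param cis_fraction Fraction of lipids in the cis conformation, in `[0, 1]`.
#' @param coverage Fractional surface coverage of the bilayer, in `[0, 1]`.
#' @return A `membrane_state` object.
#' @export
membrane_state <- function(cis_fraction = 0, coverage = 0.9) {
  for (v in c(cis_fraction = cis_fraction, coverage = coverage)) {
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop("membrane_state: cis_fraction and coverage must lie in [0, 1]")
    }
  }
  structure(list(cis_fraction = cis_fraction, coverage = coverage),
            class = "membrane_state")
}

## unit-peak Lorentzian
lorentz <- function(nu, center, fwhm) {
  hw <- fwhm / 2
  hw^2 / ((nu - center)^2 + hw^2)
}

#' Molecular loss channel
#'
#' Evaluates the per-wavenumber loss (added resonance linewidth, cm^-1) that
#' the membrane contributes to a metapixel resonance. Band strengths are
#' linearly interpolated between the trans (`cis_fraction = 0`) and cis
#' (`cis_fraction = 1`) band sets and multiplied by the surface coverage;
#' each band is a unit-peak Lorentzian.
#'
#' @param model A [molecular_model()].
#' @param state A [membrane_state()].
#' @param grid A [spectral_grid()].
#' @return Numeric vector of non-negative losses, one per grid point.
#' @export
molecular_loss <- function(model, state, grid) {
  if (!inherits(model, "molecular_model")) stop("molecular_loss: model must be a molecular_model")
  if (!inherits(state, "membrane_state")) stop("molecular_loss: state must be a membrane_state")
  assert_grid(grid)
  nu <- grid$values
  loss <- numeric(length(nu))
  cf <- state$cis_fraction
  # union over band identities (center, fwhm): absent bands have strength 0
  key <- function(b) sprintf("%.6f_%.6f", b$center, b$fwhm)
  tab <- new.env(parent = emptyenv())
  add <- function(bands, slot) {
    for (b in bands) {
      k <- key(b)
      cur <- if (is.null(tab[[k]])) list(center = b$center, fwhm = b$fwhm,
                                         trans = 0, cis = 0) else tab[[k]]
      cur[[slot]] <- cur[[slot]] + b$strength
      tab[[k]] <- cur
    }
  }
  add(model$trans_bands, "trans")
  add(model$cis_bands, "cis")
  for (k in ls(tab)) {
    b <- tab[[k]]
    w <- (1 - cf) * b$trans + cf * b$cis
    if (w > 0) loss <- loss + w * lorentz(nu, b$center, b$fwhm)
  }
  state$coverage * loss
}
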