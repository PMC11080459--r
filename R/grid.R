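#' Construct a regular wavenumber grid
#'
#' Spectra in this package live on a fixed, strictly increasing wavenumber
#' grid. The default is the model grid used throughout the analysis:
#' 1300 to 1800 cm^-1 at a 2 cm^-1 step (251 samples), the region where the
#' metapixel resonances and the photolipid vibrational bands are located.
#' The instrument grid (948 to 1800 cm^-1, same step) is available via
#' `instrument_grid()`.
#'
#' @param start First wavenumber (cm^-1).
#' @param stop Last wavenumber (cm^-1); included when `stop - start` is an
#'   integer multiple of `step`.
#' @param step Grid spacing (cm^-1), positive.
#' @return An object of class `spectral_grid`: list with `start`, `stop`,
#'   `step` and the vector of grid `values`.
#' @examples
#' g <- spectral_grid()
#' length(g$values)  # 251
#' @export
spectral_grid <- function(start = 1300, stop = 1800, step = 2) {
  if (!is.numeric(start) || !is.numeric(stop) || !is.numeric(step)) {
    stop("spectral_grid: start, stop, step must be numeric")
  }
  if (step <= 0) stop("spectral_grid: step must be positive")
  if (stop <= start) stop("spectral_grid: stop must exceed start")
  n <- floor((stop - start) / step + 1e-9) + 1L
  values <- start + (seq_len(n) - 1L) * step
  structure(
    list(start = start, stop = stop, step = step, values = values),
    class = "spectral_grid"
  )
}

#' @rdname spectral_grid
#' @export
instrument_grid <- function() spectral_grid(948, 1800, 2)

#' @export
length.spectral_grid <- function(x) length(x$values)

#' @export
print.spectral_grid <- function(x, ...) {
  cat(sprintf(
    "<spectral_grid> %g to %g cm^-1, step %g (%d samples)\n",
    x$start, x$stop, x$step, length(x$values)
  ))
  invisible(x)
}

## index of the grid point nearest nu (ties resolved toward the lower point)
grid_snap <- function(grid, nu) {
  stopifnot(inherits(grid, "spectral_grid"))
  i <- which.min(abs(grid$values - nu))
  i
}

assert_grid <- function(grid, arg = "grid") {
  if (!inherits(grid, "spectral_grid")) {
    stop(sprintf("%s must be a spectral_grid object", arg))
  }
  invisible(grid)
}
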