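#' Build the target barcode
#'
#' Constructs the 7 x 7 target barcode of metapixel designs with resonance
#' positions varying linearly over the target spectral range (by default 49
#' pixels covering 1400 to 1800 cm^-1), so that spectral position maps
#' bijectively to barcode position.
#'
#' @param n_pixels Number of designs (>= 2; default 49).
#' @param resonance_range Length-2 increasing range (cm^-1).
#' @param Q,amplitude Shared resonance parameters of all designs.
#' @return A `target_barcode`: list with `designs` (list of
#'   [metapixel_design()], design_id 1..n), `grid_shape`, `resonance_range`.
#' @examples
#' bc <- build_target_barcode()
#' bc$designs[[1]]$nu0   # 1400
#' bc$designs[[49]]$nu0  # 1800
#' @export
build_target_barcode <- function(n_pixels = 49,
                                 resonance_range = c(1400, 1800),
                                 Q = 100, amplitude = 0.85) {
  if (n_pixels < 2) stop("build_target_barcode: n_pixels must be >= 2")
  if (length(resonance_range) != 2 || diff(resonance_range) <= 0) {
    stop("build_target_barcode: resonance_range must be increasing")
  }
  nu0 <- resonance_range[1] +
    (seq_len(n_pixels) - 1) * diff(resonance_range) / (n_pixels - 1)
  designs <- lapply(seq_len(n_pixels), function(i) {
    metapixel_design(i, nu0[i], Q = Q, amplitude = amplitude)
  })
  side <- sqrt(n_pixels)
  grid_shape <- if (side == round(side)) c(side, side) else c(1, n_pixels)
  structure(list(designs = designs, grid_shape = grid_shape,
                 resonance_range = resonance_range),
            class = "target_barcode")
}

#' Default extra metapixels
#'
#' The physical barcode carries two extra metapixels beyond the 98 doubled
#' ones, used to densify the unit-cell dimension step. We place their
#' resonances at the midpoints of the two central inter-pixel gaps of the
#' target barcode, where the band-rich mid-range benefits most from denser
#' sampling.
#'
#' @param barcode A [build_target_barcode()] result.
#' @return List of 2 [metapixel_design()] with ids continuing after the
#'   barcode's.
#' @export
default_extra_designs <- function(barcode) {
  n <- length(barcode$designs)
  nu <- vapply(barcode$designs, function(d) d$nu0, numeric(1))
  mid <- floor(n / 2)
  d1 <- barcode$designs[[1]]
  lapply(seq_len(2), function(j) {
    i <- mid + j - 1
    metapixel_design(n + j, (nu[i] + nu[i + 1]) / 2,
                     Q = d1$Q, amplitude = d1$amplitude)
  })
}

#' Pixel doubling and randomized physical arrangement
#'
#' Duplicates every target design (pixel doubling, improving signal-to-noise
#' and robustness to spatial membrane variations), adds the two extra
#' designs, and arranges the resulting 100 metapixels uniformly at random on
#' the 10 x 10 physical grid under a fixed seed, so that the linear
#' resonance scaling introduces no spatial bias.
#'
#' @param barcode A [build_target_barcode()] with 49 designs (any size works;
#'   slots scale accordingly).
#' @param extra_designs List of exactly 2 extra [metapixel_design()];
#'   defaults to [default_extra_designs()].
#' @param seed Integer seed of the random permutation (Fisher-Yates via
#'   `sample()`); the layout is reproducible from it.
#' @return A `physical_layout`: list with `slots` data.frame (`slot`
#'   0-based row-major, `row`, `col`, `design_id`), `designs` (all designs
#'   indexed by id, extras included), `extras` (2 design ids), `shape`,
#'   `seed`.
#' @export
double_and_randomize <- function(barcode, extra_designs = NULL, seed = 0) {
  stopifnot(inherits(barcode, "target_barcode"))
  if (is.null(extra_designs)) extra_designs <- default_extra_designs(barcode)
  if (length(extra_designs) != 2) {
    stop("double_and_randomize: exactly 2 extra designs are required")
  }
  n <- length(barcode$designs)
  ids <- vapply(barcode$designs, function(d) d$design_id, integer(1))
  extra_ids <- vapply(extra_designs, function(d) d$design_id, integer(1))
  if (any(extra_ids %in% ids)) {
    stop("double_and_randomize: extra design ids collide with barcode ids")
  }
  pool <- c(rep(ids, each = 2), extra_ids)
  n_slots <- length(pool)
  side <- sqrt(n_slots)
  if (side != round(side)) stop("double_and_randomize: slot count must be square")
  perm <- with_local_seed(seed, sample.int(n_slots))
  assigned <- pool[perm]
  slot <- seq_len(n_slots) - 1L
  slots <- data.frame(
    slot = slot,
    row = slot %/% as.integer(side),
    col = slot %% as.integer(side),
    design_id = assigned
  )
  designs <- c(barcode$designs, extra_designs)
  names(designs) <- vapply(designs, function(d) as.character(d$design_id), "")
  structure(list(slots = slots, designs = designs, extras = extra_ids,
                 shape = c(side, side), seed = seed),
            class = "physical_layout")
}

## run expr under a given RNG seed without disturbing the caller's RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Invert a physical layout
#'
#' @param layout A [double_and_randomize()] result.
#' @return Named list mapping `design_id` to the vector of 0-based slot
#'   positions holding that design (2 for doubled designs, 1 for extras).
#' @export
design_index <- function(layout) {
  stopifnot(inherits(layout, "physical_layout"))
  split(layout$slots$slot, layout$slots$design_id)
}

#' Write / read a physical layout as JSON
#'
#' Lossless round-trip of the layout (designs, slots, extras, seed).
#' @param layout A `physical_layout`.
#' @param path File path.
#' @return `read_layout` returns a `physical_layout`.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "physical_layout"))
  obj <- list(
    shape = layout$shape, seed = layout$seed, extras = layout$extras,
    slots = layout$slots,
    designs = lapply(unname(layout$designs), function(d) {
      list(design_id = d$design_id, nu0 = d$nu0, Q = d$Q,
           amplitude = d$amplitude, scale_S = d$scale_S)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  designs <- lapply(seq_len(nrow(obj$designs)), function(i) {
    d <- obj$designs[i, ]
    metapixel_design(d$design_id, d$nu0, Q = d$Q, amplitude = d$amplitude,
                     scale_S = d$scale_S)
  })
  names(designs) <- vapply(designs, function(d) as.character(d$design_id), "")
  slots <- obj$slots
  slots$slot <- as.integer(slots$slot)
  slots$design_id <- as.integer(slots$design_id)
  structure(list(slots = slots, designs = designs,
                 extras = as.integer(obj$extras),
                 shape = as.numeric(obj$shape), seed = obj$seed),
            class = "physical_layout")
}
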