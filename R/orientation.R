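#' Orientation arithmetic on the 180-degree circle
#'
#' Ellipse orientations are axial: an orientation and its rotation by 180
#' degrees are the same stimulus. All orientations in this package live in
#' the half-open interval (-90, 90] and differences are taken along the
#' shortest axial arc. When successive quantities are within 90 degrees of
#' each other (always the case at the category and walk scales used here),
#' these operations coincide with plain linear arithmetic.
#'
#' @param x numeric vector of orientations in degrees.
#' @return `wrap_orientation()` returns `x` mapped into (-90, 90].
#' @examples
#' wrap_orientation(c(-90, 95, 180))
#' arc_diff(80, -80) # shortest arc, not 160
#' @export
wrap_orientation <- function(x) {
  x - 180 * ceiling((x - 90) / 180)
}

#' @rdname wrap_orientation
#' @param from,to orientations in degrees.
#' @return `arc_diff()` returns the signed shortest-arc difference
#'   `to - from` in (-90, 90].
#' @export
arc_diff <- function(to, from) {
  wrap_orientation(to - from)
}

#' @rdname wrap_orientation
#' @return `unwrap_orientation()` returns a continuous (unbounded) version of
#'   the series `x`, reconstructed by accumulating shortest-arc increments.
#'   Used to linearize wrapped series (e.g. random-walk means) before
#'   correlation or regression.
#' @export
unwrap_orientation <- function(x) {
  if (length(x) < 2) return(x)
  x[1] + c(0, cumsum(arc_diff(x[-1], x[-length(x)])))
}
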