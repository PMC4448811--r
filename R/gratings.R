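#' Sine-grating stimulus specification
#'
#' @param frequency Spatial frequency in cycles per degree; must be positive
#'   and below the Nyquist limit of the target image.
#' @param orientation Grating orientation in degrees. 0 is a vertical grating
#'   (luminance varies horizontally), the default used in replication runs.
#' @param phase Phase in degrees at the image centre.
#' @param contrast Michelson contrast in `[0, 1]`.
#' @param mean_luminance Mean luminance in the same (arbitrary linear) units
#'   as the output pixels.
#'
#' @return A `grating_spec` list.
#' @export
grating_spec <- function(frequency, orientation = 0, phase = 0,
                         contrast = 1, mean_luminance = 128) {
  if (!is.numeric(frequency) || length(frequency) != 1L || frequency <= 0) {
    stop("`frequency` must be a single positive number (c/deg)")
  }
  if (contrast < 0 || contrast > 1) stop("`contrast` must lie in [0, 1]")
  structure(
    list(
      frequency = frequency, orientation = orientation, phase = phase,
      contrast = contrast, mean_luminance = mean_luminance
    ),
    class = "grating_spec"
  )
}

#' Generate a sine-grating image
#'
#' Produces `L0 * (1 + c * cos(2 pi f x_theta + phase))` on a square pixel
#' grid, where `x_theta` is the coordinate (in degrees, measured from the
#' image centre) along the axis orthogonal to the grating's stripes.
#'
#' @param spec A [grating_spec()].
#' @param size Image side length in pixels (1024 for replication runs).
#' @param resolution Pixels per degree (60 for replication runs: one pixel
#'   per arcmin).
#' @return A [stimulus_image].
#' @export
#' @examples
#' g <- make_grating(grating_spec(4), size = 256)
#' range(g$pixels)
make_grating <- function(spec, size = 1024, resolution = 60) {
  stopifnot(inherits(spec, "grating_spec"), size > 0)
  if (spec$frequency >= resolution / 2) {
    stop(sprintf(
      "grating frequency %.3g c/deg is at or above the Nyquist limit %.3g c/deg",
      spec$frequency, resolution / 2
    ))
  }
  centre <- (size + 1) / 2
  coord <- (seq_len(size) - centre) / resolution # degrees
  th <- spec$orientation * pi / 180
  # matrix row = y, column = x; x_theta = x cos(th) - y sin(th)
  xt <- outer(-coord * sin(th), coord * cos(th), `+`)
  ph <- spec$phase * pi / 180
  px <- spec$mean_luminance *
    (1 + spec$contrast * cos(2 * pi * spec$frequency * xt + ph))
  stimulus_image(px, resolution,
    id = sprintf("grating_f%.3g_or%g", spec$frequency, spec$orientation)
  )
}
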