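#' Calibrated luminance image
#'
#' The common currency of the pipeline: a square 2-D luminance array together
#' with its spatial calibration in pixels per degree of visual angle. Paper
#' replication runs use 1024 x 1024 images at 60 px/deg (one pixel per arcmin),
#' so a 1024-px image spans about 17 degrees.
#'
#' @param pixels Numeric matrix of luminance values (arbitrary linear units).
#' @param resolution Pixels per degree of visual angle. Must be positive.
#' @param id Optional character label carried through to response summaries.
#'
#' @return An object of class `stimulus_image`: a list with elements
#'   `pixels`, `resolution` and `id`.
#' @export
#' @examples
#' img <- stimulus_image(matrix(rnorm(64^2), 64), resolution = 60)
#' nyquist_frequency(img)
stimulus_image <- function(pixels, resolution = 60, id = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix")
  }
  if (!all(is.finite(pixels))) {
    stop("all pixel values must be finite")
  }
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0) {
    stop("`resolution` must be a single positive number (pixels per degree)")
  }
  structure(
    list(pixels = pixels, resolution = as.numeric(resolution), id = id),
    class = "stimulus_image"
  )
}

#' @export
print.stimulus_image <- function(x, ...) {
  cat(sprintf(
    "<stimulus_image> %d x %d px, %.4g px/deg (%.3g x %.3g deg)%s\n",
    nrow(x$pixels), ncol(x$pixels), x$resolution,
    nrow(x$pixels) / x$resolution, ncol(x$pixels) / x$resolution,
    if (is.null(x$id)) "" else paste0(", id: ", x$id)
  ))
  cat(sprintf(
    "  luminance range [%.4g, %.4g], mean %.4g\n",
    min(x$pixels), max(x$pixels), mean(x$pixels)
  ))
  invisible(x)
}

#' @rdname stimulus_image
#' @param x Object to test or query.
#' @export
is_stimulus_image <- function(x) inherits(x, "stimulus_image")

#' @rdname stimulus_image
#' @export
nyquist_frequency <- function(x) {
  res <- if (is_stimulus_image(x)) x$resolution else as.numeric(x)
  res / 2
}

as_stimulus_image <- function(x, resolution = 60) {
  if (is_stimulus_image(x)) x else stimulus_image(as.matrix(x), resolution)
}

#' FFT frequency lattice in cycles per degree
#'
#' Frequencies follow the standard DFT layout: bin k of an n-point transform
#' carries k/n cycles per pixel for k <= n/2 and (k - n)/n beyond (half-open
#' Nyquist convention: for even n the n/2 bin is assigned +n/2). Multiplying
#' by the resolution converts cycles/pixel to cycles/degree.
#'
#' @param n Number of samples along one image axis.
#' @param resolution Pixels per degree.
#' @return Numeric vector of length `n`, signed frequencies in c/deg.
#' @export
fft_frequencies <- function(n, resolution = 60) {
  k <- seq_len(n) - 1L
  k <- ifelse(k <= n / 2, k, k - n)
  k / n * resolution
}

#' Radial frequency of every FFT bin
#'
#' @param n Image side length in pixels.
#' @param resolution Pixels per degree.
#' @return An `n` x `n` matrix of radial spatial frequencies (c/deg); the
#'   `[1, 1]` element is the DC bin (0 c/deg).
#' @export
radial_frequency_grid <- function(n, resolution = 60) {
  f <- fft_frequencies(n, resolution)
  sqrt(outer(f^2, f^2, `+`))
}

#' Radially averaged Fourier amplitude spectrum
#'
#' Averages `|FFT(image)|` over annuli of width one frequency-lattice step.
#' Used by the spectral-slope diagnostics and the filtered-noise tests.
#'
#' @param image A [stimulus_image] or numeric matrix.
#' @param resolution Pixels per degree (ignored when `image` is calibrated).
#' @return A data.frame with columns `frequency` (annulus centre, c/deg),
#'   `amplitude` (mean amplitude) and `n_bins` (bins in the annulus). The DC
#'   bin is excluded.
#' @export
radial_amplitude_spectrum <- function(image, resolution = 60) {
  img <- as_stimulus_image(image, resolution)
  n <- nrow(img$pixels)
  amp <- Mod(stats::fft(img$pixels))
  fr <- radial_frequency_grid(n, img$resolution)
  step <- img$resolution / n
  ring <- as.integer(round(fr / step))
  keep <- ring > 0L
  mean_amp <- tapply(amp[keep], ring[keep], mean)
  counts <- tapply(amp[keep], ring[keep], length)
  idx <- as.integer(names(mean_amp))
  data.frame(
    frequency = idx * step,
    amplitude = as.numeric(mean_amp),
    n_bins = as.integer(counts),
    row.names = NULL
  )
}

#' Log-log slope of the radial amplitude spectrum
#'
#' Fits `log(amplitude) ~ log(frequency)` over a frequency band by ordinary
#' least squares. For a 1/f^beta image the slope estimates -beta.
#'
#' @param image A [stimulus_image] or matrix.
#' @param f_range Frequency band (c/deg) used in the fit; defaults to
#'   0.5 c/deg up to half the Nyquist frequency, which avoids the sparsely
#'   populated lowest annuli and the anisotropic corner bins.
#' @param resolution Pixels per degree for uncalibrated input.
#' @return The fitted slope (a single number).
#' @export
spectral_slope <- function(image, f_range = NULL, resolution = 60) {
  img <- as_stimulus_image(image, resolution)
  if (is.null(f_range)) f_range <- c(0.5, nyquist_frequency(img) / 2)
  spec <- radial_amplitude_spectrum(img)
  spec <- spec[spec$frequency >= f_range[1] & spec$frequency <= f_range[2] &
    spec$amplitude > 0, ]
  if (nrow(spec) < 3L) stop("too few spectral bins in `f_range` to fit a slope")
  unname(stats::coef(stats::lm(log(amplitude) ~ log(frequency), data = spec))[2])
}

# Multiply an image's Fourier transform by a real radial gain and return the
# real inverse transform. `gain` is a full n x n matrix aligned with the FFT
# layout; gain[1, 1] applies to DC. Radial symmetry of the gain keeps the
# output real up to rounding, so taking Re() is exact in expectation.
apply_fourier_gain <- function(pixels, gain) {
  stopifnot(all(dim(pixels) == dim(gain)))
  ft <- stats::fft(pixels) * gain
  Re(stats::fft(ft, inverse = TRUE)) / length(pixels)
}
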