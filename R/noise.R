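#' Raised radial cosine spectral gain
#'
#' The band-pass gain used to put a spectral peak at a chosen centre
#' frequency. Working in the log-frequency domain with `d = |log f - log f0|`
#' (logarithm base selectable), the gain has three branches:
#'
#' * flat pass band: `H = T` for `d <= (1 - beta) / (2 T)`;
#' * raised-cosine transition:
#'   `H = (T / 2) * (1 + cos((pi * T / beta) * (d - (1 - beta) / (2 T))))`
#'   for `(1 - beta) / (2 T) <= d <= (1 + beta) / (2 T)`;
#' * stop band: `H = 0` beyond.
#'
#' With the default `T = 0.9` the gain at the centre frequency is 0.9, and at
#' the transition midpoint `d = 1 / (2 T)` it is exactly `T / 2`.
#'
#' @param f Spatial frequency (c/deg); vectorized. Must be positive.
#' @param f0 Centre frequency of the peak (c/deg).
#' @param T Pass-band height (and bandwidth scale), in (0, 1]. Default 0.9.
#' @param beta_roll Roll-off factor in `[0, 1]`. Default 0.5.
#' @param log_base Base of the logarithm defining the band; `exp(1)`
#'   (natural, the default) or any base > 1. The base only rescales the
#'   band's width in octaves.
#' @return Gain values in `[0, T]`, same length as `f`.
#' @export
#' @examples
#' raised_cosine_gain(3, 3) # pass band: 0.9
#' raised_cosine_gain(3 * exp(1 / 1.8), 3) # transition midpoint: 0.45
raised_cosine_gain <- function(f, f0, T = 0.9, beta_roll = 0.5,
                               log_base = exp(1)) {
  if (any(f <= 0)) stop("`f` must be positive: the log-frequency axis is undefined at f <= 0")
  if (f0 <= 0) stop("`f0` must be positive")
  if (T <= 0 || T > 1) stop("`T` must lie in (0, 1]")
  if (beta_roll < 0 || beta_roll > 1) stop("`beta_roll` must lie in [0, 1]")
  d <- abs(log(f, base = log_base) - log(f0, base = log_base))
  flat_edge <- (1 - beta_roll) / (2 * T)
  stop_edge <- (1 + beta_roll) / (2 * T)
  h <- numeric(length(d))
  pass <- d <= flat_edge
  trans <- !pass & d <= stop_edge
  h[pass] <- T
  h[trans] <- (T / 2) * (1 + cos((pi * T / beta_roll) * (d[trans] - flat_edge)))
  h
}

#' Filtered-noise stimulus specification
#'
#' Parameters of the spectrally shaped noise stimuli: Gaussian white noise
#' whose Fourier amplitudes are reshaped to a 1/f profile carrying a raised
#' radial cosine peak at `frequency`.
#'
#' @param frequency Centre frequency of the spectral peak (c/deg).
#' @param T Raised-cosine pass-band height, default 0.9.
#' @param beta_roll Raised-cosine roll-off factor, default 0.5.
#' @param log_base Logarithm base for the raised cosine (see
#'   [raised_cosine_gain()]).
#' @param peak_mode How the peak combines with the 1/f background:
#'   `"literal"` multiplies (amplitude proportional to `(1/f) * H(f)`, zero
#'   outside the cosine band); `"additive"` keeps the background (amplitude
#'   proportional to `(1/f) * (1 + H(f))`).
#' @param seed RNG seed making the stimulus reproducible.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(frequency, T = 0.9, beta_roll = 0.5,
                       log_base = exp(1), peak_mode = c("literal", "additive"),
                       seed = 1L) {
  if (!is.numeric(frequency) || length(frequency) != 1L || frequency <= 0) {
    stop("`frequency` must be a single positive number (c/deg)")
  }
  if (T <= 0 || T > 1) stop("`T` must lie in (0, 1]")
  if (beta_roll < 0 || beta_roll > 1) stop("`beta_roll` must lie in [0, 1]")
  structure(
    list(
      frequency = frequency, T = T, beta_roll = beta_roll,
      log_base = log_base, peak_mode = match.arg(peak_mode),
      seed = as.integer(seed)
    ),
    class = "noise_spec"
  )
}

#' Generate a spectrally shaped noise image
#'
#' Draws pixelwise Gaussian white noise, then multiplies its Fourier
#' transform by the radial gain `(1/f) * H(f)` (or `(1/f) * (1 + H(f))` in
#' additive mode), where `H` is the raised radial cosine peak at the spec's
#' centre frequency. The DC gain is 1, so the (near-zero) sample mean of the
#' white noise is preserved; downstream use rescales luminance anyway. The
#' output is deterministic given the spec's seed.
#'
#' @param spec A [noise_spec()].
#' @param size Image side length in pixels.
#' @param resolution Pixels per degree.
#' @return A [stimulus_image].
#' @export
make_filtered_noise <- function(spec, size = 1024, resolution = 60) {
  stopifnot(inherits(spec, "noise_spec"), size > 0)
  if (spec$frequency >= resolution / 2) {
    stop("noise centre frequency must be below the Nyquist limit")
  }
  white <- withr::with_seed(
    spec$seed,
    matrix(stats::rnorm(size^2), size, size)
  )
  gain <- noise_spectral_gain(spec, size, resolution)
  px <- apply_fourier_gain(white, gain)
  stimulus_image(px, resolution,
    id = sprintf("noise_f%.3g_seed%d", spec$frequency, spec$seed)
  )
}

# The full n x n Fourier gain matrix for a noise spec (DC bin = 1).
noise_spectral_gain <- function(spec, size, resolution) {
  fr <- radial_frequency_grid(size, resolution)
  gain <- matrix(0, size, size)
  nz <- fr > 0
  h <- raised_cosine_gain(fr[nz], spec$frequency, spec$T, spec$beta_roll,
    log_base = spec$log_base
  )
  gain[nz] <- switch(spec$peak_mode,
    literal = h / fr[nz],
    additive = (1 + h) / fr[nz]
  )
  gain[1, 1] <- 1
  gain
}

#' Natural-image surrogate specification
#'
#' Natural scenes have Fourier amplitude falling off as roughly 1/f^beta with
#' beta between 0.8 and 1.2. The surrogate generator emulates that second-
#' order structure with Gaussian noise shaped to an exact 1/f^beta radial
#' amplitude profile; it carries none of the higher-order structure (edges,
#' objects, phase alignment) of real photographs.
#'
#' @param beta Spectral exponent; must lie in `[0.5, 2]`. If `NULL`
#'   (default), a value is drawn uniformly from `[0.8, 1.2]` using `seed`.
#' @param seed RNG seed (drives both the optional beta draw and the noise).
#' @return A `surrogate_spec` list with a concrete `beta`.
#' @export
surrogate_spec <- function(beta = NULL, seed = 1L) {
  seed <- as.integer(seed)
  if (is.null(beta)) {
    beta <- withr::with_seed(seed, stats::runif(1, 0.8, 1.2))
  }
  if (beta < 0.5 || beta > 2) stop("`beta` must lie in [0.5, 2]")
  structure(list(beta = beta, seed = seed), class = "surrogate_spec")
}

#' Generate a 1/f^beta natural-image surrogate
#'
#' @param spec A [surrogate_spec()].
#' @param size Image side length in pixels.
#' @param resolution Pixels per degree.
#' @return A [stimulus_image] whose radially averaged amplitude spectrum
#'   falls off as `f^-beta` (exactly, up to the white-noise scatter).
#' @export
#' @examples
#' s <- make_surrogate_natural(surrogate_spec(beta = 1, seed = 7), size = 256)
#' spectral_slope(s) # close to -1
make_surrogate_natural <- function(spec, size = 1024, resolution = 60) {
  stopifnot(inherits(spec, "surrogate_spec"), size > 0)
  white <- withr::with_seed(
    spec$seed + 1L, # distinct stream from the beta draw
    matrix(stats::rnorm(size^2), size, size)
  )
  fr <- radial_frequency_grid(size, resolution)
  gain <- matrix(1, size, size)
  nz <- fr > 0
  gain[nz] <- fr[nz]^(-spec$beta)
  px <- apply_fourier_gain(white, gain)
  stimulus_image(px, resolution,
    id = sprintf("surrogate_b%.3g_seed%d", spec$beta, spec$seed)
  )
}

#' Rescale luminance to the display range
#'
#' Affine map of pixel values so the minimum becomes 1 and the maximum 255,
#' the luminance range used before (optional) contrast-sensitivity
#' prefiltering. A constant image has no contrast to preserve and maps to the
#' midpoint 128 by convention.
#'
#' @param image A [stimulus_image].
#' @return A [stimulus_image] with pixels in `[1, 255]`.
#' @export
rescale_luminance <- function(image) {
  img <- as_stimulus_image(image)
  rng <- range(img$pixels)
  if (diff(rng) == 0) {
    img$pixels[] <- 128
  } else {
    img$pixels <- 1 + (img$pixels - rng[1]) * (254 / diff(rng))
  }
  img
}
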