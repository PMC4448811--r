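#' Tuning distributions for the neuron population
#'
#' Discrete sampling distributions over preferred spatial frequency,
#' orientation and phase, each given as a two-column table (bin centre,
#' probability). Probabilities are renormalized to sum to 1; negative
#' entries, empty tables or all-zero probabilities are rejected.
#'
#' @param frequency Data frame with columns `value` (c/deg, inside
#'   `(0, Nyquist)`) and `probability`.
#' @param orientation Data frame over `[0, 180)` degrees.
#' @param phase Data frame over `[0, 360)` degrees.
#' @return A `tuning_distributions` object.
#' @seealso [default_tuning_distributions()] for the physiology-shaped
#'   tables shipped with the package.
#' @export
tuning_distributions <- function(frequency, orientation, phase) {
  structure(
    list(
      frequency = check_tuning_table(frequency, "frequency"),
      orientation = check_tuning_table(orientation, "orientation"),
      phase = check_tuning_table(phase, "phase")
    ),
    class = "tuning_distributions"
  )
}

check_tuning_table <- function(tab, what) {
  tab <- as.data.frame(tab)
  if (ncol(tab) < 2L) stop(what, " table needs two columns (value, probability)")
  names(tab)[1:2] <- c("value", "probability")
  tab <- tab[, 1:2]
  if (nrow(tab) == 0L) stop(what, " distribution table is empty")
  if (any(!is.finite(tab$value)) || any(!is.finite(tab$probability))) {
    stop(what, " table contains non-finite entries")
  }
  if (any(tab$probability < 0)) stop(what, " probabilities must be non-negative")
  tot <- sum(tab$probability)
  if (tot <= 0) stop(what, " distribution cannot be normalized (all-zero probabilities)")
  if (what == "frequency" && any(tab$value <= 0)) {
    stop("frequency bins must be positive")
  }
  tab$probability <- tab$probability / tot
  tab
}

#' Physiology-shaped default tuning distributions
#'
#' Loads the three tables shipped under `extdata/`: a unimodal log-domain
#' histogram of preferred spatial frequency over 0.35-11.3 c/deg with its
#' mode in the 2-6 c/deg midrange (foveal single-cell surveys concentrate
#' there, with very few cells below 1 c/deg); an orientation histogram with
#' a cardinal bias (horizontal and vertical over-represented relative to
#' obliques); and a phase histogram concentrated near 0, 90, 180 and 270
#' degrees (even- and odd-symmetric receptive fields). The tables are plain
#' CSV and can be replaced by digitized recordings without code changes.
#'
#' @return A [tuning_distributions()] object.
#' @export
default_tuning_distributions <- function() {
  path <- function(f) system.file("extdata", f, package = "gaborpop", mustWork = TRUE)
  tuning_distributions(
    frequency = utils::read.csv(path("frequency_tuning.csv")),
    orientation = utils::read.csv(path("orientation_tuning.csv")),
    phase = utils::read.csv(path("phase_tuning.csv"))
  )
}

#' Sample neuron tunings from distributions
#'
#' Draws `n` independent (frequency, orientation, phase) triples from the
#' discrete tables and derives the envelope widths from the frequency via
#' [envelope_sigma()]. Receptive-field locations are left unset; the
#' placement layer assigns them.
#'
#' @param dist A [tuning_distributions()].
#' @param n Number of neurons.
#' @param seed RNG seed; the draw is bit-reproducible given the seed.
#' @param envelope_mode Passed to [envelope_sigma()].
#' @return A data.frame (class `neuron_tunings`) with columns `frequency`,
#'   `orientation`, `phase`, `sigma1`, `sigma2`, `gain`.
#' @export
sample_tunings <- function(dist, n, seed = 1L, envelope_mode = "bandwidth") {
  stopifnot(inherits(dist, "tuning_distributions"), n >= 1)
  draw_from <- function(tab) {
    tab$value[sample.int(nrow(tab), n, replace = TRUE, prob = tab$probability)]
  }
  draws <- withr::with_seed(as.integer(seed), {
    list(
      f = draw_from(dist$frequency),
      th = draw_from(dist$orientation),
      ph = draw_from(dist$phase)
    )
  })
  s <- envelope_sigma(draws$f, envelope_mode)
  out <- data.frame(
    frequency = draws$f, orientation = draws$th, phase = draws$ph,
    sigma1 = s$sigma1, sigma2 = s$sigma2, gain = 1
  )
  class(out) <- c("neuron_tunings", class(out))
  out
}

#' The original fixed filter-bank configuration
#'
#' The classic sparse-coding filter bank: two spatial frequencies given in
#' cycles per image, four orientations and two phases — 16 tuning
#' combinations in all.
#'
#' @param frequencies_cpi Frequencies in cycles per image.
#' @param orientations Orientations in degrees.
#' @param phases Phases in degrees.
#' @return A `field_configuration` list.
#' @export
field_configuration <- function(frequencies_cpi = c(20, 40),
                                orientations = c(10, 55, 100, 145),
                                phases = c(0, 90)) {
  structure(
    list(
      frequencies_cpi = frequencies_cpi,
      orientations = orientations, phases = phases
    ),
    class = "field_configuration"
  )
}

#' Expand the fixed configuration into neuron tunings
#'
#' Forms the full cross product of the configuration grid and converts
#' cycles per image to cycles per degree via the image calibration:
#' `f[c/deg] = f[cycles/image] * resolution / size`.
#'
#' @param config A [field_configuration()].
#' @param size Image side length in pixels.
#' @param resolution Pixels per degree.
#' @param envelope_mode Passed to [envelope_sigma()].
#' @return A `neuron_tunings` data.frame with one row per combination (16
#'   for the default grid).
#' @export
field_tunings <- function(config = field_configuration(), size = 1024,
                          resolution = 60, envelope_mode = "bandwidth") {
  stopifnot(inherits(config, "field_configuration"))
  grid <- expand.grid(
    frequency_cpi = config$frequencies_cpi,
    orientation = config$orientations,
    phase = config$phases,
    KEEP.OUT.ATTRS = FALSE
  )
  f <- grid$frequency_cpi * resolution / size
  s <- envelope_sigma(f, envelope_mode)
  out <- data.frame(
    frequency = f, orientation = grid$orientation, phase = grid$phase,
    sigma1 = s$sigma1, sigma2 = s$sigma2, gain = 1
  )
  class(out) <- c("neuron_tunings", class(out))
  out
}
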