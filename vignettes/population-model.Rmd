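---
title: "A Gabor population model of V1 responses to uncomfortable and natural images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Gabor population model of V1 responses to uncomfortable and natural images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Natural scenes have stereotyped second-order statistics: their Fourier
amplitude falls off with radial spatial frequency roughly as $1/f^\beta$ with
$\beta \approx 0.8$–$1.2$. A visual system tuned to encode such inputs
sparsely — strong activity in few neurons, near-silence in the rest — will
respond *non*-sparsely to images whose spectra deviate from that regularity.
Striped patterns and band-boosted noise with excess energy in the midrange
(a few cycles per degree) are exactly the images people report as
uncomfortable to view, and this package implements a population model of
primary visual cortex that makes the connection quantitative: midrange
stimuli evoke larger, less sparse population responses than natural images.

`gaborpop` generates all stimuli internally, simulates the population
response, and scores each stimulus by two statistics of the response vector
$r_1,\dots,r_n$ across neurons:

* **total magnitude** $\sum_i |r_i|$ (equivalently $n \cdot
  \mathrm{mean}|r|$), the overall drive on the population — and a proxy for
  metabolic load;
* **population excess kurtosis** $m_4/m_2^2 - 3$ (central sample moments, no
  small-sample correction): 0 for a Gaussian response profile, large and
  positive when most neurons sit near zero and a few respond strongly, i.e.
  when the response is sparse. This is population sparseness — one stimulus,
  many neurons — not lifetime sparseness.

## Stimuli

All stimuli are 1024 × 1024 luminance arrays at 60 pixels per degree (one
pixel per arcmin), carried by the `stimulus_image` container together with
their calibration.

**Gratings.** `make_grating()` produces
$L_0\,(1 + c\cos(2\pi f x_\theta + \phi))$. The replication grid spans
0.25–12 c/deg. Orientation is a free parameter; replication runs use
vertical gratings (the choice is not load-bearing: the model's orientation
distribution is applied to the neurons, and the statistics are computed over
random phase/position draws).

**Filtered noise.** `make_filtered_noise()` reshapes the Fourier amplitudes
of Gaussian white noise to a $1/f$ profile carrying a raised radial cosine
peak $H(f)$ at a centre frequency $f_0$ (`raised_cosine_gain()`). In
log-frequency units $d = |\log f - \log f_0|$ the gain is $T$ (= 0.9) on a
flat pass band $d \le (1-\beta_r)/(2T)$, falls as a raised cosine to zero at
$d = (1+\beta_r)/(2T)$, and is zero beyond ($\beta_r = 0.5$ is the
roll-off). Two compositions of "$1/f$ with a peak" are implemented, because
the phrase is genuinely ambiguous: the default multiplies the $1/f$
background by $H$ (band-limited noise, the literal reading of
"multiplication with a raised radial cosine filter"); `peak_mode =
"additive"` uses $1/f \cdot (1 + H)$, which keeps the background and adds a
bump. The logarithm base is likewise unstated in the source formulation;
natural log is the default and `log_base` exposes the choice — the base only
rescales the band's width in octaves (about 2.4 octaves between stop edges
under natural log, much wider under base 10). The DC bin keeps gain 1 so the
sample mean survives; luminance is rescaled downstream anyway.

**Natural-image surrogates.** The model's "natural" baseline uses Gaussian
noise shaped to an exact $1/f^\beta$ radial amplitude spectrum, with $\beta$
drawn uniformly from $[0.8, 1.2]$ per image (`make_surrogate_natural()`).
This emulates the second-order structure of photographs and nothing else:
no edges, no objects, no phase alignment, and — being Gaussian — none of the
higher-order sparseness real scenes carry. Consequences are discussed under
*What the surrogates can and cannot show*. A reader for a classic
calibrated-photograph raw format (`read_raw_luminance()`) and generic
PNG/PGM I/O are provided for scoring real images; nothing in the build or
tests requires a download.

**Luminance.** Every stimulus is affinely rescaled to $[1, 255]$
(`rescale_luminance()`) before any filtering; a constant image maps to the
midpoint 128 by convention (there is no contrast to preserve).

## Pre-cortical filtering

Human contrast sensitivity is band-pass in spatial frequency. Simulation 2
prefilters stimuli by a radial contrast-sensitivity function (CSF); the
published source for the model's CSF gives no closed form, so the package
ships a standard two-branch parametric family

$$\mathrm{gain}(f) \propto (a + b f)\, e^{-(c f)^d},$$

normalized to unit peak, defaulting to $a = 0.05$, $b = 1$, $c = 1/3.5$,
$d = 1$, which places the peak at $b/c - a = 3.45$ c/deg — inside the 3–4
c/deg band the discomfort literature points to — with sensitivity at 0.25
and 12 c/deg at roughly 20–30% of peak, as any plausible photopic CSF has.
The family, not its parameter values, is the contract: everything is
swappable through `csf_model()`, and the pipeline only assumes
non-negativity and band-pass shape. The DC bin is preserved so mean
luminance is untouched. Simulation 3 bypasses the filter entirely; the
with/without contrast isolates how much of the tuning of the population
response comes from pre-cortical attenuation versus the cortical tuning
distribution.

The CSF is applied after luminance rescaling, matching the pipeline order
stimulus → CSF → cortical filtering.

## Model neurons

Each neuron is a Gabor receptive field

$$G(x, y) = A \exp\!\left(-\frac{x_p^2}{2\sigma_1^2} -
\frac{y_p^2}{2\sigma_2^2}\right) \cos(2\pi f x_p + \phi),$$

with $x_p = x\cos\theta - y\sin\theta$, $y_p = x\sin\theta + y\cos\theta$:
preferred frequency $f$, orientation $\theta$, phase $\phi$, and an
elliptical Gaussian envelope elongated 2:1 parallel to the preferred
orientation. A neuron's response is the inner product of its weights with
the image patch under its $\pm 3\sigma_2$ support, at a location drawn
uniformly over all positions where the support fits inside the image.

Two design choices here were genuinely open:

**Envelope constants.** The classical constants $\sigma_1 = 7.81/f$,
$\sigma_2 = 15.61/f$ come without units, and no unit reading we tried
reproduces the stated 1.4-octave frequency bandwidth. The default therefore
parametrizes the envelope directly by what is physiologically stated —
bandwidth 1.4 octaves and 2:1 aspect — giving $\sigma_1 = 0.41605/f$ deg
(with $f$ in c/deg) and $\sigma_2 = 2\sigma_1$; receptive fields are
self-similar across frequency ($\sigma f$ constant). The literal constants
remain available (`envelope_mode = "literal"`, read in arcmin, equivalently
pixels on the 1-px-per-arcmin grid); their 15.61/7.81 = 1.9987 elongation
is what the acceptance geometry check measures.

**Normalization.** $A$ is unspecified in the source formulation. With raw
$A = 1$ weights, response magnitude scales with envelope area ($\propto
1/f^2$), so low-frequency neurons would dominate the population magnitude
for reasons that have nothing to do with the stimulus. The default
post-processes each receptive field to zero mean and unit energy (sum of
squares 1), making cross-frequency magnitude comparisons reflect stimulus
content and removing the spurious DC response of cosine-phase Gabors; `
normalize = "raw"` keeps the literal field for comparison.

**Tuning distributions.** The population's tunings are drawn from discrete
histograms (plain CSV tables under `extdata/`, replaceable without code
changes):

* *frequency*: a unimodal log-domain histogram over 0.35–11.3 c/deg with
  mode at 2.8 c/deg and 49% of its mass in the 2–6 c/deg midrange, the
  shape foveal single-cell surveys report, with very few cells below
  1 c/deg. The lowest bin is 0.35 c/deg because a neuron preferring
  0.25 c/deg would need a ±3σ₂ support of ~1200 px under the 1.4-octave
  envelope rule — larger than the 1024-px stimulus itself — so such
  neurons cannot be placed; 0.35 c/deg (support 857 px) is the smallest
  preferred frequency whose full support fits.
* *orientation*: cardinal bias — 0° and 90° over-represented (0.16 each)
  relative to obliques (0.06);
* *phase*: concentrated near 0°, 90°, 180°, 270° (0.17 each), the even- and
  odd-symmetric receptive-field types.

The comparison model is the classic fixed bank: 20 and 40 cycles per image
(1.17 and 2.34 c/deg at the replication geometry), orientations
{10°, 55°, 100°, 145°}, phases {0°, 90°} — 16 tunings, recycled uniformly
across the population.

## Simulations and their scales

`run_simulation()` executes, per stimulus: generate → rescale to [1, 255] →
optional CSF → sample tunings → place → respond → summarize. All randomness
derives from the single master seed in the config, so a config plus seed
reproduces every number bit-for-bit. Default scales in the shipped analyses
and tests: 20 000 neurons per stimulus, 10 noise instances per centre
frequency, a 9-point frequency grid {0.25, 0.5, 1, 2, 3, 4, 6, 8, 12} c/deg
(the coarse stimulus grid plus 3 and 6 c/deg, so midrange extrema land on a
grid point), and 10–20 surrogate images for baselines. The full-scale
250 000-neuron configuration is one argument away; the extremum locations
stabilize far below it, the larger population only narrows error bars.
Reduced problem sizes were chosen so each analysis completes in minutes on
one CPU core.

`compare_models()` runs the paired first simulation: both models score the
same images at identical receptive-field locations per neuron index (each
location drawn uniformly over positions valid for the larger of the two
supports at that index), so the contrast is free of placement noise.

The population inner loop is compiled (Rcpp). It evaluates the Gabor factors
by multiplicative recurrences along each patch column — the Gaussian
exponent changes by an affine step, the carrier phase by a constant — so the
scan needs no per-pixel transcendentals; drift over a ≤1700-pixel column is
near $10^{-13}$ relative. The plain-R path (`gabor_weights()` +
`neuron_response()`) evaluates `exp`/`cos` directly and the test suite holds
the two paths together at $10^{-10}$, alongside a from-scratch brute-force
oracle.

## Numerical conventions

* FFT lattice frequencies in c/deg via `fft_frequencies()`; half-open
  Nyquist convention (for even $n$ the $n/2$ bin is assigned $+n/2$).
  Radial gains are symmetric under $k \mapsto -k$, so inverse transforms of
  filtered real images are real up to rounding and the real part is taken.
* Noise/surrogate DC: gain 1 (the $1/f$ profile is undefined at $f = 0$);
  the white noise's near-zero sample mean passes through.
* Grating frequencies at or above Nyquist are rejected with an explicit
  error; tuning-distribution tables are validated (non-negative, summing to
  1 after renormalization) before any sampling.
* Zero-variance response vectors have no kurtosis and return `NA`; constant
  images rescale to 128.
* Excess-kurtosis calibration: $10^6$ standard-normal draws give 0 ± 0.05,
  $10^6$ Laplace draws give 3 ± 0.1 (closed form), and the statistic is
  invariant to sign and scale of the response vector.

## What the surrogates can and cannot show

The $1/f^\beta$ surrogates are Gaussian random fields. Linear-filter
responses to them are Gaussian *per neuron*; population kurtosis therefore
comes entirely from variance heterogeneity across differently tuned
neurons, not from the heavy-tailed per-neuron statistics real photographs
induce. Two consequences:

* The *directional* model contrast survives: physiology-shaped tunings give
  reliably higher population kurtosis and lower mean absolute response than
  the fixed bank on the same surrogates (10/10 seeded repetitions in the
  shipped analysis, mean-abs ratio ≈ 0.7). The *magnitudes* of the
  published full-scale contrast (excess kurtosis in the hundreds for the
  modified model on photographs) are not reachable with Gaussian
  surrogates and are not asserted anywhere in this package.
* The surrogate baseline's kurtosis is modest, so the "natural images are
  encoded more sparsely than midrange noise" comparison is understated
  here; with real calibrated photographs (via `read_raw_luminance()` or
  `read_image()`) the gap widens.

## Known limitations

* The kurtosis-versus-frequency valley is broad and flat over 2–4 c/deg at
  the shipped conditions: the per-frequency means there differ by only a
  few percent, so the argmin wanders within the valley across seeds — at
  20 000 neurons it lands on 3 or 4 c/deg for both gratings and filtered
  noise, never below. Published full-scale values (3 c/deg for gratings,
  2 c/deg for noise) sit inside or at the edge of the same valley, but
  their exact location depends on the untabulated empirical frequency
  histogram and the unpublished CSF parametrization, neither of which is
  recoverable to the digit; in particular the noise minimum at 2 c/deg is
  not reproduced here. The magnitude peak at 2 c/deg, the result that
  carries the discomfort interpretation, is robust across seeds, scales
  and both stimulus classes.
* No response nonlinearities (rectification, squaring, divisive
  normalization), no orientation- or luminance-dependent CSF, no
  extrastriate stages; responses are noise-free inner products.
* Orientation distribution applies a cardinal bias to cells, but stimuli
  are scored at a single orientation per run.

## Reproducing the numbers

The numbered drivers under `analysis/` run the three simulations at the
documented scales and write their tables under `results/`;
`scripts/acceptance.R --seed <s> --out <path>` recomputes the headline
quantities (raised-cosine gain at centre, tuning-curve extrema, paired
model-comparison outcome) from a fresh seed and writes them as JSON. The
test suite (`testthat`) regenerates every fixture programmatically.
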