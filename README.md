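# gaborpop

A population model of primary visual cortex (V1) for studying why some
images are uncomfortable to look at. The package simulates the responses of
large populations of Gabor model neurons — with spatial-frequency,
orientation and phase tunings drawn from physiology-shaped distributions —
to three stimulus classes it generates internally: sine gratings, noise
with a `1/f` amplitude spectrum carrying a raised radial cosine peak at a
chosen centre frequency, and `1/f^β` Gaussian surrogates for natural
images. Each stimulus is scored by two statistics of the population
response vector:

- **total magnitude** `Σ|rᵢ|` — the overall drive on the population, a
  proxy for metabolic load;
- **population excess kurtosis** `m₄/m₂² − 3` — high when the response is
  sparse (most neurons near zero, a few strong), near zero when it is not.

Each neuron is a Gabor receptive field
`G = A·exp(−x_p²/2σ₁² − y_p²/2σ₂²)·cos(2πf·x_p + φ)` (rotated coordinates
`x_p, y_p`; envelope elongated 2:1 along the preferred orientation;
1.4-octave frequency bandwidth), applied at a random location as an inner
product with the image. The central finding the package reproduces:
stimuli with excess energy at midrange spatial frequencies (a few cycles
per degree) — the ones people judge uncomfortable — drive the model
population harder and less sparsely than natural-image-like inputs, and
the effect peaks at 2 c/deg.

Intended users: vision scientists and computational neuroscientists who
want a self-contained, deterministic reimplementation of this class of
population-response analysis, with every stimulus generator, filter and
statistic exposed and testable.

## Worked example

Score a 3 c/deg filtered-noise stimulus, a 3 c/deg grating, and a
natural-image surrogate with the same 20 000-neuron population (CSF
prefilter on):

```r
library(gaborpop)

tun     <- sample_tunings(default_tuning_distributions(), 20000, seed = 2)
grating <- rescale_luminance(make_grating(grating_spec(3)))
noise   <- rescale_luminance(make_filtered_noise(noise_spec(3, seed = 1)))
surr    <- rescale_luminance(make_surrogate_natural(surrogate_spec(seed = 4)))

rows <- lapply(list(grating, noise, surr), function(img)
  summarize_response(place_and_respond(apply_csf(img), tun, seed = 3)))
do.call(rbind, rows)
#>             stimulus_id     n total_magnitude mean_abs excess_kurtosis
#> 1        grating_f3_or0 20000         4845716   242.29          14.812
#> 2        noise_f3_seed1 20000         1889889    94.49           2.216
#> 3 surrogate_b1.03_seed4 20000         1481578    74.08           2.961
```

The midrange grating drives the population about 3× harder than the
natural-image surrogate (total magnitude 4.8M vs 1.5M); the filtered-noise
stimulus sits between. The spectral peak itself comes from the raised
radial cosine gain, which is 0.9 at its centre frequency, 0.45 at the
transition-band midpoint, and 0 in the stop band:

```r
raised_cosine_gain(c(3, 3 * exp(1 / 1.8), 9), f0 = 3)
#> [1] 0.90 0.45 0.00
```

The paired model comparison (physiology-shaped tunings versus the classic
16-filter bank, identical images and receptive-field locations) is run by
`compare_models()`; the full tuning-curve simulations by
`run_simulation(experiment_config(...))`. The numbered scripts under
`analysis/` run all three simulations at documented scales and write their
tables under `results/`.

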