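test_that("Fourier reshaping is exact at every non-DC bin", {
  n <- 128
  for (mode in c("literal", "additive")) {
    spec <- noise_spec(3, peak_mode = mode, seed = 9)
    img <- make_filtered_noise(spec, size = n, resolution = 60)
    white <- withr::with_seed(9L, matrix(stats::rnorm(n^2), n, n))
    ratio <- Mod(stats::fft(img$pixels)) / Mod(stats::fft(white))
    gain <- gaborpop:::noise_spectral_gain(spec, n, 60)
    expect_equal(ratio[-1], gain[-1], tolerance = 1e-9)
  }
})

test_that("noise images are reproducible by seed and distinct across seeds", {
  a <- make_filtered_noise(noise_spec(2, seed = 4), size = 64)
  b <- make_filtered_noise(noise_spec(2, seed = 4), size = 64)
  c <- make_filtered_noise(noise_spec(2, seed = 5), size = 64)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, c$pixels))
})

test_that("the raised-cosine peak shows up in the radial spectrum", {
  img <- make_filtered_noise(noise_spec(3, peak_mode = "additive", seed = 2),
    size = 512, resolution = 60
  )
  spec <- radial_amplitude_spectrum(img)
  # compensate the 1/f background; the residual must peak near 3 c/deg
  resid <- spec$amplitude * spec$frequency
  peak_f <- spec$frequency[which.max(resid)]
  expect_lt(abs(log(peak_f / 3)), log(1.3))

  # literal mode has no energy outside the cosine band at all
  lit <- make_filtered_noise(noise_spec(3, seed = 2), size = 512)
  sl <- radial_amplitude_spectrum(lit)
  outside <- sl$frequency > 3 * exp(1.5 / 1.8) * 1.1
  expect_true(all(sl$amplitude[outside] < 1e-10 * max(sl$amplitude)))
})

test_that("surrogate spectral slopes recover the target exponent", {
  for (beta in c(0.8, 1.0, 1.2)) {
    img <- make_surrogate_natural(surrogate_spec(beta = beta, seed = 31),
      size = 512, resolution = 60
    )
    expect_equal(spectral_slope(img), -beta, tolerance = 0.05)
  }
})

test_that("a zero exponent leaves the spectrum white", {
  img <- make_surrogate_natural(
    structure(list(beta = 0, seed = 3L), class = "surrogate_spec"),
    size = 512
  )
  expect_equal(spectral_slope(img), 0, tolerance = 0.05)
})

test_that("default spectral exponents are drawn from [0.8, 1.2]", {
  betas <- vapply(1:50, function(s) surrogate_spec(seed = s)$beta, numeric(1))
  expect_true(all(betas >= 0.8 & betas <= 1.2))
  expect_gt(diff(range(betas)), 0.1) # actually varies
  # and the draw is seed-reproducible
  expect_identical(surrogate_spec(seed = 7)$beta, surrogate_spec(seed = 7)$beta)
})

test_that("surrogate images are seed-deterministic", {
  a <- make_surrogate_natural(surrogate_spec(beta = 1, seed = 11), size = 64)
  b <- make_surrogate_natural(surrogate_spec(beta = 1, seed = 11), size = 64)
  c <- make_surrogate_natural(surrogate_spec(beta = 1, seed = 12), size = 64)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, c$pixels))
})

test_that("spec validation catches bad parameters", {
  expect_error(noise_spec(-1), regexp = "positive")
  expect_error(noise_spec(2, T = 1.2), regexp = "T")
  expect_error(surrogate_spec(beta = 3), regexp = "beta")
  expect_error(make_filtered_noise(noise_spec(40), size = 64, resolution = 60),
    regexp = "Nyquist"
  )
})
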