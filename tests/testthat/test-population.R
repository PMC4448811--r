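# a small calibrated image the toy neurons (f >= 2 c/deg at 60 px/deg)
# fit into, plus one neuron with a set centre
toy_image <- function(seed = 1, n = 256) {
  withr::with_seed(seed, stimulus_image(matrix(rnorm(n^2), n), 60))
}
toy_neuron <- function(f = 4, or = 30, ph = 60, x = 128, y = 130) {
  neuron_params(f, or, ph, x = x, y = y)
}

test_that("a zero image evokes zero response and linearity holds", {
  np <- toy_neuron()
  zero <- stimulus_image(matrix(0, 256, 256), 60)
  expect_identical(neuron_response(zero, np), 0)
  i1 <- toy_image(1)
  i2 <- toy_image(2)
  r1 <- neuron_response(i1, np)
  r2 <- neuron_response(i2, np)
  mix <- stimulus_image(2.5 * i1$pixels - 0.7 * i2$pixels, 60)
  expect_equal(neuron_response(mix, np), 2.5 * r1 - 0.7 * r2, tolerance = 1e-9)
})

test_that("a matched full-field grating drives the neuron as brute force says", {
  f <- 4
  or <- 20
  ph <- 45
  g <- make_grating(grating_spec(f, orientation = or, phase = ph), size = 256)
  np <- neuron_params(f, or, ph, x = 129, y = 127)
  r <- neuron_response(g, np)
  oracle <- brute_force_response(
    g$pixels, f, or, ph, np$sigma1, np$sigma2, 129, 127
  )
  expect_equal(r, oracle, tolerance = 1e-9)
  expect_gt(r, 0) # matched in phase: strong positive drive
})

test_that("supports outside the image are rejected", {
  img <- toy_image()
  np <- toy_neuron(f = 2, x = 10, y = 128) # radius 75 at f = 2
  expect_error(neuron_response(img, np), regexp = "outside")
  expect_error(
    place_and_respond(toy_image(1, 64), sample_tunings(toy_distributions(), 5, 1)),
    regexp = "too small.*c/deg"
  )
})

test_that("the compiled population path equals the R reference path", {
  img <- toy_image(3)
  tun <- sample_tunings(toy_distributions(), 40, seed = 9)
  pr <- place_and_respond(img, tun, seed = 4)
  ref <- vapply(seq_len(40), function(k) {
    np <- neuron_params(tun$frequency[k], tun$orientation[k], tun$phase[k],
      sigma1 = tun$sigma1[k], sigma2 = tun$sigma2[k],
      x = pr$centres[k, 1], y = pr$centres[k, 2]
    )
    neuron_response(img, np)
  }, numeric(1))
  expect_equal(pr$responses, ref, tolerance = 1e-10)
})

test_that("population placement is seed-deterministic", {
  img <- toy_image(5)
  tun <- sample_tunings(toy_distributions(), 200, seed = 2)
  a <- place_and_respond(img, tun, seed = 11)
  b <- place_and_respond(img, tun, seed = 11)
  c <- place_and_respond(img, tun, seed = 12)
  expect_identical(a$responses, b$responses)
  expect_identical(a$centres, b$centres)
  expect_false(identical(a$responses, c$responses))
})

test_that("small tuning banks are recycled across a larger population", {
  img <- toy_image(6)
  bank <- sample_tunings(toy_distributions(), 4, seed = 1)
  pr <- place_and_respond(img, bank, n = 300, seed = 3)
  expect_length(pr$responses, 300)
  expect_true(all(pr$tunings$frequency %in% bank$frequency))
})

test_that("magnitude and kurtosis are sign-symmetric and scale-consistent", {
  withr::with_seed(10, r <- rt(5000, df = 5))
  expect_equal(total_magnitude(r), total_magnitude(-r))
  expect_equal(excess_kurtosis(r), excess_kurtosis(-r))
  expect_equal(excess_kurtosis(3.7 * r), excess_kurtosis(r), tolerance = 1e-12)
  expect_equal(total_magnitude(r), length(r) * mean(abs(r)), tolerance = 1e-9)
  expect_identical(total_magnitude(rep(0, 10)), 0)
})

test_that("excess kurtosis matches known distributions", {
  withr::with_seed(21, {
    g <- rnorm(1e6)
    # Laplace via difference of exponentials
    l <- rexp(1e6) - rexp(1e6)
  })
  expect_equal(excess_kurtosis(g), 0, tolerance = 0.05)
  expect_equal(excess_kurtosis(l), 3, tolerance = 0.1)
})

test_that("zero-variance responses yield an explicit missing kurtosis", {
  expect_true(is.na(excess_kurtosis(rep(2, 100))))
  expect_error(excess_kurtosis(c(1, 2, 3)), regexp = "at least 4")
})

test_that("response histograms are normalized and match naive counting", {
  withr::with_seed(13, x <- rnorm(2000))
  h <- response_histogram(x)
  expect_equal(sum(h$probability), 1, tolerance = 1e-12)
  # symmetric vector -> symmetric histogram
  xs <- c(x, -x)
  hs <- response_histogram(xs)
  expect_equal(hs$probability, rev(hs$probability), tolerance = 1e-12)
  # naive counting oracle on fixed breaks
  breaks <- seq(-6, 6, by = 0.5)
  h2 <- response_histogram(x, breaks = breaks)
  naive <- vapply(seq_len(length(breaks) - 1), function(i) {
    if (i == 1) {
      sum(x >= breaks[i] & x <= breaks[i + 1])
    } else {
      sum(x > breaks[i] & x <= breaks[i + 1])
    }
  }, numeric(1)) / length(x)
  expect_equal(h2$probability, naive, tolerance = 1e-12)
})

test_that("the full pipeline equals brute force on 16x16 toy images", {
  # three neurons, tiny image, low resolution so the supports fit
  res <- 4
  withr::with_seed(33, img <- stimulus_image(matrix(rnorm(16^2), 16), res))
  dist <- tuning_distributions(
    frequency = data.frame(value = c(1.6, 2, 2.4), probability = rep(1 / 3, 3)),
    orientation = data.frame(value = c(0, 60, 120), probability = rep(1 / 3, 3)),
    phase = data.frame(value = c(0, 90), probability = c(0.5, 0.5))
  )
  tun <- sample_tunings(dist, 3, seed = 2)
  pr <- place_and_respond(img, tun, seed = 8)
  oracle <- vapply(1:3, function(k) {
    brute_force_response(
      img$pixels, tun$frequency[k], tun$orientation[k], tun$phase[k],
      tun$sigma1[k], tun$sigma2[k],
      pr$centres[k, 1], pr$centres[k, 2],
      resolution = res
    )
  }, numeric(1))
  expect_equal(pr$responses, oracle, tolerance = 1e-12)
})

test_that("summaries carry the algebraic identities", {
  img <- toy_image(7)
  tun <- sample_tunings(toy_distributions(), 500, seed = 5)
  pr <- place_and_respond(img, tun, seed = 6)
  s <- summarize_response(pr)
  expect_equal(s$total_magnitude, s$n * s$mean_abs, tolerance = 1e-9)
  expect_gte(s$excess_kurtosis, -2)
  expect_equal(s$n, 500)
})
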