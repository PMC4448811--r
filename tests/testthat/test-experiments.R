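# Reduced-geometry configs keep these tests fast: 256-px images at 60 px/deg
# with toy tunings whose receptive fields fit.
small_config <- function(...) {
  defaults <- list(
    simulation = 2,
    frequencies = c(2, 4, 8),
    n_neurons = 400,
    n_noise_seeds = 2,
    n_surrogate_images = 2,
    size = 256,
    tunings = toy_distributions()
  )
  do.call(experiment_config, utils::modifyList(defaults, list(...)))
}

test_that("invalid configurations fail before any computation", {
  expect_error(experiment_config(simulation = 5), regexp = "simulation")
  expect_error(experiment_config(frequencies = c(2, 40)), regexp = "Nyquist")
  expect_error(experiment_config(nonsense = 1), regexp = "unknown config keys")
  expect_error(experiment_config(noise = list(bogus = 2)), regexp = "unknown noise")
  expect_error(
    run_simulation(experiment_config(simulation = 1)),
    regexp = "compare_models"
  )
})

test_that("a simulation run is reproducible from config plus seed", {
  cfg <- small_config(seed = 99)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$table, b$table)
  expect_identical(a$details, b$details)
  c <- run_simulation(small_config(seed = 100))
  expect_false(identical(a$table, c$table))
})

test_that("the tuning-curve table has one row per class and frequency", {
  res <- run_simulation(small_config(seed = 1))
  tab <- res$table
  expect_setequal(unique(tab$class), c("grating", "noise", "surrogate"))
  for (cls in c("grating", "noise")) {
    expect_setequal(tab$frequency[tab$class == cls], c(2, 4, 8))
  }
  expect_equal(sum(tab$class == "surrogate"), 1)
  expect_equal(tab$n_images[tab$class == "noise"], rep(2, 3))
  expect_true(all(tab$mean_total_magnitude >= 0))
})

test_that("halving the neuron count halves magnitude but not kurtosis", {
  cfg1 <- small_config(
    seed = 5, n_neurons = 4000, classes = "noise",
    n_surrogate_images = 0, frequencies = c(2, 4)
  )
  cfg2 <- small_config(
    seed = 5, n_neurons = 2000, classes = "noise",
    n_surrogate_images = 0, frequencies = c(2, 4)
  )
  r1 <- run_simulation(cfg1)
  r2 <- run_simulation(cfg2)
  m1 <- r1$table$mean_total_magnitude
  m2 <- r2$table$mean_total_magnitude
  expect_equal(m2 / m1, rep(0.5, 2), tolerance = 0.1)
  # kurtosis is unbiased by the population size, not halved with it
  expect_equal(r2$table$mean_excess_kurtosis, r1$table$mean_excess_kurtosis,
    tolerance = 0.5
  )
})

test_that("surrogate response histograms peak in the zero bin", {
  dist <- toy_distributions(frequencies = c(1, 2, 4), probs = c(0.3, 0.4, 0.3))
  img <- rescale_luminance(
    make_surrogate_natural(surrogate_spec(seed = 17), size = 512)
  )
  tun <- sample_tunings(dist, 5000, seed = 2)
  pr <- place_and_respond(img, tun, seed = 3)
  m <- max(abs(pr$responses))
  h <- response_histogram(pr, breaks = seq(-m, m, length.out = 22))
  modal <- h$centre[which.max(h$probability)]
  expect_equal(modal, 0, tolerance = 1e-9) # the bin containing zero wins
  expect_equal(sum(h$probability), 1, tolerance = 1e-12)
})

test_that("model comparison pairs images and receptive-field locations", {
  cmp <- compare_models(
    n_rep = 2, n_neurons = 300, size = 512,
    tunings = toy_distributions(), seed = 21
  )
  expect_equal(nrow(cmp$reps), 2)
  expect_equal(nrow(cmp$table), 2)
  expect_setequal(cmp$table$model, c("physiological", "field_configuration"))
  expect_true(all(is.finite(cmp$reps$mean_abs_ratio)))
  # reproducibility of the paired draw
  cmp2 <- compare_models(
    n_rep = 2, n_neurons = 300, size = 512,
    tunings = toy_distributions(), seed = 21
  )
  expect_identical(cmp$reps, cmp2$reps)
})

test_that("bypassing the CSF shifts the grating magnitude peak no higher", {
  # directional contract between simulations 2 and 3 at reduced scale
  cfg2 <- small_config(seed = 8)
  cfg3 <- experiment_config(
    simulation = 3, frequencies = c(2, 4, 8),
    n_neurons = 400, n_noise_seeds = 2, n_surrogate_images = 0,
    size = 256, tunings = toy_distributions(), seed = 8
  )
  r2 <- run_simulation(cfg2)
  r3 <- run_simulation(cfg3)
  for (cls in c("grating", "noise")) {
    p2 <- tuning_extrema(r2, cls)$magnitude_peak
    p3 <- tuning_extrema(r3, cls)$magnitude_peak
    expect_lte(p3, p2)
  }
})
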