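test_that("degenerate single-bin distributions give identical neurons", {
  dist <- tuning_distributions(
    frequency = data.frame(value = 3, probability = 1),
    orientation = data.frame(value = 90, probability = 1),
    phase = data.frame(value = 45, probability = 1)
  )
  tun <- sample_tunings(dist, 20, seed = 1)
  expect_true(all(tun$frequency == 3))
  expect_true(all(tun$orientation == 90))
  expect_true(all(tun$phase == 45))
  expect_true(all(tun$sigma2 == 2 * tun$sigma1))
})

test_that("the default frequency distribution is midrange-dominated", {
  dist <- default_tuning_distributions()
  tun <- sample_tunings(dist, 1e5, seed = 42)
  modal <- as.numeric(names(which.max(table(tun$frequency))))
  expect_gte(modal, 2)
  expect_lte(modal, 6)
  expect_true(all(tun$frequency > 0 & tun$frequency < 30))
})

test_that("empirical histograms match the target densities", {
  dist <- default_tuning_distributions()
  tun <- sample_tunings(dist, 1e5, seed = 7)
  for (dim in c("frequency", "orientation", "phase")) {
    target <- dist[[dim]]
    emp <- table(factor(tun[[dim]], levels = target$value)) / nrow(tun)
    expect_lt(max(abs(as.numeric(emp) - target$probability)), 0.01)
  }
})

test_that("sampling is bit-reproducible under a fixed seed", {
  dist <- default_tuning_distributions()
  expect_identical(
    sample_tunings(dist, 1000, seed = 3),
    sample_tunings(dist, 1000, seed = 3)
  )
  expect_false(identical(
    sample_tunings(dist, 1000, seed = 3)$frequency,
    sample_tunings(dist, 1000, seed = 4)$frequency
  ))
})

test_that("malformed distribution tables are rejected", {
  expect_error(
    tuning_distributions(
      frequency = data.frame(value = numeric(0), probability = numeric(0)),
      orientation = data.frame(value = 0, probability = 1),
      phase = data.frame(value = 0, probability = 1)
    ),
    regexp = "empty"
  )
  expect_error(
    tuning_distributions(
      frequency = data.frame(value = c(1, 2), probability = c(0, 0)),
      orientation = data.frame(value = 0, probability = 1),
      phase = data.frame(value = 0, probability = 1)
    ),
    regexp = "normalized"
  )
  expect_error(
    tuning_distributions(
      frequency = data.frame(value = c(1, 2), probability = c(0.5, -0.5)),
      orientation = data.frame(value = 0, probability = 1),
      phase = data.frame(value = 0, probability = 1)
    ),
    regexp = "non-negative"
  )
})

test_that("the fixed configuration expands to 16 unique tunings", {
  tun <- field_tunings(size = 1024, resolution = 60)
  expect_equal(nrow(tun), 16)
  expect_equal(nrow(unique(tun[, c("frequency", "orientation", "phase")])), 16)
  # cycles per image -> cycles per degree conversion
  expect_setequal(
    round(unique(tun$frequency), 10),
    round(c(20, 40) * 60 / 1024, 10)
  )
  # cross-check by counting cycles across the image: a grating at this
  # frequency completes exactly 20 cycles over 1024 px
  f <- 20 * 60 / 1024
  expect_equal(f * (1024 / 60), 20, tolerance = 1e-12)
})
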