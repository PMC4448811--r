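# Independent oracles, written from the definitions and kept free of the
# package's implementation paths.

# Literal Gabor evaluation: plain loops, direct exp/cos, no recurrences.
brute_force_gabor <- function(frequency, orientation, phase, sigma1, sigma2,
                              radius, resolution = 60,
                              normalize = TRUE, gain = 1) {
  s1 <- sigma1 * resolution
  s2 <- sigma2 * resolution
  fpx <- frequency / resolution
  th <- orientation * pi / 180
  ph <- phase * pi / 180
  n <- 2 * radius + 1
  w <- matrix(0, n, n)
  for (i in seq_len(n)) { # row = y
    for (j in seq_len(n)) { # col = x
      dy <- i - radius - 1
      dx <- j - radius - 1
      xp <- dx * cos(th) - dy * sin(th)
      yp <- dx * sin(th) + dy * cos(th)
      w[i, j] <- gain * exp(-xp^2 / (2 * s1^2) - yp^2 / (2 * s2^2)) *
        cos(2 * pi * fpx * xp + ph)
    }
  }
  if (normalize) {
    w <- w - mean(w)
    w <- w / sqrt(sum(w^2))
  }
  w
}

# Inner product of a brute-force receptive field with an image patch.
brute_force_response <- function(image_px, frequency, orientation, phase,
                                 sigma1, sigma2, cx, cy, resolution = 60,
                                 normalize = TRUE) {
  radius <- as.integer(ceiling(3 * sigma2 * resolution))
  w <- brute_force_gabor(frequency, orientation, phase, sigma1, sigma2,
    radius, resolution,
    normalize = normalize
  )
  patch <- image_px[(cy - radius):(cy + radius), (cx - radius):(cx + radius)]
  s <- 0
  for (i in seq_len(nrow(w))) {
    for (j in seq_len(ncol(w))) s <- s + patch[i, j] * w[i, j]
  }
  s
}

# Location (kx, ky in c/deg) and value of the largest non-DC FFT amplitude.
fft_peak <- function(px, resolution = 60) {
  amp <- Mod(stats::fft(px))
  amp[1, 1] <- 0
  idx <- arrayInd(which.max(amp), dim(amp))
  f <- gaborpop::fft_frequencies(nrow(px), resolution)
  list(kx = f[idx[2]], ky = f[idx[1]], amplitude = max(amp))
}

# Fraction of non-DC spectral energy in the 3x3 bin neighbourhoods of
# (kx, ky) and its conjugate mirror.
band_energy_fraction <- function(px, kx, ky, resolution = 60) {
  n <- nrow(px)
  amp2 <- Mod(stats::fft(px))^2
  amp2[1, 1] <- 0
  f <- gaborpop::fft_frequencies(n, resolution)
  ix <- which.min(abs(f - kx))
  iy <- which.min(abs(f - ky))
  neigh <- function(i) ((i - 2):(i)) %% n + 1 # i-1, i, i+1 in 1-based wrap
  sel <- matrix(FALSE, n, n)
  sel[neigh(iy), neigh(ix)] <- TRUE
  # conjugate bin: index i maps to (n - i + 2) wrapped
  cx <- (n - ix + 1) %% n + 1
  cy <- (n - iy + 1) %% n + 1
  sel[neigh(cy), neigh(cx)] <- TRUE
  sum(amp2[sel]) / sum(amp2)
}

# A tiny tuning-distribution set whose neurons fit small test images.
toy_distributions <- function(frequencies = c(2, 3, 4),
                              probs = c(0.3, 0.4, 0.3)) {
  gaborpop::tuning_distributions(
    frequency = data.frame(value = frequencies, probability = probs),
    orientation = data.frame(value = c(0, 45, 90, 135), probability = rep(0.25, 4)),
    phase = data.frame(value = c(0, 90, 180, 270), probability = rep(0.25, 4))
  )
}
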