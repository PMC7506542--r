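test_that("Welch PSD localizes a pure tone and respects Parseval", {
  fs <- 1000
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 35 * t)
  psd <- welch_psd(x, fs)
  expect_equal(psd$freq_hz[which.max(psd$power)], 35, tolerance = 0.5)
  expect_true(all(psd$power >= 0))
  expect_lte(psd$freq_hz[2] - psd$freq_hz[1], 1)

  # constant trace: all-zero PSD after DC removal
  psd0 <- welch_psd(rep(3.7, 2000), fs)
  expect_equal(max(psd0$power), 0)

  # white noise: integrated PSD approximates the signal variance
  set.seed(42)
  w <- rnorm(5000)
  psdw <- welch_psd(w, fs)
  tot <- sum(psdw$power) * (psdw$freq_hz[2] - psdw$freq_hz[1])
  expect_equal(tot, var(w), tolerance = 0.1)

  expect_error(welch_psd(rnorm(100), fs), "too short")
})

test_that("band power integrates the half-open band additively", {
  fs <- 1000
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  psd <- welch_psd(sin(2 * pi * 35 * t), fs)
  expect_gt(band_power(psd, 25, 50) / max(band_power(psd, 55, 80), 1e-12), 100)
  expect_equal(band_power(psd, 25, 50) + band_power(psd, 50, 80),
               band_power(psd, 25, 80))
  expect_error(band_power(psd, 600, 700), "empty")
  zero <- welch_psd(rep(0, 2000), fs)
  expect_equal(band_power(zero, 25, 50), 0)
})

test_that("transfer entropy matches the brute-force entropy oracle exactly", {
  # exhaustive over all binary sequence pairs at short lengths
  for (len in 4:6) {
    for (i in 0:(2^len - 1)) {
      x <- int_to_bits(i, len)
      for (j in 0:(2^len - 1)) {
        y <- int_to_bits(j, len)
        expect_equal(ca3net:::te_binned(x, y)$te_raw, te_oracle(x, y),
                     tolerance = 1e-12)
      }
    }
  }
  # random binary pairs at lengths up to 12
  set.seed(7)
  for (rep in 1:500) {
    len <- sample(7:12, 1)
    x <- rbinom(len, 1, runif(1, 0.2, 0.8))
    y <- rbinom(len, 1, runif(1, 0.2, 0.8))
    expect_equal(ca3net:::te_binned(x, y)$te_raw, te_oracle(x, y),
                 tolerance = 1e-12)
  }
  # non-binary counts
  set.seed(8)
  for (rep in 1:100) {
    x <- rpois(50, 1.5)
    y <- rpois(50, 1.5)
    expect_equal(ca3net:::te_binned(x, y)$te_raw, te_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("nTE approaches 1 for a delayed copy and 0 for independence", {
  set.seed(1)
  x <- rbinom(10000, 1, 0.5)
  y <- c(0L, x[-10000])
  r <- nte_binned(x, y, shuffles = 30, seed = 1)
  expect_true(r$defined)
  expect_gt(r$nte, 0.9)
  expect_equal(r$h_cond_bits, 1, tolerance = 0.01)

  indep <- nte_binned(rbinom(3000, 1, 0.3), rbinom(3000, 1, 0.3),
                      shuffles = 30, seed = 2)
  expect_lt(abs(indep$nte * indep$h_cond_bits - 0),
            3 * indep$shuffle_sd_bits + 1e-9)
})

test_that("nTE is directional and flags degenerate output", {
  set.seed(3)
  x <- rbinom(5000, 1, 0.5)
  y <- c(0L, x[-5000])
  fwd <- nte_binned(x, y, shuffles = 20, seed = 1)$nte
  rev <- nte_binned(y, x, shuffles = 20, seed = 1)$nte
  expect_gt(fwd, rev)

  silent <- nte_binned(rbinom(500, 1, 0.5), rep(0L, 500), shuffles = 5)
  expect_false(silent$defined)
  expect_true(is.na(silent$nte))
})

test_that("spike-time nTE interface bins over the analysis window", {
  set.seed(4)
  pair <- gen_coupled_pair(10, 1, lag_bins = 1, bin_ms = 15,
                           duration_ms = 60000, seed = 4)
  r <- nte(pair$input_times, pair$output_times, bin_ms = 15,
           window = c(0, 60000), shuffles = 20, seed = 1)
  expect_true(r$defined)
  expect_gt(r$nte, 0.5)
  expect_error(nte(1:10, 1:10, window = c(0, 1000)), "100 bins")
})

test_that("modulation index profile math: uniform -> 0, concentrated -> 1", {
  expect_equal(mi_from_profile(rep(1, 18)), 0)
  expect_equal(mi_from_profile(c(5, rep(0, 17))), 1)
  expect_true(is.na(mi_from_profile(rep(0, 18))))
  expect_error(mi_from_profile(c(-1, rep(1, 17))))
  # intermediate concentration is strictly between
  m <- mi_from_profile(c(4, 2, rep(1, 16)))
  expect_gt(m, 0); expect_lt(m, 1)
})

test_that("modulation index detects phase-amplitude coupling and its absence", {
  mis <- vapply(c(0, 0.5, 1), function(cpl) {
    mean(vapply(1:5, function(s) {
      sig <- gen_pac_signal(coupling = cpl, duration_s = 5, noise_sd = 0.1,
                            seed = s)
      modulation_index(sig$trace, sig$fs_hz)$mi
    }, 1.0))
  }, 1.0)
  expect_lt(mis[1], 0.01)
  expect_lt(mis[2], mis[3])
  expect_gt(mis[3], 10 * mis[1])
})

test_that("modulation index is invariant to amplitude rescaling", {
  sig <- gen_pac_signal(coupling = 0.7, seed = 9)
  m1 <- modulation_index(sig$trace, sig$fs_hz)$mi
  m2 <- modulation_index(sig$trace * 37.5, sig$fs_hz)$mi
  expect_equal(m1, m2, tolerance = 1e-10)
})

test_that("popCV: Poisson ~ 1, periodic = 0, volleys = sqrt(N-1)", {
  cvs <- vapply(1:20, function(s) {
    pop_cv(gen_poisson_population(5, 200, 5000, seed = s))$popcv
  }, 1.0)
  expect_equal(mean(cvs), 1, tolerance = 0.1)

  periodic <- pop_cv(seq(0, 5000, by = 10))
  expect_equal(periodic$popcv, 0)

  volleys <- gen_volley_population(100, 100, jitter_ms = 0,
                                   duration_ms = 5000, seed = 1)
  expect_equal(pop_cv(volleys)$popcv, sqrt(99), tolerance = 0.05 * sqrt(99))

  # time rescaling leaves popCV unchanged
  tt <- unlist(gen_background_events(10, 5, 2000, seed = 3))
  expect_equal(pop_cv(tt)$popcv, pop_cv(tt * 3.3)$popcv, tolerance = 1e-12)

  expect_false(pop_cv(c(1))$defined)
})

test_that("population rate counts spikes per neuron per second", {
  expect_equal(pop_rate(numeric(0), 100, c(0, 1000)), 0)
  expect_equal(pop_rate(rep(seq(100, 4900, length.out = 5), 800), 800,
                        c(0, 5000)), 1)
  expect_error(pop_rate(1:5, 10, c(100, 100)))
})
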