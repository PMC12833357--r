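# Point-source LFP, filtering, Welch PSD, band metrics and spectrogram.

test_that("compute_lfp reproduces the single-source arithmetic", {
  # 1 nA at 50 um with Re = 230 Ohm cm -> 230e-9 / (4 pi 50e-4) V
  geom <- lfp_geometry(1)
  v <- compute_lfp(matrix(1), geom)
  expect_equal(v, 230e-9 / (4 * pi * 50e-4), tolerance = 1e-9)
  expect_equal(v, 3.66e-6, tolerance = 0.01)
  expect_equal(compute_lfp(matrix(0, 5, 1), geom), rep(0, 5))
})

test_that("compute_lfp is linear and falls off as 1/r", {
  geom <- lfp_geometry(c(3, 2))
  I1 <- matrix(rnorm(50), 10, 5)
  I2 <- matrix(rnorm(50), 10, 5)
  expect_equal(compute_lfp(2 * I1 + 3 * I2, geom),
               2 * compute_lfp(I1, geom) + 3 * compute_lfp(I2, geom),
               tolerance = 1e-12)
  g1 <- lfp_geometry(1, offset = 50)
  g2 <- lfp_geometry(1, offset = 100)
  expect_equal(compute_lfp(matrix(1), g1) / compute_lfp(matrix(1), g2), 2)
  expect_error(compute_lfp(matrix(1, 2, 3), g1), "match")
})

test_that("preprocess removes trends and passes the spindle band", {
  fs <- 10000
  ramp <- make_tone_mixture(NULL, duration = 4000, fs = fs, trend = 2)
  expect_lt(max(abs(preprocess(ramp, fs))), 1e-6)
  tone7 <- make_tone_mixture(tone_df(7), duration = 4000, fs = fs)
  out7 <- preprocess(tone7, fs)
  mid <- 10000:30000  # avoid filter edges
  expect_gt(max(out7[mid]), 0.9)
  tone50 <- make_tone_mixture(tone_df(50), duration = 4000, fs = fs)
  expect_lt(max(abs(preprocess(tone50, fs)[mid])), 0.1)
})

test_that("welch_psd has 0.5 Hz bins and recovers pure tones", {
  x <- make_tone_mixture(tone_df(7), duration = 6000)
  psd <- welch_psd(x)
  expect_equal(diff(psd$freq[1:2]), 0.5)
  expect_equal(psd$freq[which.max(psd$power)], 7)
  expect_true(all(welch_psd(rep(0, 40000))$power == 0))
  expect_error(welch_psd(rep(0, 100)), "shorter")
})

test_that("welch_psd integrates to the signal variance", {
  x <- make_tone_mixture(NULL, duration = 8000, noise_sd = 1, seed = 42)
  psd <- welch_psd(x)
  total <- sum(psd$power) * 0.5
  expect_lt(abs(total - 1), 0.1)
})

test_that("band_metrics labels concentrated power correctly", {
  freq <- seq(0, 20, by = 0.5)
  mk <- function(at, p) {
    d <- data.frame(freq = freq, power = 0)
    d$power[match(at, freq)] <- p
    class(d) <- c("thalnet_psd", "data.frame")
    d
  }
  swd <- band_metrics(mk(4, 1))
  expect_equal(swd$state, "SWD")
  expect_equal(swd$swd_rel, 1)
  expect_equal(swd$peak_frequency, 4)
  spin <- band_metrics(mk(8, 1))
  expect_equal(spin$state, "spindle")
  expect_equal(spin$peak_frequency, 8)
  tie <- band_metrics(mk(c(4, 8), c(1, 1)))
  expect_equal(tie$state, "intermediate")
  expect_error(band_metrics(mk(4, 1)[0, ]), "empty")
  # disjoint band powers cannot exceed the total
  x <- make_tone_mixture(data.frame(freq = c(4, 8), amp = c(1, 1)), 6000)
  bm <- band_metrics(welch_psd(preprocess(x)))
  expect_lte(bm$swd_rel + bm$spindle_rel, 1)
})

test_that("spectrogram tracks stationary and switching tones", {
  x <- make_tone_mixture(tone_df(7), duration = 6000)
  sg <- spectrogram(x)
  ridge <- sg$freq[apply(sg$power, 2, which.max)]
  expect_true(all(ridge == 7))
  spliced <- c(make_tone_mixture(tone_df(4), 4000),
               make_tone_mixture(tone_df(8), 4000))
  sg2 <- spectrogram(spliced, window = 10000, hop = 10000)
  ridge2 <- sg2$freq[apply(sg2$power, 2, which.max)]
  expect_equal(ridge2[1], 4)
  expect_equal(tail(ridge2, 1), 8)
  expect_true(all(spectrogram(rep(0, 40000))$power == 0))
})

test_that("LFP recording subset is configurable and geometry matches it", {
  r <- cached_scenario(75, 1, FALSE, keep_sim = TRUE)
  sim <- r$sim
  expect_equal(nrow(sim$lfp_cells), 20)  # 10 RS + 10 IB by default
  lfp <- compute_lfp(sim)
  expect_equal(length(lfp), nrow(sim$V))
  expect_true(all(is.finite(lfp)))
})
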