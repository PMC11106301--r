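test_that("welch_psd matches the brute-force DFT periodogram oracle", {
  withr::local_seed(3)
  fs <- 256
  for (i in 1:5) {
    x <- rnorm(fs)
    got <- welch_psd(x, fs)
    ref <- oracle_psd(x, fs)
    expect_equal(got$freq, ref$freq)
    expect_lt(max(abs(got$power - ref$power)) / max(ref$power), 1e-10)
  }
  expect_error(welch_psd(rnorm(100), fs), "1-s blocks")
})

test_that("a pure sinusoid concentrates its power in its own band", {
  fs <- 1024
  p <- welch_psd(sine_block(10, fs), fs)
  nondc <- p$freq > 0
  frac <- sum(p$power[p$freq >= 8 & p$freq <= 12]) / sum(p$power[nondc])
  expect_gt(frac, 0.95)
  bp <- band_powers(p)
  expect_true(all(bp["alpha"] > 10 * bp[c("delta", "theta", "beta",
                                          "gamma", "high_gamma")]))
})

test_that("all-zero input gives an all-zero PSD and white noise a flat one", {
  fs <- 512
  expect_true(all(welch_psd(rep(0, fs), fs)$power == 0))

  withr::local_seed(11)
  tr <- lfp_trace(rnorm(1000 * fs), fs = fs)
  bp <- band_powers(session_psd(tr))
  # equal mean density in every band for white noise, up to MC error
  expect_equal(unname(bp["delta"] / bp["gamma"]), 1, tolerance = 0.1)
  expect_equal(unname(bp["alpha"] / bp["high_gamma"]), 1, tolerance = 0.1)
})

test_that("Parseval identity holds for the single-window configuration", {
  withr::local_seed(4)
  fs <- 512
  x <- rnorm(fs)
  p <- welch_psd(x, fs)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(fs - 1)) / (fs - 1))
  lhs <- sum(p$power) * 1                      # bin width 1 Hz
  rhs <- sum((x * w)^2) / sum(w^2)
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("session_psd averages per-segment PSDs linearly", {
  fs <- 128
  seg <- sine_block(10, fs)
  tr <- lfp_trace(rep(seg, 4), fs = fs)
  expect_equal(session_psd(tr)$power, welch_psd(seg, fs)$power)

  tr2 <- lfp_trace(c(seg, rep(0, fs)), fs = fs)
  expect_equal(session_psd(tr2)$power, welch_psd(seg, fs)$power / 2)
})

test_that("1-s segmentation floors the duration and partitions the samples", {
  fs <- 100
  tr <- lfp_trace(seq_len(1070), fs = fs)
  blocks <- segment_1s(tr)
  expect_equal(dim(blocks), c(100L, 10L))
  expect_equal(as.vector(blocks), as.numeric(seq_len(1000)))
  expect_equal(ncol(segment_1s(lfp_trace(1:100, fs = fs))), 1L)
  expect_error(segment_1s(lfp_trace(1:99, fs = fs)), "shorter")
})

test_that("preprocess notches line noise, preserves the passband and zeros", {
  fs <- 1024
  tr60 <- lfp_trace(rep(sine_block(60, fs), 8), fs = fs)
  p0 <- session_psd(tr60)
  p1 <- session_psd(preprocess(tr60))
  att_db <- 10 * log10(p0$power[p0$freq == 60] / p1$power[p1$freq == 60])
  expect_gt(att_db, 20)

  tr10 <- lfp_trace(rep(sine_block(10, fs), 8), fs = fs)
  out <- preprocess(tr10)
  mid <- 2049:6144   # steady-state region away from filter edges
  expect_equal(max(abs(out$samples[mid])), 1, tolerance = 0.01)

  z <- preprocess(lfp_trace(rep(0, 2 * fs), fs = fs))
  expect_true(all(abs(z$samples) < 1e-12))
  expect_error(preprocess(lfp_trace(rep(0, 400), fs = 400)), "too low")
})

test_that("band powers exclude DC, honour Nyquist and scale as amplitude squared", {
  psd <- data.frame(freq = 0:256, power = rep(1, 257))
  bp <- band_powers(psd, fs = 512)
  expect_true(all(bp == 1))

  psd_dc <- data.frame(freq = 0:256, power = c(100, rep(0, 256)))
  expect_equal(unname(band_powers(psd_dc, fs = 512)["delta"]), 0)

  expect_error(band_powers(data.frame(freq = 0:64, power = rep(1, 65)),
                           fs = 128), "Nyquist")

  withr::local_seed(8)
  fs <- 512
  x <- rnorm(10 * fs)
  b1 <- band_power_series(lfp_trace(x, fs = fs))
  b2 <- band_power_series(lfp_trace(3 * x, fs = fs))
  for (b in c("delta", "alpha", "gamma", "low", "high"))
    expect_equal(b2[[b]], 9 * b1[[b]], tolerance = 1e-12)
})

test_that("HLR is the high/low power ratio with invalidity as data", {
  s <- bp_series(low = c(1, 2, 4, 0), high = c(1, 4, 4, 5))
  h <- hlr(s)
  expect_equal(h$hlr[1:3], c(1, 2, 1))
  expect_false(h$valid[4])
  expect_true(is.na(h$hlr[4]))
})

test_that("HLR is invariant to global amplitude scaling through the full chain", {
  withr::local_seed(9)
  fs <- 512
  x <- rnorm(8 * fs)
  h1 <- hlr(band_power_series(preprocess(lfp_trace(x, fs = fs))))
  h2 <- hlr(band_power_series(preprocess(lfp_trace(7.3 * x, fs = fs))))
  expect_equal(h1$hlr, h2$hlr, tolerance = 1e-10)
})

test_that("band correlation matrix averages per-subject Pearson structure", {
  n <- 500
  withr::local_seed(10)
  v <- runif(n)
  s <- bp_series(low = v, high = v)
  s$delta <- s$theta <- v          # identical series correlate at 1
  m <- band_correlation_matrix(list(s))
  expect_equal(m["delta", "theta"], 1)
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 1))

  # independent white-noise band series decorrelate
  s2 <- bp_series(low = runif(10000), high = runif(10000))
  for (b in c("delta", "theta", "alpha", "beta", "gamma", "high_gamma"))
    s2[[b]] <- runif(10000)
  m2 <- band_correlation_matrix(list(s2))
  expect_lt(max(abs(m2[upper.tri(m2)])), 0.1)

  # constant series yield flagged NA entries, excluded from the average
  s3 <- bp_series(low = runif(100), high = runif(100))
  s3$delta <- 1
  m3 <- band_correlation_matrix(list(s3))
  expect_true(is.na(m3["delta", "theta"]))
})

test_that("generator low/high drivers reproduce the anticorrelated band structure", {
  b <- simulate_cohort(quick_config(duration_s = 1800, seed = 21))
  m <- band_correlation_matrix(b$band_powers)
  expect_gt(m["delta", "theta"], 0.5)
  expect_gt(m["gamma", "high_gamma"], 0.5)
  expect_lt(m["delta", "gamma"], -0.2)
  expect_lt(m["alpha", "high_gamma"], -0.2)
})

test_that("robust scaler centres rows by median/IQR and flags constants", {
  spec <- rbind(c(3, 4, 5, 6, 7), rep(2, 5))
  out <- robust_scale_spectrogram(spec)
  expect_equal(IQR(spec[1, ]), 2)
  expect_equal(out[1, 5], (7 - 5) / 2)   # (x - median) / IQR
  expect_true(all(is.na(out[2, ])))
  expect_equal(attr(out, "invalid_rows"), 2L)

  withr::local_seed(2)
  sp <- matrix(rexp(50 * 20), nrow = 50)
  sc <- robust_scale_spectrogram(sp)
  expect_equal(unname(apply(sc, 1, median)), rep(0, 50), tolerance = 1e-12)
})
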