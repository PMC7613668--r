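test_that("band-pass design hits the half-power edges and band structure", {
  cas <- design_bandpass(filter_chain_config())
  H <- function(f) Mod(cascade_response(cas, f))
  # -3 dB within 0.1 dB at both edges
  expect_equal(20 * log10(H(8)), -10 * log10(2), tolerance = 0.1)
  expect_equal(20 * log10(H(22)), -10 * log10(2), tolerance = 0.1)
  # DC zero, Nyquist < -60 dB
  expect_equal(H(0), 0, tolerance = 1e-10)
  expect_lt(20 * log10(H(128)), -60)
  # geometric mid-band gain within 0.5 dB of unity
  expect_equal(20 * log10(H(sqrt(8 * 22))), 0, tolerance = 0.5)
  # all sections stable
  for (s in cas$sections) {
    expect_lt(abs(s$a[3]), 1)
    expect_lt(abs(s$a[2]), 1 + s$a[3])
  }
  expect_error(filter_chain_config(low_hz = 0), "band edges")
  expect_error(filter_chain_config(high_hz = 200), "band edges")
})

test_that("coefficient quantization is half-LSB exact and preserves the response", {
  cas <- design_bandpass(filter_chain_config())
  fp <- quantize_coefficients(cas)
  expect_true(all(fp$coef_int >= -32768 & fp$coef_int <= 32767))
  # per-coefficient error <= half LSB of Q2.13 (= 2^-14)
  orig <- sapply(cas$sections, function(s) c(s$b, s$a[2:3]))
  deq <- fp$coef_int / 2^fp$shift
  expect_true(all(abs(deq - orig) <= 2^-14 + 1e-15))
  # -3 dB points move by < 3%
  e0 <- lfpdetect:::half_power_edges(cas)
  e1 <- lfpdetect:::half_power_edges(lfpdetect:::dequantize_cascade(fp))
  expect_true(all(abs(e1 - e0) / e0 < 0.03))
  # out-of-range coefficient names the offending section
  big <- cas
  big$sections[[2]]$b <- big$sections[[2]]$b * 100
  expect_error(quantize_coefficients(big), "section 2")
})

test_that("fixed-point filtering matches the float reference within the noise bound", {
  cas <- design_bandpass(filter_chain_config())
  fp <- quantize_coefficients(cas)
  bound <- lfpdetect:::fixed_point_error_bound(fp)
  ref <- lfpdetect:::dequantize_cascade(fp)

  # zero in, zero out
  expect_equal(as.integer(filter_fixed(fp, rep(0L, 100))), rep(0L, 100))

  # impulse response within the bound
  imp <- c(16384L, rep(0L, 511))
  expect_lt(max(abs(filter_fixed(fp, imp) - filter_float(ref, imp))), bound)

  # random half-scale input: inside the bound, no saturation
  set.seed(21)
  x <- as.integer(round(runif(2560, -16384, 16383)))
  y <- filter_fixed(fp, x)
  expect_identical(attr(y, "saturations"), 0L)
  expect_lt(max(abs(y - filter_float(ref, x))), bound)

  # inputs beyond 16 bits are rejected
  expect_error(filter_fixed(fp, c(0L, 40000L)), "16-bit")
})

test_that("fixed-point chain attenuates out-of-band tones by >= 20 dB", {
  fp <- quantize_coefficients(design_bandpass(filter_chain_config()))
  t <- (0:2559) / 256
  mk <- function(f) as.integer(round(8000 * sin(2 * pi * f * t)))
  rms_ss <- function(y) sqrt(mean(as.numeric(y[513:2560])^2))
  expect_gt(20 * log10(rms_ss(filter_fixed(fp, mk(14))) /
                         rms_ss(filter_fixed(fp, mk(50)))), 20)
})

test_that("fixed-point filtering is exactly shift-invariant", {
  fp <- quantize_coefficients(design_bandpass(filter_chain_config()))
  set.seed(31)
  x <- as.integer(round(runif(500, -8000, 8000)))
  k <- 17
  y1 <- as.integer(filter_fixed(fp, x))
  y2 <- as.integer(filter_fixed(fp, c(rep(0L, k), x)))
  expect_identical(y2[(k + 1):(k + 500)], y1)
})

test_that("saturating accumulator clamps instead of wrapping and is counted", {
  # a pathological section (b0 = b1 = 3.999) overflows 32 bits on
  # consecutive full-scale samples
  fp <- structure(list(coef_int = matrix(c(32767L, 32767L, 0L, 0L, 0L), 5),
                       shift = 13, coeff_bits = 16, accum_bits = 32,
                       fs = 256, config = NULL),
                  class = "fixed_point_cascade")
  y <- filter_fixed(fp, c(32767L, 32767L))
  expect_gt(attr(y, "saturations"), 0)
  expect_true(all(abs(y) <= 32767))
})

test_that("EMA envelope follows its closed form and fixed point of the recurrence", {
  # unit step: y[n] = 1 - (1 - 1/32)^n; at n = 32 samples this is ~0.638
  y <- envelope_ema(rep(1, 64), 32)
  expect_equal(y[32], 1 - (1 - 1 / 32)^32, tolerance = 1e-12)
  expect_equal(y, 1 - (1 - 1 / 32)^(1:64), tolerance = 1e-12)
  # constant input converges monotonically to |c|
  yc <- envelope_ema(rep(-3, 2000), 32)
  expect_true(all(diff(yc) >= -1e-12))
  expect_equal(yc[2000], 3, tolerance = 1e-6)
  expect_equal(envelope_ema(rep(0, 50), 32), rep(0, 50))
  expect_error(envelope_ema(1:5, 0), "decay_samples")
  # fixed-point envelope tracks the float recurrence closely
  set.seed(41)
  xi <- as.integer(round(runif(1000, -2000, 2000)))
  expect_lt(max(abs(lfpdetect:::envelope_ema_fixed(xi, 32) -
                      envelope_ema(xi, 32))), 1)
})

test_that("classifier trace on a synthetic event is positive inside, negative far away", {
  cfg <- synth_config(120, n_events = 1, count_mode = "fixed", seed = 71)
  rec <- synthesize_recording(cfg)
  ann <- rec$annotations
  tr <- classify_filter(rec, filter_chain_config(threshold = 2))
  expect_s3_class(tr, "classifier_trace")
  expect_equal(length(tr$scores), length(rec$samples))
  # event interior (taper excluded) is flagged
  mid <- tr$times_s > ann$onset_s + 1 & tr$times_s < ann$offset_s - 1
  expect_gt(mean(tr$labels[mid]), 0.9)
  # remote background (> 10 s away) is quiet
  far <- tr$times_s < ann$onset_s - 10 | tr$times_s > ann$offset_s + 10
  expect_lt(mean(tr$labels[far]), 0.01)
})

test_that("degenerate thresholds and threshold monotonicity behave", {
  rec <- generate_background(5, 256, 1, seed = 81)
  tr0 <- classify_filter(rec, filter_chain_config(threshold = 0))
  expect_true(all(tr0$labels == 1))
  trbig <- classify_filter(rec, filter_chain_config(threshold = 1e9))
  expect_true(all(trbig$labels == 0))
  # raising the threshold never turns a negative positive
  t1 <- classify_filter(rec, filter_chain_config(threshold = 0.2))
  t2 <- classify_filter(rec, filter_chain_config(threshold = 0.4))
  expect_true(all(t2$labels <= t1$labels))
  # fs mismatch instructs resampling
  rec512 <- lfp_recording(rnorm(1024), 512)
  expect_error(classify_filter(rec512, filter_chain_config()), "resample")
})

test_that("float and fixed arithmetic paths agree on the envelope scale", {
  rec <- synthesize_recording(synth_config(60, n_events = 1,
                                           count_mode = "fixed", seed = 91))
  trx <- classify_filter(rec, filter_chain_config(), arithmetic = "fixed")
  trf <- classify_filter(rec, filter_chain_config(), arithmetic = "float")
  expect_lt(mean(abs(trx$scores - trf$scores)), 0.05)
})
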