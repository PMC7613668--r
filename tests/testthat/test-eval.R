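test_that("ROC endpoints, symmetry and chance level are correct", {
  y <- c(0, 0, 1, 1, 0, 1)
  expect_equal(roc_curve(y, y)$auroc, 1.0)
  expect_equal(roc_curve(1 - y, y)$auroc, 0.0)
  expect_equal(roc_curve(c(0.2, 0.3, 0.9, 0.8, 0.1, 0.7), y)$auroc, 1.0)

  # chance level under label permutation
  set.seed(1)
  s <- runif(1e4); yy <- sample(rep(0:1, 5e3))
  expect_equal(roc_curve(s, yy)$auroc, 0.5, tolerance = 0.03)

  # score-sign reversal maps A to 1 - A
  a1 <- roc_curve(s, yy)$auroc
  expect_equal(roc_curve(-s, yy)$auroc, 1 - a1, tolerance = 1e-12)

  # invariance under strictly monotone transforms
  set.seed(2)
  s2 <- rnorm(500); y2 <- rbinom(500, 1, plogis(s2))
  expect_equal(roc_curve(s2, y2)$auroc, roc_curve(exp(s2), y2)$auroc,
               tolerance = 1e-12)

  # endpoints present, rates monotone
  r <- roc_curve(s2, y2)
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))

  expect_error(roc_curve(s2, rep(1, 500)), "both classes")
  expect_error(roc_curve(1:3, 1:2), "equal length")
})

test_that("hand-rolled ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  s <- rnorm(400); y <- rbinom(400, 1, plogis(2 * s))
  a_ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
  expect_equal(roc_curve(s, y)$auroc, a_ref, tolerance = 1e-10)
})

test_that("truth labels at trace timestamps follow the half-open convention", {
  tr <- classifier_trace(times_s = c(0.5, 1.0, 1.5, 2.0, 2.5),
                         scores = rep(0, 5), labels = rep(0, 5),
                         hop_samples = 128, fs = 256)
  ann <- data.frame(onset_s = 1.0, offset_s = 2.0, label = "seizure")
  expect_equal(trace_truth(tr, ann), c(0L, 1L, 1L, 0L, 0L))
})

test_that("onset latency measures first detection inside the search window", {
  hop_s <- 20 / 256
  times <- seq_len(256) * hop_s
  ann <- data.frame(onset_s = times[100], offset_s = times[100] + 4,
                    label = "seizure")
  # positive from exactly the onset timestamp: latency 0
  lab <- as.integer(times >= ann$onset_s)
  tr <- classifier_trace(times, lab, lab, 20, 256)
  lat <- onset_latency(tr, ann)
  expect_equal(lat$mean_latency_s, 0)
  expect_equal(lat$missed, 0)

  # first positive 3 windows after onset: latency quantized to hop multiples
  lab2 <- as.integer(times >= ann$onset_s + 3 * hop_s)
  lat2 <- onset_latency(classifier_trace(times, lab2, lab2, 20, 256), ann)
  expect_equal(lat2$mean_latency_s, 3 * 0.078125)

  # all-negative trace: everything missed, mean absent
  lat3 <- onset_latency(classifier_trace(times, times * 0, times * 0, 20,
                                         256), ann)
  expect_equal(lat3$missed, 1)
  expect_true(is.na(lat3$mean_latency_s))

  # detection outside the search window does not count
  lab4 <- as.integer(times >= ann$onset_s + 12)
  expect_equal(onset_latency(classifier_trace(times, lab4, lab4, 20, 256),
                             ann, search_window_s = 10)$missed, 1)

  expect_warning(onset_latency(tr, NULL), "no annotations")
})

test_that("overlap percentage is exact for aligned segments", {
  hop_s <- 0.5
  times <- seq_len(40) * hop_s          # 0.5 .. 20 s
  ann <- data.frame(onset_s = 10, offset_s = 14, label = "seizure")
  mk <- function(lab) classifier_trace(times, lab, lab, 128, 256)
  all_on <- rep(1L, 40)
  expect_equal(overlap_percent(mk(all_on), ann)$percent, 100)
  expect_equal(overlap_percent(mk(rep(0L, 40)), ann)$percent, 0)
  # positive during exactly the first half of the 4 s event
  half <- as.integer(times > 10 & times <= 12)
  expect_equal(overlap_percent(mk(half), ann)$percent, 50)
  # zero-duration events are excluded with a warning
  expect_warning(ov <- overlap_percent(mk(all_on),
                                       rbind(ann, data.frame(onset_s = 3,
                                                             offset_s = 3,
                                                             label = "x"))),
                 "zero-duration")
  expect_length(ov$percent, 1)
})

test_that("an event with zero overlap is necessarily missed", {
  times <- seq(0.5, 20, by = 0.5)
  lab <- as.integer(times > 15 & times <= 16)
  tr <- classifier_trace(times, lab, lab, 128, 256)
  ann <- data.frame(onset_s = c(2, 14.5), offset_s = c(4, 16),
                    label = "seizure")
  ov <- overlap_percent(tr, ann)
  expect_equal(ov$percent[1], 0)
  expect_gt(ov$percent[2], 0)
  for (i in 1:2) {
    dur <- ann$offset_s[i] - ann$onset_s[i]
    lat <- onset_latency(tr, ann[i, ], search_window_s = dur)
    expect_equal(lat$missed, if (ov$percent[i] == 0) 1L else 0L)
  }
})

test_that("response maps have the right shape, range and band structure", {
  cfg <- filter_chain_config()
  rm1 <- response_map(cfg, c(5, 14, 50), c(5, 30), repeats = 3, seed = 51)
  expect_equal(dim(rm1$mean_output), c(3, 2))
  expect_true(all(rm1$mean_output >= 0 & rm1$mean_output <= 1))
  # in-band tone beats out-of-band tone at high amplitude
  expect_gt(rm1$mean_output[2, 2], rm1$mean_output[3, 2])
  expect_error(response_map(cfg, c(5, 200), 10), "Nyquist")

  # filter response is (noise-tolerantly) non-decreasing in amplitude in-band
  rm2 <- response_map(cfg, 14, c(2, 5, 10, 20, 40), repeats = 5, seed = 52)
  expect_true(all(diff(as.numeric(rm2$mean_output)) > -0.05))
})

test_that("network response maps run on fitted, raw and quantized models", {
  fit <- fx_fit()
  rm_ <- response_map(fit, c(6, 30), c(10, 30), repeats = 2, seed = 53)
  expect_equal(dim(rm_$mean_output), c(2, 2))
  rq <- response_map(quantize_model(fit$model), c(6, 30), c(10, 30),
                     repeats = 2, seed = 53)
  expect_equal(dim(rq$mean_output), c(2, 2))
  # low-frequency high-amplitude tone drives the trained network hard
  expect_gt(rm_$mean_output[1, 2], 0.8)
})
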