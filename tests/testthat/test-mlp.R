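test_that("initialization produces the documented shapes and counts", {
  m <- init_mlp(20, 8, seed = 1)
  expect_equal(n_parameters(m), 20 * 8 + 8 + 8 * 1 + 1)  # 177
  expect_equal(n_parameters(init_mlp(20, 4, seed = 1)), 89)
  expect_identical(init_mlp(20, 8, seed = 5)$layers,
                   init_mlp(20, 8, seed = 5)$layers)
  expect_false(identical(init_mlp(20, 8, seed = 5)$layers,
                         init_mlp(20, 8, seed = 6)$layers))
  expect_warning(init_mlp(20, integer(0), seed = 1), "single-layer")
  expect_error(init_mlp(0, 8), "window_len")
})

test_that("forward pass matches hand arithmetic on tiny models", {
  # all-zero weights: logistic of 0
  m <- init_mlp(4, 2, seed = 1, input_scale_uV = 1)
  m$layers <- lapply(m$layers, function(l) {
    l$W[] <- 0; l$b[] <- 0; l
  })
  expect_equal(forward(m, c(1, 2, 3, 4)), 0.5)

  # 2-input, 1-hidden-unit, unit weights, zero biases, input (1,1):
  # hidden = relu(2) = 2, output = sigmoid(2)
  m2 <- init_mlp(2, 1, seed = 1, input_scale_uV = 1)
  m2$layers[[1]]$W <- matrix(c(1, 1), 1); m2$layers[[1]]$b <- 0
  m2$layers[[2]]$W <- matrix(1); m2$layers[[2]]$b <- 0
  expect_equal(forward(m2, c(1, 1)), 1 / (1 + exp(-2)), tolerance = 1e-12)

  # scores always inside (0,1)
  m3 <- init_mlp(10, c(6, 3), seed = 2)
  set.seed(3)
  s <- replicate(20, forward(m3, rnorm(10, sd = 30)))
  expect_true(all(s > 0 & s < 1))

  expect_error(forward(m3, rnorm(9)), "window")
})

test_that("convolutional front end reduces to known special cases", {
  # identity impulse kernel, stride 1, linear activation: the head sees the
  # raw (normalized) samples
  cm <- init_cnn(20, n_kernels = 1, kernel_len = 8, stride = 1,
                 hidden_sizes = 2, seed = 4, activation = "linear")
  cm$conv$K[] <- 0; cm$conv$K[1, 1] <- 1; cm$conv$b[] <- 0
  set.seed(5)
  w <- rnorm(20, sd = 10)
  cache <- lfpdetect:::forward_batch(cm, matrix(w, 1), keep_cache = TRUE)$cache
  expect_equal(as.numeric(cache$acts[[1]]),
               (w / cm$input_scale_uV)[1:13], tolerance = 1e-12)

  # zero kernels with zero biases: head input all zero, score 0.5
  cm0 <- init_cnn(20, seed = 6)
  cm0$conv$K[] <- 0; cm0$conv$b[] <- 0
  expect_equal(conv_forward(cm0, w), 0.5)

  expect_error(conv_forward(init_mlp(20, 8, seed = 1), w), "convolutional")
  expect_error(init_cnn(10, kernel_len = 16), "kernel_len")
})

test_that("a matched-filter CNN learns to prefer burst-bearing windows", {
  toy <- fx_toy_dataset()
  cm <- init_cnn(20, n_kernels = 2, kernel_len = 8, stride = 2,
                 hidden_sizes = 4, seed = 7)
  # matched filter: in-phase and quadrature copies of the burst template
  tt <- (0:7) / 256
  cm$conv$K[1, ] <- sin(2 * pi * 14 * tt)
  cm$conv$K[2, ] <- cos(2 * pi * 14 * tt)
  fit <- train_mlp(toy, model = cm,
                   config = train_config(epochs = 1200, batch_size = 120,
                                         learning_rate = 0.05, seed = 8))
  s <- predict(fit, toy$windows)
  expect_gt(mean(s[toy$labels == 1]), mean(s[toy$labels == 0]) + 0.3)
})

test_that("8-bit quantization obeys its range and rounding contracts", {
  fit <- fx_fit()
  q <- quantize_model(fit$model)
  for (i in seq_along(q$layers)) {
    l <- q$layers[[i]]
    expect_true(all(l$W$int >= -128 & l$W$int <= 127))
    expect_true(all(l$b$int >= -128 & l$b$int <= 127))
    expect_true(all(abs(l$W$int * l$W$scale - fit$model$layers[[i]]$W)
                    <= l$W$scale / 2 + 1e-12))
  }
  # all-zero tensor: scale 1, integers 0
  mz <- init_mlp(4, 2, seed = 1)
  mz$layers[[1]]$W[] <- 0
  qz <- quantize_model(mz)
  expect_equal(qz$layers[[1]]$W$scale, 1)
  expect_true(all(qz$layers[[1]]$W$int == 0))
})

test_that("quantized inference stays close to float inference", {
  fit <- fx_fit()
  q <- quantize_model(fit$model)
  set.seed(9)
  X <- matrix(rnorm(1000 * 20, sd = 8), ncol = 20)
  sf <- lfpdetect:::forward_batch(fit$model, X)$score
  sq <- lfpdetect:::forward_batch(lfpdetect:::as_float_model(q), X)$score
  expect_lt(mean(abs(sf - sq)), 0.05)
})

test_that("windowed classification obeys the output-rate and consensus arithmetic", {
  fit <- fx_fit()
  rec <- generate_background(10, 256, 1, seed = 10)   # 2560 samples
  tr <- classify_windows(fit$model, rec)
  expect_length(tr$scores, 128)                        # floor(2560/20)
  expect_equal(tr$hop_samples, 20)
  expect_equal(tr$times_s[1], 20 / 256)
  # output-rate contract for a non-multiple length
  rec2 <- lfp_recording(rnorm(1013), 256)
  expect_length(classify_windows(fit$model, rec2)$scores, floor(1013 / 20))
  # determinism
  expect_identical(tr$scores, classify_windows(fit$model, rec)$scores)
  # too short
  expect_warning(tr0 <- classify_windows(fit$model, lfp_recording(rnorm(5), 256)),
                 "shorter")
  expect_length(tr0$scores, 0)

  # consensus arithmetic
  expect_equal(consensus_adjust(c(1, 0, 1), 3), c(1, 1 / 2, 2 / 3))
  expect_equal(consensus_adjust(rep(0.42, 10), 3), rep(0.42, 10))
  expect_equal(consensus_adjust(c(0.2, 0.4, 0.6, 0.8), 2),
               c(0.2, 0.3, 0.5, 0.7))
})

test_that("strict-vote consensus only fires on unanimity", {
  m <- init_mlp(2, 1, seed = 11, input_scale_uV = 1)
  # force raw scores: amplitude-coded windows through a steep model
  m$layers[[1]]$W <- matrix(c(10, 10), 1); m$layers[[1]]$b <- 0
  m$layers[[2]]$W <- matrix(10); m$layers[[2]]$b <- -5
  rec <- lfp_recording(c(1, 1, 0, 0, 1, 1, 1, 1, 1, 1), 256)
  trv <- classify_windows(m, rec, mode = "votes")
  # first unanimous run of 3 positive raw outputs is windows 3..5
  raw <- attr(trv, "raw_scores")
  v <- as.integer(raw >= 0.5)
  manual <- vapply(seq_along(v), function(k)
    as.integer(all(v[max(1, k - 2):k] == 1)), integer(1))
  expect_equal(trv$labels, manual)
})

test_that("consensus averaging never increases label transitions", {
  set.seed(12)
  for (i in 1:100) {
    s <- runif(sample(10:200, 1))
    th <- runif(1)
    raw_tr <- lfpdetect:::label_transitions(s >= th)
    adj_tr <- lfpdetect:::label_transitions(consensus_adjust(s, 3) >= th)
    expect_lte(adj_tr, raw_tr)
  }
})
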