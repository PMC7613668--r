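#' Initialize a compact windowed MLP
#'
#' Builds the untrained multi-layer perceptron used as the seizure-state
#' classifier: a fixed-length window of raw LFP samples in, a single score
#' in (0, 1) out. Hidden units are rectified-linear, the output unit is
#' logistic. Weights use a scaled-uniform (Glorot) initializer; biases
#' start at zero. Inputs are normalized by a fixed full-scale constant
#' (`input_scale_uV`) rather than per-window statistics, since an implanted
#' device cannot standardize online.
#'
#' @param window_len input samples per window (default 20).
#' @param hidden_sizes integer vector of hidden-layer widths (default 8).
#'   An empty vector yields a single-layer perceptron (warned).
#' @param seed integer seed for the initializer.
#' @param input_scale_uV microvolt amplitude mapped to 1.0 at the input.
#' @return An object of class `mlp_model`.
#' @export
init_mlp <- function(window_len = 20, hidden_sizes = 8, seed = NULL,
                     input_scale_uV = 50) {
  if (window_len < 1) stop_arg("`window_len` must be >= 1")
  if (length(hidden_sizes) == 0) {
    warning("no hidden layers: model degenerates to a single-layer perceptron")
  } else if (any(hidden_sizes < 1)) stop_arg("hidden sizes must be >= 1")
  sizes <- c(window_len, hidden_sizes, 1)
  layers <- with_seed(seed, lapply(seq_len(length(sizes) - 1), function(i) {
    fan_in <- sizes[i]; fan_out <- sizes[i + 1]
    lim <- sqrt(6 / (fan_in + fan_out))
    list(W = matrix(stats::runif(fan_out * fan_in, -lim, lim),
                    nrow = fan_out),
         b = numeric(fan_out))
  }))
  structure(list(window_len = window_len, hidden_sizes = hidden_sizes,
                 conv = NULL, layers = layers,
                 hidden_activation = "relu", output_activation = "sigmoid",
                 input_scale_uV = input_scale_uV),
            class = "mlp_model")
}

#' Initialize an MLP with a convolutional front end
#'
#' Variant that inserts a small 1-D convolution layer (a learned filter
#' bank) between the input window and the dense head. Defaults: 4 kernels
#' of length 8, stride 2.
#'
#' @inheritParams init_mlp
#' @param n_kernels,kernel_len,stride convolution-layer geometry.
#' @param activation convolution-layer activation, `"relu"` or `"linear"`.
#' @return An object of class `mlp_model` with a non-null `conv` component.
#' @export
init_cnn <- function(window_len = 20, n_kernels = 4, kernel_len = 8,
                     stride = 2, hidden_sizes = 8, seed = NULL,
                     input_scale_uV = 50,
                     activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  if (kernel_len > window_len)
    stop_arg("`kernel_len` cannot exceed `window_len`")
  npatch <- floor((window_len - kernel_len) / stride) + 1
  n_feat <- npatch * n_kernels
  model <- with_seed(seed, {
    m <- init_mlp(n_feat, hidden_sizes, seed = NULL,
                  input_scale_uV = input_scale_uV)
    lim <- sqrt(6 / (kernel_len + n_kernels))
    m$conv <- list(K = matrix(stats::runif(n_kernels * kernel_len, -lim, lim),
                              nrow = n_kernels),
                   b = numeric(n_kernels), stride = stride,
                   activation = activation, npatch = npatch)
    m
  })
  model$window_len <- window_len
  model
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

conv_patch_cols <- function(conv, window_len) {
  L <- ncol(conv$K)
  lapply(seq_len(conv$npatch),
         function(p) (p - 1) * conv$stride + seq_len(L))
}

# Batched forward pass. X: n x window_len matrix of raw microvolt windows.
# Returns list(score, cache) where cache holds per-layer activations for
# backpropagation.
forward_batch <- function(model, X, keep_cache = FALSE) {
  if (ncol(X) != model$window_len)
    stop_arg("window length ", ncol(X), " does not match the model's ",
             model$window_len)
  H <- X / model$input_scale_uV
  cache <- list(Z0 = H)
  if (!is.null(model$conv)) {
    cols <- conv_patch_cols(model$conv, model$window_len)
    feats <- vector("list", model$conv$npatch)
    pre <- vector("list", model$conv$npatch)
    for (p in seq_along(cols)) {
      A <- H[, cols[[p]], drop = FALSE] %*% t(model$conv$K)
      A <- sweep(A, 2, model$conv$b, "+")
      pre[[p]] <- A
      feats[[p]] <- if (model$conv$activation == "relu") relu(A) else A
    }
    H <- do.call(cbind, feats)
    if (keep_cache) { cache$conv_pre <- pre; cache$conv_cols <- cols }
  }
  acts <- list(H)
  pres <- list()
  nl <- length(model$layers)
  for (i in seq_len(nl)) {
    A <- H %*% t(model$layers[[i]]$W)
    A <- sweep(A, 2, model$layers[[i]]$b, "+")
    pres[[i]] <- A
    H <- if (i < nl) relu(A) else sigmoid(A)
    acts[[i + 1]] <- H
  }
  if (keep_cache) { cache$acts <- acts; cache$pres <- pres }
  list(score = as.numeric(H), cache = if (keep_cache) cache else NULL)
}

#' Score a single input window
#'
#' Forward pass of the (possibly convolutional) network on one window of
#' raw samples; returns the logistic output in (0, 1).
#'
#' @param model an `mlp_model` or `quantized_mlp`.
#' @param window numeric vector of exactly `window_len` samples (microvolts).
#' @return Scalar score in (0, 1).
#' @export
forward <- function(model, window) {
  model <- as_float_model(model)
  if (length(window) != model$window_len)
    stop_arg("window has ", length(window), " samples; model expects ",
             model$window_len)
  forward_batch(model, matrix(window, nrow = 1))$score
}

#' @rdname forward
#' @export
conv_forward <- function(model, window) {
  m <- as_float_model(model)
  if (is.null(m$conv))
    stop_arg("model has no convolutional front end")
  forward(model, window)
}

#' Post-training 8-bit quantization of network weights
#'
#' Symmetric per-tensor quantization: every weight matrix, bias vector and
#' convolution kernel bank is stored as signed integers with a real scale
#' factor `max(|w|) / (2^(bits-1) - 1)` (an all-zero tensor gets scale 1).
#' Inference dequantizes and computes in real arithmetic.
#'
#' @param model a trained `mlp_model`.
#' @param bits integer word length (default 8).
#' @return An object of class `quantized_mlp`.
#' @export
quantize_model <- function(model, bits = 8) {
  stopifnot(inherits(model, "mlp_model"))
  qmax <- 2^(bits - 1) - 1
  qt <- function(w) {
    s <- max(abs(w)) / qmax
    if (s == 0) s <- 1
    list(int = round(w / s), scale = s)
  }
  out <- unclass(model)
  out$layers <- lapply(model$layers, function(l)
    list(W = qt(l$W), b = qt(l$b)))
  if (!is.null(model$conv)) {
    out$conv$K <- qt(model$conv$K)
    out$conv$b <- qt(model$conv$b)
  }
  out$bits <- bits
  class(out) <- "quantized_mlp"
  out
}

# Reconstruct a float model from a quantized one (int x scale).
as_float_model <- function(model) {
  if (inherits(model, "mlp_model")) return(model)
  stopifnot(inherits(model, "quantized_mlp"))
  dq <- function(t) t$int * t$scale
  out <- unclass(model)
  out$layers <- lapply(model$layers, function(l)
    list(W = dq(l$W), b = as.numeric(dq(l$b))))
  if (!is.null(model$conv)) {
    out$conv$K <- dq(model$conv$K)
    out$conv$b <- as.numeric(dq(model$conv$b))
  }
  out$bits <- NULL
  class(out) <- "mlp_model"
  out
}

#' @export
print.mlp_model <- function(x, ...) {
  topo <- paste(c(x$window_len, x$hidden_sizes, 1), collapse = "-")
  cv <- if (!is.null(x$conv))
    sprintf(" conv(%dx%d, stride %d) +", nrow(x$conv$K), ncol(x$conv$K),
            x$conv$stride) else ""
  cat(sprintf("<mlp_model>%s %s, %d parameters, input scale %g uV\n",
              cv, topo, n_parameters(x), x$input_scale_uV))
  invisible(x)
}

#' @export
print.quantized_mlp <- function(x, ...) {
  topo <- paste(c(x$window_len, x$hidden_sizes, 1), collapse = "-")
  cat(sprintf("<quantized_mlp> %s, %d-bit weights\n", topo, x$bits))
  invisible(x)
}

#' Trainable parameter count of a network
#' @param model an `mlp_model` or `quantized_mlp`.
#' @return Integer number of weights and biases.
#' @export
n_parameters <- function(model) {
  model <- as_float_model(model)
  n <- sum(vapply(model$layers,
                  function(l) length(l$W) + length(l$b), numeric(1)))
  if (!is.null(model$conv))
    n <- n + length(model$conv$K) + length(model$conv$b)
  as.integer(n)
}

#' Consensus smoothing of window scores
#'
#' The "adjusted" output: each raw window score is replaced by the mean of
#' the most recent `consensus` raw scores (the first outputs average the
#' history available so far). Averaging with a positive kernel is
#' variation-diminishing, so thresholding the adjusted score never toggles
#' more often than thresholding the raw score.
#'
#' @param scores numeric vector of raw window scores.
#' @param consensus number of consecutive outputs combined (default 3).
#' @return Numeric vector of adjusted scores, same length.
#' @export
consensus_adjust <- function(scores, consensus = 3) {
  if (consensus < 1) stop_arg("`consensus` must be >= 1")
  n <- length(scores)
  if (n == 0 || consensus == 1) return(scores)
  cs <- cumsum(scores)
  k <- seq_len(n)
  full <- k >= consensus
  out <- numeric(n)
  out[!full] <- cs[!full] / k[!full]
  if (any(full)) {
    i <- k[full]
    out[full] <- (cs[i] - c(0, cs)[i - consensus + 1]) / consensus
  }
  out
}

label_transitions <- function(labels) sum(diff(as.integer(labels)) != 0)

#' Run a windowed network classifier over a recording
#'
#' Splits the recording into non-overlapping windows of `window_len`
#' samples (hop = window length), scores each, applies consensus smoothing,
#' and thresholds. Timestamps are placed at window ends.
#'
#' @param model an `mlp_model` or `quantized_mlp`.
#' @param recording an [lfp_recording] sampled at the model's training rate.
#' @param threshold decision threshold on the adjusted score (ties
#'   positive).
#' @param consensus number of consecutive window scores combined.
#' @param mode `"mean"` (default): threshold the mean of the last
#'   `consensus` raw scores. `"votes"`: strict unanimity of the last
#'   `consensus` raw thresholded labels (scores still report the mean).
#' @return A [classifier_trace()] with `hop_samples = window_len`.
#' @export
classify_windows <- function(model, recording, threshold = 0.5,
                             consensus = 3, mode = c("mean", "votes")) {
  stopifnot(inherits(recording, "lfp_recording"))
  mode <- match.arg(mode)
  fm <- as_float_model(model)
  wl <- fm$window_len
  nw <- floor(length(recording$samples) / wl)
  if (nw == 0) {
    warning("recording shorter than one window; returning empty trace")
    return(classifier_trace(numeric(0), numeric(0), integer(0), wl,
                            recording$fs))
  }
  X <- matrix(recording$samples[seq_len(nw * wl)], nrow = nw, ncol = wl,
              byrow = TRUE)
  raw <- forward_batch(fm, X)$score
  adj <- consensus_adjust(raw, consensus)
  labels <- if (mode == "mean") adj >= threshold else {
    v <- as.integer(raw >= threshold)
    vadj <- consensus_adjust(v, consensus)
    vadj >= 1 - 1e-12
  }
  tr <- classifier_trace((seq_len(nw) * wl) / recording$fs, adj, labels, wl,
                         recording$fs)
  attr(tr, "raw_scores") <- raw
  tr
}
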