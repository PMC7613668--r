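#' Run the floating-point reference filter
#'
#' Applies the biquad cascade section by section in double precision. This
#' is the validation reference for the fixed-point path.
#'
#' @param cascade a `biquad_cascade` (or `fixed_point_cascade`, which is
#'   dequantized first).
#' @param samples numeric input sequence.
#' @return Filtered sequence, same length.
#' @export
filter_float <- function(cascade, samples) {
  if (inherits(cascade, "fixed_point_cascade"))
    cascade <- dequantize_cascade(cascade)
  y <- as.numeric(samples)
  for (s in cascade$sections)
    y <- as.numeric(signal::filter(s$b, s$a, y))
  y * cascade$overall_gain
}

#' Run the fixed-point Direct Form I filter
#'
#' Embedded-faithful integer path: per section, products of 16-bit
#' coefficients and 16-bit signals accumulate in a saturating 32-bit
#' register; the section output is renormalized by an arithmetic right
#' shift with round-half-away-from-zero and clamped to 16 bits before
#' feeding the next section. Saturation events are counted, not raised.
#'
#' @param cascade a `fixed_point_cascade` from [quantize_coefficients()].
#' @param samples integer input samples, each within the signed 16-bit range.
#' @return Integer output sequence with attribute `"saturations"` giving the
#'   number of saturation events observed.
#' @export
filter_fixed <- function(cascade, samples) {
  stopifnot(inherits(cascade, "fixed_point_cascade"))
  if (any(abs(samples) > 32767))
    stop_arg("input samples must be representable in 16-bit signed")
  if (any(samples != round(samples)))
    stop_arg("input samples must be integers (quantize first)")
  res <- df1_cascade_fixed_cpp(as.integer(samples),
                               matrix(as.integer(cascade$coef_int), nrow = 5),
                               cascade$shift)
  structure(res$y, saturations = res$saturations)
}

# Worst-case output error of the fixed-point cascade relative to the float
# reference run with the *quantized* coefficient values, in output LSBs.
# Each section's shift-rounding injects at most 1/2 LSB per sample at its
# output; that error recirculates through the section's own feedback (1/A_i)
# and passes through every downstream section, so its contribution is
# bounded by 0.5 * ||h_i||_1 where h_i is the impulse response of
# (1/A_i) * prod_{j>i} H_j. Summed over sections.
fixed_point_error_bound <- function(cascade, n_ir = 4096) {
  stopifnot(inherits(cascade, "fixed_point_cascade"))
  fl <- dequantize_cascade(cascade)
  S <- length(fl$sections)
  imp <- c(1, numeric(n_ir - 1))
  total <- 0
  for (i in seq_len(S)) {
    h <- as.numeric(signal::filter(1, fl$sections[[i]]$a, imp))
    if (i < S) for (j in (i + 1):S) {
      s <- fl$sections[[j]]
      h <- as.numeric(signal::filter(s$b, s$a, h))
    }
    total <- total + 0.5 * sum(abs(h))
  }
  total
}

#' Rectified exponential-moving-average envelope
#'
#' Folds absolute-value rectification into a first-order smoother:
#' `y[n] = y[n-1] + (|x[n]| - y[n-1]) / decay_samples`, with `y[0]`
#' starting from 0. With the default decay of 32 samples the smoothing
#' factor is 1/32 (one right shift in the fixed-point path).
#'
#' @param samples input sequence (any sign; rectified internally).
#' @param decay_samples decay coefficient, at least 1.
#' @return Envelope sequence, same length.
#' @export
envelope_ema <- function(samples, decay_samples = 32) {
  if (decay_samples < 1) stop_arg("`decay_samples` must be >= 1")
  d <- decay_samples
  as.numeric(stats::filter(abs(samples) / d, 1 - 1 / d, method = "recursive"))
}

# Fixed-point envelope: integer input LSBs in, envelope in LSB units out
# (state held with 15 fractional bits in a 32-bit register).
envelope_ema_fixed <- function(samples_int, decay_samples = 32) {
  ema_envelope_fixed_cpp(as.integer(samples_int), as.integer(decay_samples),
                         15L)
}

#' Construct a classifier trace
#'
#' Time-aligned classifier output: timestamps, real-valued scores and
#' binary labels, one row per classifier output, plus the output interval
#' in input samples.
#'
#' @param times_s output timestamps in seconds (strictly increasing).
#' @param scores real-valued detector output.
#' @param labels binary decisions (0/1).
#' @param hop_samples input samples per output (1 for the filter chain,
#'   the window length for the windowed networks).
#' @param fs input sampling rate in Hz.
#' @return An object of class `classifier_trace`.
#' @export
classifier_trace <- function(times_s, scores, labels, hop_samples, fs) {
  stopifnot(length(times_s) == length(scores),
            length(scores) == length(labels))
  if (length(times_s) > 1 && any(diff(times_s) <= 0))
    stop_arg("`times_s` must be strictly increasing")
  structure(list(times_s = as.numeric(times_s), scores = as.numeric(scores),
                 labels = as.integer(labels != 0),
                 hop_samples = hop_samples, fs = fs),
            class = "classifier_trace")
}

#' @export
print.classifier_trace <- function(x, ...) {
  cat(sprintf(paste0("<classifier_trace> %d outputs (hop %d sample(s) @ %g ",
                     "Hz), %.1f%% positive\n"),
              length(x$times_s), x$hop_samples, x$fs,
              100 * mean(x$labels)))
  invisible(x)
}

#' @export
plot.classifier_trace <- function(x, ...) {
  graphics::plot(x$times_s, x$scores, type = "l", xlab = "time (s)",
                 ylab = "score", ...)
  pos <- x$labels == 1
  if (any(pos))
    graphics::points(x$times_s[pos], x$scores[pos], col = "red", pch = ".",
                     cex = 2)
  invisible(x)
}

#' Run the band-power filter-chain classifier over a recording
#'
#' The full baseline detector: band-pass filter, absolute-value
#' rectification, exponential-moving-average envelope, threshold. Produces
#' one output per input sample (`hop_samples = 1`); scores are envelope
#' values in microvolts, labels are `envelope >= threshold` (ties positive).
#'
#' @param recording an [lfp_recording] at the configured sampling rate
#'   (resample first with [resample_recording()] otherwise).
#' @param config a [filter_chain_config()].
#' @param arithmetic `"fixed"` (default; embedded-faithful integer path
#'   after quantizing input against `input_full_scale_uV`) or `"float"`
#'   (reference path in microvolts).
#' @return A [classifier_trace()]; in the fixed path the attribute
#'   `"saturations"` carries the saturation-event count.
#' @export
classify_filter <- function(recording, config = filter_chain_config(),
                            arithmetic = c("fixed", "float")) {
  stopifnot(inherits(recording, "lfp_recording"),
            inherits(config, "filter_chain_config"))
  arithmetic <- match.arg(arithmetic)
  if (abs(recording$fs - config$fs) > 1e-9)
    stop_arg("recording is sampled at ", recording$fs, " Hz but the chain ",
             "expects ", config$fs,
             " Hz; resample first with resample_recording()")
  cascade <- design_bandpass(config)
  nsat <- 0L
  if (arithmetic == "fixed") {
    fp <- quantize_coefficients(cascade)
    lsb <- config$input_full_scale_uV / 32767
    xi <- pmin(32767, pmax(-32768, round(recording$samples / lsb)))
    yf <- filter_fixed(fp, xi)
    nsat <- attr(yf, "saturations")
    env <- envelope_ema_fixed(yf, config$ema_decay_samples) * lsb
  } else {
    y <- filter_float(cascade, recording$samples)
    env <- envelope_ema(y, config$ema_decay_samples)
  }
  tr <- classifier_trace(sample_times(length(env), config$fs), env,
                         env >= config$threshold, 1L, config$fs)
  attr(tr, "saturations") <- nsat
  tr
}
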