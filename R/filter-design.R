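#' Filter-chain configuration
#'
#' Parameters of the baseline band-power detector: an 8-22 Hz 4th-order
#' Butterworth band-pass (Direct Form I, 16-bit coefficients, 32-bit
#' accumulators), absolute-value rectification, an exponential moving
#' average envelope with a 32-sample decay coefficient, and a fixed
#' threshold, all at a 256 Hz sampling rate.
#'
#' @param low_hz,high_hz band edges in Hz (half-power points).
#' @param order total transfer-function order of the band-pass (must be
#'   even; 4 gives two biquad sections). An order-per-edge reading of a
#'   "4th-order band-pass" corresponds to `order = 8`.
#' @param fs sampling rate in Hz.
#' @param ema_decay_samples envelope decay coefficient: the smoothing factor
#'   is `1/ema_decay_samples` (a single right shift in fixed point when it
#'   is a power of two).
#' @param threshold detection threshold in envelope units (microvolts). The
#'   default suits the package's synthetic amplitude scales (1 uVrms
#'   background vs 10 uVrms events).
#' @param input_full_scale_uV amplitude mapped to digital full scale
#'   (32767) when quantizing input for the fixed-point path.
#' @return An object of class `filter_chain_config`.
#' @export
filter_chain_config <- function(low_hz = 8, high_hz = 22, order = 4,
                                fs = 256, ema_decay_samples = 32,
                                threshold = 2.5,
                                input_full_scale_uV = 50) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop_arg("band edges must satisfy 0 < low_hz < high_hz < fs/2")
  if (order < 2 || order %% 2 != 0)
    stop_arg("`order` must be a positive even integer")
  if (ema_decay_samples < 1) stop_arg("`ema_decay_samples` must be >= 1")
  check_positive(input_full_scale_uV, "input_full_scale_uV")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order, fs = fs,
                 ema_decay_samples = ema_decay_samples, threshold = threshold,
                 input_full_scale_uV = input_full_scale_uV),
            class = "filter_chain_config")
}

#' @export
print.filter_chain_config <- function(x, ...) {
  cat(sprintf(paste0("<filter_chain_config> %g-%g Hz order-%d Butterworth @ ",
                     "%g Hz, EMA decay %d samples, threshold %g uV\n"),
              x$low_hz, x$high_hz, x$order, x$fs, x$ema_decay_samples,
              x$threshold))
  invisible(x)
}

#' Design the Butterworth band-pass as a biquad cascade
#'
#' Designs the digital Butterworth band-pass (bilinear transform with
#' pre-warped band edges, via [signal::butter()]) and factors it into
#' second-order sections. Zeros are split so every section is itself a
#' band-pass (`b = g * (1, 0, -1)`); the overall gain is distributed so
#' that each cascade prefix has unit peak magnitude, keeping intermediate
#' fixed-point signals inside the 16-bit word.
#'
#' @param config a [filter_chain_config()].
#' @return An object of class `biquad_cascade`: a list of sections, each
#'   with numerator `b` (length 3) and denominator `a = c(1, a1, a2)`.
#' @export
design_bandpass <- function(config) {
  stopifnot(inherits(config, "filter_chain_config"))
  nsec <- config$order / 2
  fl <- config$low_hz / (config$fs / 2)
  fh <- config$high_hz / (config$fs / 2)
  ba <- signal::butter(nsec, c(fl, fh), type = "pass")
  k <- ba$b[1]
  poles <- polyroot(rev(ba$a))
  if (any(Mod(poles) >= 1))
    stop_arg("designed filter is unstable; check band edges and order")
  pairs <- pair_poles(poles)
  # unscaled band-pass sections b = (1, 0, -1); distribute gain so each
  # cascade prefix peaks at 1 (evaluated on a fine frequency grid)
  f <- seq(0.5, config$fs / 2 - 0.5, by = 0.25)
  sections <- lapply(pairs, function(a) list(b = c(1, 0, -1), a = c(1, a)))
  prefix <- rep(1 + 0i, length(f))
  gains <- numeric(nsec)
  for (i in seq_len(nsec)) {
    H <- section_response(sections[[i]], f, config$fs)
    if (i < nsec) {
      gains[i] <- 1 / max(Mod(prefix * H))
      prefix <- prefix * H * gains[i]
    } else {
      gains[i] <- k / prod(gains[seq_len(i - 1)])
    }
  }
  for (i in seq_len(nsec)) sections[[i]]$b <- sections[[i]]$b * gains[i]
  structure(list(sections = sections, overall_gain = 1, fs = config$fs,
                 config = config),
            class = "biquad_cascade")
}

# Group the poles of the overall transfer function into conjugate pairs,
# returning per-section denominator coefficients c(a1, a2).
pair_poles <- function(poles, tol = 1e-8) {
  cplx <- poles[Im(poles) > tol]
  realp <- sort(Re(poles[abs(Im(poles)) <= tol]))
  pairs <- lapply(cplx[order(-Mod(cplx))],
                  function(p) c(-2 * Re(p), Mod(p)^2))
  while (length(realp) >= 2) {
    p1 <- realp[1]; p2 <- realp[length(realp)]
    realp <- realp[-c(1, length(realp))]
    pairs <- c(pairs, list(c(-(p1 + p2), p1 * p2)))
  }
  if (length(realp) == 1)
    stop_arg("odd number of real poles; cannot form biquad sections")
  pairs
}

section_response <- function(section, f, fs) {
  z1 <- exp(-2i * pi * f / fs)
  (section$b[1] + section$b[2] * z1 + section$b[3] * z1^2) /
    (section$a[1] + section$a[2] * z1 + section$a[3] * z1^2)
}

#' Complex frequency response of a biquad cascade
#'
#' @param cascade a `biquad_cascade` or `fixed_point_cascade`.
#' @param f frequencies in Hz.
#' @return Complex response at each frequency.
#' @export
cascade_response <- function(cascade, f) {
  if (inherits(cascade, "fixed_point_cascade")) cascade <- dequantize_cascade(cascade)
  H <- rep(1 + 0i, length(f))
  for (s in cascade$sections) H <- H * section_response(s, f, cascade$fs)
  H * cascade$overall_gain
}

# Locate the two half-power (-3 dB) frequencies of a band-pass cascade by
# root finding on |H|^2 - 1/2 around the peak.
half_power_edges <- function(cascade) {
  fs <- cascade$fs
  f <- seq(0.05, fs / 2 - 0.05, by = 0.01)
  mag2 <- Mod(cascade_response(cascade, f))^2
  ipk <- which.max(mag2)
  g <- function(x) Mod(cascade_response(cascade, x))^2 - 0.5
  lo_i <- max(which(mag2[seq_len(ipk)] < 0.5))
  hi_i <- ipk - 1 + min(which(mag2[ipk:length(f)] < 0.5))
  lo <- stats::uniroot(g, c(f[lo_i], f[ipk]), tol = 1e-8)$root
  hi <- stats::uniroot(g, c(f[ipk], f[hi_i]), tol = 1e-8)$root
  c(low_hz = lo, high_hz = hi)
}

#' @export
print.biquad_cascade <- function(x, ...) {
  edges <- half_power_edges(x)
  cat(sprintf("<biquad_cascade> %d section(s) @ %g Hz, -3 dB at %.2f / %.2f Hz\n",
              length(x$sections), x$fs, edges[1], edges[2]))
  for (i in seq_along(x$sections)) {
    s <- x$sections[[i]]
    cat(sprintf("  [%d] b = (%+.5f, %+.5f, %+.5f)  a = (1, %+.5f, %+.5f)\n",
                i, s$b[1], s$b[2], s$b[3], s$a[2], s$a[3]))
  }
  invisible(x)
}

#' Quantize a biquad cascade to fixed-point coefficients
#'
#' Rounds every coefficient to the nearest representable value in a signed
#' Q-format with `coeff_bits` total bits (default Q2.13 in 16 bits: the
#' coefficients of a stable biquad fit in +/-4). Checks range and
#' post-quantization stability.
#'
#' @param cascade a `biquad_cascade` from [design_bandpass()].
#' @param coeff_bits coefficient word length (default 16).
#' @param frac_bits fractional bits of the Q-format (default
#'   `coeff_bits - 3`, i.e. Q2.13 for 16 bits).
#' @return An object of class `fixed_point_cascade` holding integer
#'   coefficient sets, the per-section right-shift amount, and word sizes.
#' @export
quantize_coefficients <- function(cascade, coeff_bits = 16,
                                  frac_bits = coeff_bits - 3) {
  stopifnot(inherits(cascade, "biquad_cascade"))
  q <- 2^frac_bits
  lim <- c(-2^(coeff_bits - 1), 2^(coeff_bits - 1) - 1)
  coef <- sapply(cascade$sections,
                 function(s) c(s$b[1], s$b[2], s$b[3], s$a[2], s$a[3]))
  coef <- matrix(coef, nrow = 5)
  ints <- round(coef * q)
  for (s in seq_len(ncol(ints))) {
    if (any(ints[, s] < lim[1] | ints[, s] > lim[2]))
      stop_arg("section ", s, " has a coefficient outside the Q",
               coeff_bits - 1 - frac_bits, ".", frac_bits, " range")
    a1 <- ints[4, s] / q; a2 <- ints[5, s] / q
    if (!(abs(a2) < 1 && abs(a1) < 1 + a2))
      stop_arg("section ", s, " became unstable after quantization")
  }
  structure(list(coef_int = ints, shift = frac_bits, coeff_bits = coeff_bits,
                 accum_bits = 32, fs = cascade$fs, config = cascade$config),
            class = "fixed_point_cascade")
}

# Rebuild a float cascade from quantized integers (for response evaluation
# and as the rounding-noise-free reference).
dequantize_cascade <- function(fp) {
  stopifnot(inherits(fp, "fixed_point_cascade"))
  q <- 2^fp$shift
  sections <- lapply(seq_len(ncol(fp$coef_int)), function(s) {
    v <- fp$coef_int[, s] / q
    list(b = v[1:3], a = c(1, v[4], v[5]))
  })
  structure(list(sections = sections, overall_gain = 1, fs = fp$fs,
                 config = fp$config),
            class = "biquad_cascade")
}

#' @export
print.fixed_point_cascade <- function(x, ...) {
  cat(sprintf("<fixed_point_cascade> %d section(s), Q%d.%d coefficients, %d-bit accumulators\n",
              ncol(x$coef_int), x$coeff_bits - 1 - x$shift, x$shift,
              x$accum_bits))
  invisible(x)
}
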