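#' ROC curve by threshold sweep
#'
#' Sweeps the decision threshold over the unique score values and computes
#' the true- and false-positive rate at each, with the area under the
#' curve by trapezoidal integration. The endpoints (0,0) and (1,1) are
#' always included.
#'
#' @param scores real-valued classifier output, one per output timestep.
#' @param truth_labels binary ground truth of the same length, derived
#'   from annotations at the classifier's output timestamps (see
#'   [trace_truth()]); must contain both classes.
#' @return An object of class `roc_curve` with `thresholds`, `tpr`, `fpr`
#'   and `auroc`.
#' @export
roc_curve <- function(scores, truth_labels) {
  truth_labels <- as.integer(truth_labels != 0)
  if (length(scores) != length(truth_labels))
    stop_arg("`scores` and `truth_labels` must have equal length")
  npos <- sum(truth_labels == 1); nneg <- sum(truth_labels == 0)
  if (npos == 0 || nneg == 0)
    stop_arg("`truth_labels` must contain both classes; AUROC is undefined")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth_labels[ord]
  # cumulative counts at each unique score value (predict positive when
  # score >= threshold)
  last <- cumsum(!duplicated(s, fromLast = FALSE))
  keep <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(y)[keep]; fp <- cumsum(1 - y)[keep]
  thresholds <- c(Inf, s[keep])
  tpr <- c(0, tp / npos); fpr <- c(0, fp / nneg)
  if (tpr[length(tpr)] != 1 || fpr[length(fpr)] != 1) {
    tpr <- c(tpr, 1); fpr <- c(fpr, 1); thresholds <- c(thresholds, -Inf)
  }
  auroc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr,
                 auroc = auroc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d operating points, AUROC %.4f\n",
              length(x$thresholds), x$auroc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "false positive rate", ylab = "true positive rate",
                 ...)
  graphics::abline(0, 1, lty = 3)
  graphics::legend("bottomright", sprintf("AUROC = %.3f", x$auroc),
                   bty = "n")
  invisible(x)
}

#' Ground truth at a classifier's output timestamps
#'
#' Binary truth per trace output: 1 when the output timestamp falls inside
#' an annotated event (half-open intervals).
#'
#' @param trace a [classifier_trace()].
#' @param annotations annotation data frame (`onset_s`, `offset_s`,
#'   `label`).
#' @return Integer vector of 0/1, one per trace output.
#' @export
trace_truth <- function(trace, annotations) {
  stopifnot(inherits(trace, "classifier_trace"))
  ann <- normalize_annotations(annotations, Inf)
  as.integer(annotation_mask(trace$times_s, ann))
}

#' Detection latency at event onsets
#'
#' For each annotated event, the latency is the time of the first positive
#' classifier output within `[onset, onset + search_window_s]`, minus the
#' onset. Events with no positive output in that window count as missed;
#' the mean is over detected events only.
#'
#' @param trace a [classifier_trace()].
#' @param annotations annotation data frame sharing the trace's time base.
#' @param search_window_s how far past the onset to search (default 10 s).
#' @return An object of class `latency_result`: per-event table
#'   (`onset_s`, `detected`, `latency_s`), `missed` count and
#'   `mean_latency_s` (`NA` when nothing was detected).
#' @export
onset_latency <- function(trace, annotations, search_window_s = 10) {
  stopifnot(inherits(trace, "classifier_trace"))
  ann <- normalize_annotations(annotations, Inf)
  if (nrow(ann) == 0) {
    warning("no annotations; empty latency result")
    return(structure(list(events = data.frame(onset_s = numeric(0),
                                              detected = logical(0),
                                              latency_s = numeric(0)),
                          missed = 0L, mean_latency_s = NA_real_),
                     class = "latency_result"))
  }
  lat <- rep(NA_real_, nrow(ann))
  for (i in seq_len(nrow(ann))) {
    o <- ann$onset_s[i]
    hit <- which(trace$labels == 1 & trace$times_s >= o &
                   trace$times_s <= o + search_window_s)
    if (length(hit)) lat[i] <- trace$times_s[hit[1]] - o
  }
  detected <- !is.na(lat)
  structure(list(events = data.frame(onset_s = ann$onset_s,
                                     detected = detected, latency_s = lat),
                 missed = sum(!detected),
                 mean_latency_s = if (any(detected))
                   mean(lat[detected]) else NA_real_),
            class = "latency_result")
}

#' @export
print.latency_result <- function(x, ...) {
  cat(sprintf("<latency_result> %d event(s), %d missed, mean latency %s\n",
              nrow(x$events), x$missed,
              if (is.na(x$mean_latency_s)) "-"
              else sprintf("%.3f s", x$mean_latency_s)))
  invisible(x)
}

#' Overlap between positive classifier output and labeled events
#'
#' Per event: 100 x (time inside the event during which the trace is
#' positive) / (event duration). Trace labels are held piecewise-constant
#' over each output's hop interval.
#'
#' @param trace a [classifier_trace()].
#' @param annotations annotation data frame sharing the trace's time base.
#' @return An object of class `overlap_result`: per-event `percent` values
#'   in \[0, 100\] and a decile histogram (`hist_counts`, `hist_breaks`).
#' @export
overlap_percent <- function(trace, annotations) {
  stopifnot(inherits(trace, "classifier_trace"))
  ann <- as.data.frame(annotations)
  dur <- ann$offset_s - ann$onset_s
  if (any(dur <= 0)) {
    warning("excluding ", sum(dur <= 0), " zero-duration event(s)")
    ann <- ann[dur > 0, , drop = FALSE]
    dur <- dur[dur > 0]
  }
  hop_s <- trace$hop_samples / trace$fs
  seg_end <- trace$times_s
  seg_start <- seg_end - hop_s
  pos <- trace$labels == 1
  pct <- vapply(seq_len(nrow(ann)), function(i) {
    ov <- pmin(seg_end[pos], ann$offset_s[i]) -
      pmax(seg_start[pos], ann$onset_s[i])
    100 * sum(pmax(ov, 0)) / dur[i]
  }, numeric(1))
  pct <- pmin(100, pmax(0, pct))
  h <- graphics::hist(pct, breaks = seq(0, 100, by = 10), plot = FALSE)
  structure(list(percent = pct, hist_counts = h$counts,
                 hist_breaks = h$breaks),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> %d event(s), mean overlap %.1f%%\n",
              length(x$percent),
              if (length(x$percent)) mean(x$percent) else NA))
  invisible(x)
}

#' Frequency-amplitude response map of a classifier
#'
#' The interpretation experiment: present 1-second sinusoidal test tones
#' over fresh background noise at every (frequency, amplitude) grid point,
#' `repeats` times each with random phase and noise, and record the mean
#' classifier output. For the filter chain the output is the peak envelope
#' during the tone normalized to \[0, 1\] by the envelope a full-scale
#' rectified sinusoid settles to (`2/pi * input_full_scale_uV`); for the
#' networks it is the mean consensus-adjusted score.
#'
#' @param classifier a [filter_chain_config()], `mlp_model`,
#'   `quantized_mlp` or `mlp_fit`.
#' @param freqs_hz tone frequencies (all below Nyquist).
#' @param amps_uV tone peak amplitudes in microvolts.
#' @param repeats tones averaged per grid point (default 10).
#' @param seed integer seed.
#' @param fs sampling rate (networks; the filter chain uses its config).
#' @param background_rms_uV background noise rms under each tone.
#' @param consensus consensus length for network classifiers.
#' @param ... passed to methods.
#' @return An object of class `response_map`: `freqs_hz`, `amps_uV`,
#'   `mean_output` (matrix, frequencies x amplitudes, entries in \[0, 1\])
#'   and `repeats`.
#' @export
response_map <- function(classifier, freqs_hz, amps_uV, repeats = 10,
                         seed = NULL, ...) {
  UseMethod("response_map")
}

response_map_grid <- function(score_tone, freqs_hz, amps_uV, repeats, seed,
                              fs, background_rms_uV) {
  if (any(freqs_hz >= fs / 2))
    stop_arg("all test frequencies must be below the Nyquist rate fs/2")
  M <- matrix(NA_real_, length(freqs_hz), length(amps_uV),
              dimnames = list(signif(freqs_hz, 4), signif(amps_uV, 4)))
  ctr <- 0
  for (fi in seq_along(freqs_hz)) for (ai in seq_along(amps_uV)) {
    vals <- vapply(seq_len(repeats), function(r) {
      ctr <<- ctr + 1
      tone <- generate_test_tone(freqs_hz[fi], amps_uV[ai], 1, fs,
                                 phase = NULL,
                                 background_rms_uV = background_rms_uV,
                                 seed = derive_seed(seed, ctr))
      score_tone(tone)
    }, numeric(1))
    M[fi, ai] <- mean(vals)
  }
  M[] <- pmin(1, pmax(0, M))
  structure(list(freqs_hz = freqs_hz, amps_uV = amps_uV,
                 mean_output = M, repeats = repeats),
            class = "response_map")
}

#' @rdname response_map
#' @export
response_map.filter_chain_config <- function(classifier, freqs_hz, amps_uV,
                                             repeats = 10, seed = NULL,
                                             background_rms_uV = 1, ...) {
  ref_env <- (2 / pi) * classifier$input_full_scale_uV
  score_tone <- function(tone) {
    tr <- classify_filter(tone, classifier)
    min(1, max(tr$scores) / ref_env)
  }
  response_map_grid(score_tone, freqs_hz, amps_uV, repeats, seed,
                    classifier$fs, background_rms_uV)
}

#' @rdname response_map
#' @export
response_map.mlp_model <- function(classifier, freqs_hz, amps_uV,
                                   repeats = 10, seed = NULL, fs = 256,
                                   background_rms_uV = 1, consensus = 3,
                                   ...) {
  score_tone <- function(tone) {
    tr <- classify_windows(classifier, tone, consensus = consensus)
    mean(tr$scores)
  }
  response_map_grid(score_tone, freqs_hz, amps_uV, repeats, seed, fs,
                    background_rms_uV)
}

#' @rdname response_map
#' @export
response_map.quantized_mlp <- response_map.mlp_model

#' @rdname response_map
#' @export
response_map.mlp_fit <- function(classifier, freqs_hz, amps_uV,
                                 repeats = 10, seed = NULL, ...) {
  response_map(classifier$model, freqs_hz, amps_uV, repeats, seed, ...)
}

#' @export
print.response_map <- function(x, ...) {
  cat(sprintf("<response_map> %d freqs x %d amps, %d repeats, output range [%.3f, %.3f]\n",
              length(x$freqs_hz), length(x$amps_uV), x$repeats,
              min(x$mean_output), max(x$mean_output)))
  invisible(x)
}

#' @export
plot.response_map <- function(x, ...) {
  graphics::image(x = x$freqs_hz, y = x$amps_uV, z = x$mean_output,
                  xlab = "test frequency (Hz)",
                  ylab = "test amplitude (uV)",
                  main = "mean classifier output", zlim = c(0, 1), ...)
  invisible(x)
}
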