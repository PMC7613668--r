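#' Construct a single-channel LFP recording
#'
#' The basic data container used throughout the package: a uniformly sampled
#' amplitude sequence in microvolts, its sampling rate, and optional interval
#' annotations marking events (half-open intervals `[onset_s, offset_s)` in
#' seconds from record start).
#'
#' @param samples numeric vector of amplitudes in microvolts.
#' @param fs sampling rate in Hz.
#' @param annotations data frame with columns `onset_s`, `offset_s`, `label`,
#'   or `NULL` for none. Annotations must be non-overlapping, sorted by onset
#'   and contained within the record duration.
#' @return An object of class `lfp_recording`.
#' @export
lfp_recording <- function(samples, fs, annotations = NULL) {
  check_positive(fs, "fs")
  samples <- as.numeric(samples)
  if (anyNA(samples)) stop_arg("`samples` must not contain NA")
  ann <- normalize_annotations(annotations, length(samples) / fs)
  structure(list(samples = samples, fs = fs, annotations = ann),
            class = "lfp_recording")
}

normalize_annotations <- function(annotations, duration_s) {
  if (is.null(annotations) || nrow(as.data.frame(annotations)) == 0L) {
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  ann <- as.data.frame(annotations)
  req <- c("onset_s", "offset_s")
  if (!all(req %in% names(ann)))
    stop_arg("annotations need columns onset_s, offset_s")
  if (is.null(ann$label)) ann$label <- "seizure"
  ann <- ann[order(ann$onset_s), c("onset_s", "offset_s", "label")]
  rownames(ann) <- NULL
  if (any(ann$onset_s < 0) || any(ann$offset_s <= ann$onset_s))
    stop_arg("each annotation must satisfy 0 <= onset_s < offset_s")
  if (any(ann$offset_s > duration_s + 1e-9))
    stop_arg("annotation extends past the end of the recording")
  if (nrow(ann) > 1L &&
      any(ann$onset_s[-1L] < ann$offset_s[-nrow(ann)] - 1e-12))
    stop_arg("annotations must be non-overlapping")
  ann
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d samples @ %g Hz (%.1f s), %d annotation(s)\n",
              length(x$samples), x$fs, duration_s(x), nrow(x$annotations)))
  if (length(x$samples))
    cat(sprintf("  rms %.3g uV, range [%.3g, %.3g] uV\n",
                signal_rms(x$samples), min(x$samples), max(x$samples)))
  invisible(x)
}

#' Recording duration in seconds
#' @param recording an `lfp_recording`.
#' @return Duration in seconds.
#' @export
duration_s <- function(recording) length(recording$samples) / recording$fs

signal_rms <- function(x) sqrt(mean(x^2))

# Time stamp of sample i (1-based): the instant the sample was taken.
sample_times <- function(n, fs) (seq_len(n) - 1) / fs

# Logical mask: which of the given times fall inside any annotation
# (half-open [onset, offset)).
annotation_mask <- function(times_s, annotations) {
  inside <- rep(FALSE, length(times_s))
  if (nrow(annotations) == 0L) return(inside)
  for (i in seq_len(nrow(annotations))) {
    inside <- inside | (times_s >= annotations$onset_s[i] &
                          times_s < annotations$offset_s[i])
  }
  inside
}
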