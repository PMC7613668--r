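#' Generate pink-noise background activity
#'
#' Produces the inter-ictal baseline used throughout: Gaussian noise with a
#' 1/f power spectrum (the standard first approximation to background LFP),
#' scaled to a requested root-mean-square amplitude. The DC bin is zeroed.
#'
#' @param duration_s duration in seconds.
#' @param fs sampling rate in Hz (default 256).
#' @param rms_uV target rms amplitude in microvolts.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return An [lfp_recording] with no annotations.
#' @export
generate_background <- function(duration_s, fs = 256, rms_uV = 1, seed = NULL) {
  check_positive(duration_s, "duration_s")
  check_positive(fs, "fs")
  if (!is.numeric(rms_uV) || rms_uV < 0) stop_arg("`rms_uV` must be >= 0")
  n <- round(duration_s * fs)
  x <- with_seed(seed, pink_noise(n, fs))
  r <- signal_rms(x)
  if (rms_uV == 0 || r == 0) x <- numeric(n) else x <- x * (rms_uV / r)
  lfp_recording(x, fs)
}

# White Gaussian noise shaped to a 1/f amplitude-squared spectrum in the
# frequency domain. Unit scale; callers renormalize to the requested rms.
pink_noise <- function(n, fs) {
  if (n == 0L) return(numeric(0))
  w <- stats::rnorm(n)
  if (n == 1L) return(w)
  X <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n       # two-sided frequency axis
  g <- ifelse(f > 0, 1 / sqrt(f), 0) # amplitude ~ f^(-1/2) => power ~ 1/f
  Re(stats::fft(X * g, inverse = TRUE)) / n
}

#' Generate an epileptiform burst waveform
#'
#' Returns an amplitude-tapered oscillatory burst emulating an epileptiform
#' discharge. Two templates are available: `"spikewave"`, a sawtooth-like
#' fundamental (default 4 Hz) with phase-locked harmonics whose energy
#' overlaps the 8-22 Hz detector band; and `"narrowband"`, a sinusoid at a
#' frequency drawn inside `band_hz`. A raised-cosine taper smooths onset and
#' offset; the whole burst is scaled to the requested rms.
#'
#' @param duration_s burst duration in seconds (taper included).
#' @param fs sampling rate in Hz.
#' @param rms_uV target rms over the whole burst, in microvolts; 0 gives an
#'   all-zero sequence.
#' @param band_hz scalar center frequency or `c(low, high)` range for the
#'   burst energy (used directly by the narrowband template; the spike-wave
#'   template caps its harmonics at the band's upper edge).
#' @param seed integer seed.
#' @param template `"spikewave"` or `"narrowband"`.
#' @param f0_hz spike-wave fundamental frequency (default 4 Hz).
#' @param taper_s raised-cosine taper length at each end, seconds.
#' @return Numeric vector of `round(duration_s * fs)` samples, in microvolts.
#' @export
generate_event <- function(duration_s, fs = 256, rms_uV = 10,
                           band_hz = c(8, 22), seed = NULL,
                           template = c("spikewave", "narrowband"),
                           f0_hz = 4, taper_s = 0.5) {
  check_positive(duration_s, "duration_s")
  check_positive(fs, "fs")
  template <- match.arg(template)
  if (any(band_hz <= 0) || any(band_hz >= fs / 2))
    stop_arg("`band_hz` must lie strictly inside (0, fs/2)")
  n <- round(duration_s * fs)
  if (rms_uV == 0) return(numeric(n))
  t <- sample_times(n, fs)
  x <- with_seed(seed, {
    if (template == "spikewave") {
      f_hi <- max(band_hz)
      n_harm <- max(1L, floor(f_hi / f0_hz))
      phi <- stats::runif(1, 0, 2 * pi)
      v <- numeric(n)
      for (h in seq_len(n_harm))
        v <- v + sin(2 * pi * h * f0_hz * t + h * phi) / h
      v
    } else {
      f <- if (length(band_hz) == 2L) stats::runif(1, band_hz[1], band_hz[2])
           else band_hz[1]
      sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
    }
  })
  x <- x * raised_cosine_taper(n, fs, taper_s)
  r <- signal_rms(x)
  if (r == 0) return(numeric(n))
  x * (rms_uV / r)
}

raised_cosine_taper <- function(n, fs, taper_s) {
  w <- rep(1, n)
  m <- min(round(taper_s * fs), floor(n / 2))
  if (m > 0L) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(m) - 0.5) / m))
    w[seq_len(m)] <- ramp
    w[n + 1L - seq_len(m)] <- ramp
  }
  w
}

#' Synthetic-recording configuration
#'
#' Bundles the parameters of [synthesize_recording()]. Defaults reflect the
#' amplitude scales of the clinical setting emulated here: ~1 uVrms
#' background activity against ~10 uVrms epileptiform discharges, with
#' events a few seconds to tens of seconds long and rare (about 1.25 per
#' hour, i.e. ~30 events in 24 h of recording).
#'
#' @param duration_s total record duration, seconds.
#' @param fs sampling rate in Hz.
#' @param background_rms_uV background rms amplitude, microvolts.
#' @param event_rms_uV event rms amplitude, microvolts; must exceed the
#'   background rms.
#' @param event_rate_per_hour expected event count per hour.
#' @param event_duration_range_s `c(min, max)` event duration, seconds.
#' @param event_band_hz frequency band carrying event energy.
#' @param event_template `"spikewave"` or `"narrowband"` (see
#'   [generate_event()]).
#' @param count_mode `"poisson"` draws the event count from a Poisson law at
#'   the configured rate; `"fixed"` uses exactly `n_events`.
#' @param n_events event count for `count_mode = "fixed"` (default: the
#'   rounded rate expectation).
#' @param min_gap_s minimum gap between consecutive events, seconds.
#' @param seed integer seed driving all randomness of the synthesis.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(duration_s, fs = 256, background_rms_uV = 1,
                         event_rms_uV = 10, event_rate_per_hour = 1.25,
                         event_duration_range_s = c(5, 15),
                         event_band_hz = c(8, 22),
                         event_template = "spikewave",
                         count_mode = c("poisson", "fixed"), n_events = NULL,
                         min_gap_s = 10, seed = NULL) {
  check_positive(duration_s, "duration_s")
  check_positive(fs, "fs")
  if (event_rms_uV <= background_rms_uV)
    stop_arg("`event_rms_uV` must exceed `background_rms_uV`")
  if (event_rate_per_hour < 0) stop_arg("`event_rate_per_hour` must be >= 0")
  if (length(event_duration_range_s) != 2L ||
      any(event_duration_range_s <= 0) ||
      diff(event_duration_range_s) < 0)
    stop_arg("`event_duration_range_s` must be c(min, max) with 0 < min <= max")
  structure(list(duration_s = duration_s, fs = fs,
                 background_rms_uV = background_rms_uV,
                 event_rms_uV = event_rms_uV,
                 event_rate_per_hour = event_rate_per_hour,
                 event_duration_range_s = event_duration_range_s,
                 event_band_hz = event_band_hz,
                 event_template = event_template,
                 count_mode = match.arg(count_mode),
                 n_events = n_events, min_gap_s = min_gap_s, seed = seed),
            class = "synth_config")
}

# Draw non-overlapping event onsets by rejection sampling. Durations are
# given; events keep min_gap_s clear of each other and of the record edges.
place_events <- function(duration_s, durations_s, min_gap_s) {
  n <- length(durations_s)
  if (n == 0L) return(numeric(0))
  if (sum(durations_s) + (n + 1) * min_gap_s > duration_s)
    stop_arg("cannot place ", n, " events totalling ",
             round(sum(durations_s), 1), " s in ", duration_s,
             " s with a ", min_gap_s, " s minimum gap: record too short")
  onsets <- numeric(0)
  offsets <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(2000L)) {
      o <- stats::runif(1, min_gap_s, duration_s - durations_s[i] - min_gap_s)
      if (all(o >= offsets + min_gap_s | o + durations_s[i] + min_gap_s <= onsets)) {
        onsets <- c(onsets, o); offsets <- c(offsets, o + durations_s[i])
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop_arg("could not place event ", i, " of ", n,
               " without violating the ", min_gap_s, " s gap constraint")
  }
  sort(onsets)
}

#' Synthesize an annotated LFP recording
#'
#' Generates pink-noise background of the configured duration and inserts
#' oscillatory epileptiform bursts at random, non-overlapping onsets. One
#' annotation per inserted event covers exactly the burst's tapered extent.
#' Fully reproducible from `config$seed`.
#'
#' @param config a [synth_config()].
#' @return An [lfp_recording] with one annotation per event.
#' @export
synthesize_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    expect_n <- config$event_rate_per_hour * config$duration_s / 3600
    n_ev <- if (config$count_mode == "fixed")
      config$n_events %||% round(expect_n)
    else stats::rpois(1, expect_n)
    durs <- stats::runif(n_ev, config$event_duration_range_s[1],
                         config$event_duration_range_s[2])
    onsets <- place_events(config$duration_s, durs, config$min_gap_s)
    bg <- generate_background(config$duration_s, config$fs,
                              config$background_rms_uV, seed = NULL)
    x <- bg$samples
    ann <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      label = character(0), stringsAsFactors = FALSE)
    for (i in seq_along(onsets)) {
      ev <- generate_event(durs[i], config$fs, config$event_rms_uV,
                           config$event_band_hz, seed = NULL,
                           template = config$event_template)
      i0 <- round(onsets[i] * config$fs) + 1L
      idx <- i0:(i0 + length(ev) - 1L)
      x[idx] <- x[idx] + ev
      ann <- rbind(ann, data.frame(onset_s = (i0 - 1L) / config$fs,
                                   offset_s = (i0 - 1L + length(ev)) / config$fs,
                                   label = "seizure",
                                   stringsAsFactors = FALSE))
    }
    lfp_recording(x, config$fs, ann)
  })
}

#' Generate a sinusoidal test tone over background noise
#'
#' The probe stimulus of the response-map experiment: a sinusoid of given
#' peak amplitude and phase superimposed on freshly drawn pink background
#' noise (background rms 0 gives a clean tone). Duration defaults to 1 s.
#'
#' @param freq_hz tone frequency, strictly below Nyquist.
#' @param amplitude_uV peak amplitude in microvolts.
#' @param duration_s duration in seconds (default 1).
#' @param fs sampling rate in Hz.
#' @param phase phase in radians; `NULL` draws it uniformly.
#' @param background_rms_uV rms of the superimposed background noise.
#' @param seed integer seed (drives phase, if random, and the noise).
#' @return An [lfp_recording] with no annotations.
#' @export
generate_test_tone <- function(freq_hz, amplitude_uV, duration_s = 1,
                               fs = 256, phase = NULL,
                               background_rms_uV = 0, seed = NULL) {
  check_positive(freq_hz, "freq_hz")
  check_positive(duration_s, "duration_s")
  if (freq_hz >= fs / 2)
    stop_arg("`freq_hz` must be strictly below the Nyquist rate fs/2")
  if (amplitude_uV < 0) stop_arg("`amplitude_uV` must be >= 0")
  n <- round(duration_s * fs)
  with_seed(seed, {
    ph <- phase %||% stats::runif(1, 0, 2 * pi)
    x <- amplitude_uV * sin(2 * pi * freq_hz * sample_times(n, fs) + ph)
    if (background_rms_uV > 0) {
      x <- x + generate_background(duration_s, fs, background_rms_uV,
                                   seed = NULL)$samples
    }
    lfp_recording(x, fs)
  })
}
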