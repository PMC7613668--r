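# Recording, annotation, trace and model I/O, plus resampling.

#' Write a recording to EDF or CSV
#'
#' EDF (European Data Format, the clinical convention for this data class)
#' stores a single channel as 16-bit integers in 1-second data records;
#' the physical range is fitted to the signal, so amplitudes round-trip
#' within the 16-bit scaling error. Durations are padded with zeros to a
#' whole number of seconds. The CSV fallback writes two columns,
#' `time_s, amplitude_uV`, exactly.
#'
#' Annotations are not embedded; write them separately with
#' [write_annotations()].
#'
#' @param recording an [lfp_recording].
#' @param path output file; extension picks the format when
#'   `format = "auto"`.
#' @param format `"auto"`, `"edf"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, format = c("auto", "edf",
                                                        "csv")) {
  stopifnot(inherits(recording, "lfp_recording"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "edf"
  if (format == "csv") {
    df <- data.frame(time_s = sample_times(length(recording$samples),
                                           recording$fs),
                     amplitude_uV = recording$samples)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    write_edf(recording, path)
  }
  invisible(path)
}

pad8 <- function(x) formatC(as.character(x), width = 8, flag = "-")
padn <- function(x, n) formatC(as.character(x), width = n, flag = "-")

write_edf <- function(recording, path) {
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop_arg("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  x <- recording$samples
  nrec <- max(1L, as.integer(ceiling(length(x) / fs)))
  x <- c(x, numeric(nrec * fs - length(x)))
  pmax_ <- signif(max(abs(x), 1e-6) * 1.000001, 6)
  dig <- as.integer(round(x / pmax_ * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad8("0"), padn("synthetic LFP", 80), padn("lfpdetect", 80),
    pad8("01.01.00"), pad8("00.00.00"), pad8(512), padn("", 44),
    pad8(nrec), pad8(1), padn(1, 4),
    padn("LFP", 16), padn("synthetic", 80), pad8("uV"),
    pad8(format(-pmax_, trim = TRUE)), pad8(format(pmax_, trim = TRUE)),
    pad8(-32768), pad8(32767), padn("", 80), pad8(fs), padn("", 32))
  writeChar(hdr, con, eos = NULL)
  writeBin(dig, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a recording from EDF or CSV
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"edf"` or `"csv"`.
#' @param fs sampling rate in Hz, required for CSV input (CSV carries no
#'   header rate).
#' @return An [lfp_recording] (no annotations; see [read_annotations()]).
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"),
                           fs = NULL) {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "edf"
  if (format == "csv") {
    df <- tryCatch(utils::read.csv(path),
                   error = function(e) stop_arg("malformed CSV: ",
                                                conditionMessage(e)))
    if (nrow(df) == 0) stop_arg("empty CSV recording: ", path)
    if (!"amplitude_uV" %in% names(df))
      stop_arg("CSV recording needs an `amplitude_uV` column")
    if (is.null(fs)) {
      stop_arg("CSV input carries no sampling rate; pass `fs` explicitly")
    }
    if ("time_s" %in% names(df) && nrow(df) > 2) {
      dt <- diff(df$time_s)
      if (max(abs(dt - 1 / fs)) > 0.01 / fs)
        stop_arg("non-uniform timestamps in ", path,
                 " (expected spacing ", signif(1 / fs, 6), " s)")
    }
    return(lfp_recording(df$amplitude_uV, fs))
  }
  read_edf(path)
}

read_edf <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 512) stop_arg("not a valid single-channel EDF file: ",
                                      path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  nrec <- as.integer(substr(hdr, 237, 244))
  recdur <- as.numeric(substr(hdr, 245, 252))
  ns <- as.integer(substr(hdr, 253, 256))
  if (is.na(ns) || ns != 1)
    stop_arg("expected a single-channel EDF, found ns = ", ns)
  sig <- readChar(con, 256, useBytes = TRUE)
  pmin_ <- as.numeric(substr(sig, 105, 112))
  pmax_ <- as.numeric(substr(sig, 113, 120))
  dmin_ <- as.numeric(substr(sig, 121, 128))
  dmax_ <- as.numeric(substr(sig, 129, 136))
  spr <- as.integer(substr(sig, 217, 224))
  if (anyNA(c(nrec, recdur, pmin_, pmax_, dmin_, dmax_, spr)))
    stop_arg("malformed EDF header in ", path)
  dig <- readBin(con, integer(), n = nrec * spr, size = 2,
                 endian = "little")
  if (length(dig) != nrec * spr)
    stop_arg("EDF data truncated: expected ", nrec * spr, " samples, got ",
             length(dig))
  phys <- pmin_ + (dig - dmin_) * (pmax_ - pmin_) / (dmax_ - dmin_)
  lfp_recording(phys, spr / recdur)
}

#' Read and write annotation tables
#'
#' Annotations travel as CSV with the header `onset_s,offset_s,label`.
#'
#' @param annotations annotation data frame.
#' @param path CSV file path.
#' @return `write_annotations` returns `path` invisibly; `read_annotations`
#'   returns a validated, sorted annotation data frame.
#' @export
write_annotations <- function(annotations, path) {
  ann <- normalize_annotations(annotations, Inf)
  utils::write.csv(ann, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  df <- utils::read.csv(path)
  normalize_annotations(df, Inf)
}

#' Read and write classifier traces
#'
#' Trace CSV has columns `time_s,score,label` plus one comment line
#' carrying the output hop and sampling rate so the trace reconstructs
#' exactly.
#'
#' @param trace a [classifier_trace()].
#' @param path CSV file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` a
#'   [classifier_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "classifier_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lfpdetect trace hop_samples=%d fs=%g",
                     trace$hop_samples, trace$fs), con)
  utils::write.csv(data.frame(time_s = trace$times_s, score = trace$scores,
                              label = trace$labels),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  first <- readLines(path, n = 1)
  m <- regmatches(first,
                  regexec("hop_samples=([0-9]+) fs=([0-9.]+)", first))[[1]]
  if (length(m) != 3) stop_arg("missing trace metadata header in ", path)
  df <- utils::read.csv(path, comment.char = "#")
  classifier_trace(df$time_s, df$score, df$label, as.integer(m[2]),
                   as.numeric(m[3]))
}

#' Resample a recording to a target rate
#'
#' Polyphase rational-ratio resampling (via [signal::resample()]).
#' Annotations are carried over unchanged in seconds. A no-op when the
#' rate already matches.
#'
#' @param recording an [lfp_recording].
#' @param target_fs target sampling rate in Hz (default 256).
#' @return An [lfp_recording] at `target_fs`.
#' @export
resample_recording <- function(recording, target_fs = 256) {
  stopifnot(inherits(recording, "lfp_recording"))
  check_positive(target_fs, "target_fs")
  if (abs(recording$fs - target_fs) < 1e-9) return(recording)
  pq <- rational_ratio(target_fs, recording$fs)
  y <- signal::resample(recording$samples, pq[1], pq[2])
  lfp_recording(as.numeric(y), target_fs, recording$annotations)
}

rational_ratio <- function(a, b, max_den = 4096) {
  for (q in seq_len(max_den)) {
    p <- a * q / b
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop_arg("cannot express ", a, "/", b, " as a small rational ratio")
}

#' Save and load network models
#'
#' Models are stored as self-describing JSON holding the topology, the
#' input normalization constant, every weight tensor and, for quantized
#' models, the integer tensors with their scale factors. Quantized models
#' round-trip bit-exactly.
#'
#' @param model an `mlp_model` or `quantized_mlp` (an `mlp_fit` saves its
#'   model component).
#' @param path JSON file path.
#' @return `save_model` returns `path` invisibly; `load_model` the
#'   reconstructed model.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "mlp_fit")) model <- model$model
  stopifnot(inherits(model, c("mlp_model", "quantized_mlp")))
  obj <- unclass(model)
  obj$type <- class(model)[1]
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE),
                  error = function(e) stop_arg("unreadable model file: ",
                                               conditionMessage(e)))
  for (f in c("type", "window_len", "layers", "input_scale_uV"))
    if (is.null(obj[[f]])) stop_arg("model file missing field `", f, "`")
  if (!obj$type %in% c("mlp_model", "quantized_mlp"))
    stop_arg("unknown model type `", obj$type, "`")
  quant <- obj$type == "quantized_mlp"
  fix_tensor <- function(t, int = FALSE) {
    if (quant) {
      if (is.null(t$int) || is.null(t$scale))
        stop_arg("model file missing field `int`/`scale` in a tensor")
      t$int <- as_num_mat(t$int)
      t
    } else as_num_mat(t)
  }
  layers <- obj$layers
  obj$layers <- lapply(seq_along(layers), function(i) {
    l <- layers[[i]]
    if (is.null(l$W) || is.null(l$b))
      stop_arg("model file missing field `W`/`b` in layer ", i)
    Wt <- fix_tensor(l$W); bt <- fix_tensor(l$b)
    if (!quant) bt <- as.numeric(bt)
    list(W = Wt, b = bt)
  })
  if (!is.null(obj$conv) && length(obj$conv)) {
    obj$conv$K <- fix_tensor(obj$conv$K)
    obj$conv$b <- fix_tensor(obj$conv$b)
    if (!quant) obj$conv$b <- as.numeric(obj$conv$b)
  } else obj$conv <- NULL
  type <- obj$type
  obj$type <- NULL
  obj$hidden_sizes <- as.numeric(obj$hidden_sizes %||% integer(0))
  # restore matrix shapes that JSON may have collapsed (1-row weights)
  in0 <- if (!is.null(obj$conv)) {
    kmat <- if (quant) obj$conv$K$int else obj$conv$K
    if (!is.matrix(kmat)) {
      kmat <- matrix(kmat, nrow = 1)
      if (quant) obj$conv$K$int <- kmat else obj$conv$K <- kmat
    }
    obj$conv$npatch * nrow(kmat)
  } else obj$window_len
  sizes <- c(in0, obj$hidden_sizes, 1)
  for (i in seq_along(obj$layers)) {
    reshape <- function(w) {
      if (!is.matrix(w)) w <- matrix(w, nrow = sizes[i + 1], byrow = TRUE)
      if (!all(dim(w) == c(sizes[i + 1], sizes[i])))
        stop_arg("layer ", i, " weight shape ", paste(dim(w), collapse = "x"),
                 " does not match topology ", sizes[i + 1], "x", sizes[i])
      w
    }
    if (quant) obj$layers[[i]]$W$int <- reshape(obj$layers[[i]]$W$int)
    else obj$layers[[i]]$W <- reshape(obj$layers[[i]]$W)
  }
  structure(obj, class = type)
}

as_num_mat <- function(x) {
  if (is.matrix(x)) return(x * 1)
  if (is.list(x)) return(do.call(rbind, lapply(x, as.numeric)))
  as.numeric(x)
}

#' Read a YAML run configuration
#'
#' Accepts a YAML file with optional top-level keys `filter`, `synth`,
#' `train` whose sub-keys mirror the arguments of
#' [filter_chain_config()], [synth_config()] and [train_config()], plus an
#' optional global `seed` propagated to any section that does not set its
#' own.
#'
#' @param path YAML file path.
#' @return A list with elements `filter`, `synth`, `train` (those present)
#'   and `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  y <- yaml::read_yaml(path)
  out <- list(seed = y$seed)
  if (!is.null(y$filter)) out$filter <- do.call(filter_chain_config, y$filter)
  if (!is.null(y$synth)) {
    if (is.null(y$synth$seed)) y$synth$seed <- y$seed
    out$synth <- do.call(synth_config, y$synth)
  }
  if (!is.null(y$train)) {
    if (is.null(y$train$seed)) y$train$seed <- y$seed
    out$train <- do.call(train_config, y$train)
  }
  out
}
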