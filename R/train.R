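#' Slice a recording into fixed-length labeled windows
#'
#' Consecutive windows of `window_len` samples taken every `hop` samples.
#' A window is labeled positive when more than half of its samples fall
#' inside an annotated event (majority-overlap rule). Provenance (source
#' recording id and start index of every window) is retained so that
#' dataset splits can be audited.
#'
#' @param recording an [lfp_recording].
#' @param window_len samples per window.
#' @param hop samples between window starts (default: `window_len`,
#'   non-overlapping).
#' @param recording_id identifier stored in the provenance table.
#' @return An object of class `windowed_dataset` with fields `windows`
#'   (matrix, one row per window), `labels` (0/1), `fs`, `window_len`,
#'   `provenance`.
#' @export
window_dataset <- function(recording, window_len, hop = window_len,
                           recording_id = "rec1") {
  stopifnot(inherits(recording, "lfp_recording"))
  n <- length(recording$samples)
  if (n < window_len)
    stop_arg("recording has ", n, " samples, shorter than one window (",
             window_len, ")")
  nw <- floor((n - window_len) / hop) + 1
  starts <- (seq_len(nw) - 1) * hop + 1
  X <- matrix(0, nrow = nw, ncol = window_len)
  for (k in seq_len(nw))
    X[k, ] <- recording$samples[starts[k]:(starts[k] + window_len - 1)]
  inside <- annotation_mask(sample_times(n, recording$fs),
                            recording$annotations)
  labels <- vapply(starts, function(s)
    as.integer(sum(inside[s:(s + window_len - 1)]) > window_len / 2),
    integer(1))
  structure(list(windows = X, labels = labels, fs = recording$fs,
                 window_len = window_len,
                 provenance = data.frame(recording_id = recording_id,
                                         start_index = starts,
                                         stringsAsFactors = FALSE)),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("<windowed_dataset> %d windows of %d samples @ %g Hz (%d pos / %d neg)\n",
              nrow(x$windows), x$window_len, x$fs, sum(x$labels == 1),
              sum(x$labels == 0)))
  invisible(x)
}

subset_dataset <- function(ds, idx) {
  structure(list(windows = ds$windows[idx, , drop = FALSE],
                 labels = ds$labels[idx], fs = ds$fs,
                 window_len = ds$window_len,
                 provenance = ds$provenance[idx, , drop = FALSE]),
            class = "windowed_dataset")
}

combine_datasets <- function(dss) {
  stopifnot(length(unique(vapply(dss, function(d) d$window_len, numeric(1)))) == 1)
  structure(list(windows = do.call(rbind, lapply(dss, `[[`, "windows")),
                 labels = unlist(lapply(dss, `[[`, "labels")),
                 fs = dss[[1]]$fs, window_len = dss[[1]]$window_len,
                 provenance = do.call(rbind, lapply(dss, `[[`, "provenance"))),
            class = "windowed_dataset")
}

#' Rebalance a windowed dataset to a fixed negative:positive ratio
#'
#' Keeps every positive window and subsamples negatives uniformly without
#' replacement to exactly `neg_pos_ratio` negatives per positive (default
#' 3:1, biasing the training material towards the background class as a
#' seizure detector will see in deployment).
#'
#' @param dataset a `windowed_dataset`.
#' @param neg_pos_ratio negatives kept per positive (>= 1).
#' @param seed integer seed for the subsample.
#' @return A `windowed_dataset` with `#neg == neg_pos_ratio * #pos`.
#' @export
balance_dataset <- function(dataset, neg_pos_ratio = 3, seed = NULL) {
  stopifnot(inherits(dataset, "windowed_dataset"))
  if (neg_pos_ratio < 1) stop_arg("`neg_pos_ratio` must be >= 1")
  pos <- which(dataset$labels == 1)
  neg <- which(dataset$labels == 0)
  if (length(pos) == 0) stop_arg("dataset has no positive windows")
  need <- round(neg_pos_ratio * length(pos))
  if (length(neg) < need)
    stop_arg("insufficient negatives: need ", need, " for ", length(pos),
             " positives at ratio ", neg_pos_ratio, ", have ", length(neg))
  keep_neg <- if (length(neg) == need) neg else
    with_seed(seed, sort(sample(neg, need)))
  subset_dataset(dataset, sort(c(pos, keep_neg)))
}

#' Split a windowed dataset into training and validation parts
#'
#' Disjoint, exhaustive partition at the window level, stratified by class
#' by default so both halves keep the dataset's class proportions (within
#' rounding). A class with fewer than 2 members forces an unstratified
#' split with a warning.
#'
#' @param dataset a `windowed_dataset`.
#' @param train_frac fraction assigned to training (default 0.70).
#' @param seed integer seed.
#' @param stratified preserve per-class proportions (default TRUE).
#' @return A list with elements `train` and `validation`.
#' @export
split_dataset <- function(dataset, train_frac = 0.70, seed = NULL,
                          stratified = TRUE) {
  stopifnot(inherits(dataset, "windowed_dataset"))
  if (!(train_frac > 0 && train_frac < 1))
    stop_arg("`train_frac` must be in (0, 1)")
  n <- nrow(dataset$windows)
  if (n == 0) stop_arg("dataset is empty")
  if (stratified && any(table(factor(dataset$labels, c(0, 1))) < 2)) {
    warning("a class has fewer than 2 members; falling back to unstratified split")
    stratified <- FALSE
  }
  idx_train <- with_seed(seed, {
    if (stratified) {
      unlist(lapply(split(seq_len(n), dataset$labels), function(ix)
        sample(ix, round(train_frac * length(ix)))))
    } else sample(seq_len(n), round(train_frac * n))
  })
  idx_train <- sort(idx_train)
  list(train = subset_dataset(dataset, idx_train),
       validation = subset_dataset(dataset, setdiff(seq_len(n), idx_train)))
}

#' Training configuration
#'
#' @param neg_pos_ratio negative:positive window ratio used upstream.
#' @param train_frac training fraction of the 70:30 split.
#' @param epochs gradient-descent epochs (default 200).
#' @param learning_rate fixed step size (default 0.01).
#' @param batch_size mini-batch size (default 32).
#' @param seed integer seed driving shuffling (and initialization when the
#'   caller lets the trainer build the model).
#' @return An object of class `train_config`.
#' @export
train_config <- function(neg_pos_ratio = 3, train_frac = 0.70, epochs = 200,
                         learning_rate = 0.01, batch_size = 32,
                         seed = NULL) {
  if (neg_pos_ratio < 1) stop_arg("`neg_pos_ratio` must be >= 1")
  if (!(train_frac > 0 && train_frac < 1))
    stop_arg("`train_frac` must be in (0, 1)")
  check_positive(epochs, "epochs")
  check_positive(learning_rate, "learning_rate")
  check_positive(batch_size, "batch_size")
  structure(list(neg_pos_ratio = neg_pos_ratio, train_frac = train_frac,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = seed),
            class = "train_config")
}

# Mean binary cross entropy with probability clipping at eps.
bce_loss <- function(p, y, eps = 1e-7) {
  p <- pmin(1 - eps, pmax(eps, p))
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# One gradient step on a mini batch; returns the updated model and the
# batch loss. Backpropagates through the dense stack and, when present,
# the convolutional front end.
sgd_step <- function(model, X, y, lr) {
  fw <- forward_batch(model, X, keep_cache = TRUE)
  p <- fw$score
  cache <- fw$cache
  nb <- length(y)
  nl <- length(model$layers)
  delta <- matrix((p - y) / nb, ncol = 1)      # dL/d(pre-activation), output
  for (i in rev(seq_len(nl))) {
    Hin <- cache$acts[[i]]
    dW <- t(delta) %*% Hin
    db <- colSums(delta)
    if (i > 1 || !is.null(model$conv)) {
      dH <- delta %*% model$layers[[i]]$W
      if (i > 1) delta <- dH * (cache$pres[[i - 1]] > 0)
      else dconv <- dH
    }
    model$layers[[i]]$W <- model$layers[[i]]$W - lr * dW
    model$layers[[i]]$b <- model$layers[[i]]$b - lr * db
  }
  if (!is.null(model$conv)) {
    k <- nrow(model$conv$K)
    Z <- cache$Z0
    dK <- matrix(0, nrow = k, ncol = ncol(model$conv$K))
    dbk <- numeric(k)
    for (p_i in seq_along(cache$conv_cols)) {
      dF <- dconv[, (p_i - 1) * k + seq_len(k), drop = FALSE]
      dA <- if (model$conv$activation == "relu")
        dF * (cache$conv_pre[[p_i]] > 0) else dF
      dK <- dK + t(dA) %*% Z[, cache$conv_cols[[p_i]], drop = FALSE]
      dbk <- dbk + colSums(dA)
    }
    model$conv$K <- model$conv$K - lr * dK
    model$conv$b <- model$conv$b - lr * dbk
  }
  list(model = model, loss = bce_loss(p, y))
}

#' Train a windowed network by mini-batch gradient descent
#'
#' Minimizes mean binary cross entropy over the training windows with
#' plain mini-batch gradient descent at a fixed learning rate, recording
#' per-epoch training and validation loss. Fully reproducible from
#' `config$seed`.
#'
#' @param train a `windowed_dataset` of training windows.
#' @param validation optional `windowed_dataset` for per-epoch validation
#'   loss.
#' @param model an initialized `mlp_model` (from [init_mlp()] or
#'   [init_cnn()]); if `NULL`, a fresh default MLP matching the data's
#'   window length is initialized from `hidden_sizes` and `config$seed`.
#' @param hidden_sizes hidden-layer widths used when `model` is `NULL`.
#' @param config a [train_config()].
#' @return An object of class `mlp_fit`: the trained `model`, a `history`
#'   data frame (epoch, train_loss, val_loss), the configuration, and
#'   fitted training scores. Methods: `print`, `summary`, `coef`,
#'   `predict`, `plot`, `residuals`.
#' @export
train_mlp <- function(train, validation = NULL, model = NULL,
                      hidden_sizes = 8, config = train_config()) {
  stopifnot(inherits(train, "windowed_dataset"),
            inherits(config, "train_config"))
  if (is.null(model))
    model <- init_mlp(train$window_len, hidden_sizes, seed = config$seed)
  if (model$window_len != train$window_len)
    stop_arg("model window length ", model$window_len,
             " does not match dataset window length ", train$window_len)
  X <- train$windows; y <- train$labels
  n <- nrow(X)
  hist_train <- hist_val <- numeric(config$epochs)
  model <- with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (b0 in seq(1, n, by = config$batch_size)) {
        ix <- ord[b0:min(b0 + config$batch_size - 1, n)]
        st <- sgd_step(model, X[ix, , drop = FALSE], y[ix],
                       config$learning_rate)
        model <- st$model
        losses <- c(losses, st$loss)
        if (!is.finite(st$loss))
          stop_arg("training diverged (non-finite loss) at epoch ", ep,
                   "; reduce the learning rate")
      }
      hist_train[ep] <- mean(losses)
      hist_val[ep] <- if (!is.null(validation))
        bce_loss(forward_batch(model, validation$windows)$score,
                 validation$labels) else NA_real_
    }
    model
  })
  fitted <- forward_batch(model, X)$score
  structure(list(model = model,
                 history = data.frame(epoch = seq_len(config$epochs),
                                      train_loss = hist_train,
                                      val_loss = hist_val),
                 config = config,
                 fitted = fitted, y = y,
                 validation_loss = if (!is.null(validation))
                   hist_val[config$epochs] else NA_real_,
                 call = match.call()),
            class = "mlp_fit")
}

#' Hyperparameter grid search over window length and hidden width
#'
#' For every cell (window length, hidden units): re-window the source
#' recordings, rebalance, split, train a fresh seeded model, and record
#' the validation binary cross entropy. A failing cell is marked invalid
#' (NA) and the surface is still returned.
#'
#' @param recordings an [lfp_recording] or list of them (the raw material
#'   re-windowed at every window length).
#' @param window_lengths,hidden_sizes grid axes.
#' @param config a [train_config()].
#' @param choose `"min_loss"` picks the argmin cell; `"low_complexity"`
#'   picks, among cells within 10% of the minimum loss, the one with the
#'   fewest parameters (the transition-zone rule).
#' @param repeats models trained (with derived seeds) and averaged per
#'   cell.
#' @return An object of class `error_surface` with the loss matrix
#'   (rows = window lengths, columns = hidden sizes) and `chosen_cell`.
#' @export
grid_search <- function(recordings, window_lengths, hidden_sizes,
                        config = train_config(),
                        choose = c("min_loss", "low_complexity"),
                        repeats = 1) {
  choose <- match.arg(choose)
  if (inherits(recordings, "lfp_recording")) recordings <- list(recordings)
  if (length(window_lengths) == 0 || length(hidden_sizes) == 0)
    stop_arg("grid axes must be non-empty")
  loss <- matrix(NA_real_, nrow = length(window_lengths),
                 ncol = length(hidden_sizes),
                 dimnames = list(window_lengths, hidden_sizes))
  for (wi in seq_along(window_lengths)) {
    w <- window_lengths[wi]
    cell_data <- tryCatch({
      dss <- lapply(seq_along(recordings), function(i)
        window_dataset(recordings[[i]], w, recording_id = paste0("rec", i)))
      ds <- combine_datasets(dss)
      ds <- balance_dataset(ds, config$neg_pos_ratio,
                            seed = derive_seed(config$seed, w))
      split_dataset(ds, config$train_frac,
                    seed = derive_seed(config$seed, 1000 + w))
    }, error = function(e) NULL)
    if (is.null(cell_data)) next
    for (hi in seq_along(hidden_sizes)) {
      h <- hidden_sizes[hi]
      vals <- vapply(seq_len(repeats), function(r) {
        tryCatch({
          cfg <- config
          cfg$seed <- derive_seed(config$seed, 7 * w + 131 * h + r)
          fit <- train_mlp(cell_data$train, cell_data$validation,
                           hidden_sizes = h, config = cfg)
          fit$validation_loss
        }, error = function(e) NA_real_)
      }, numeric(1))
      loss[wi, hi] <- if (all(is.na(vals))) NA_real_ else
        mean(vals, na.rm = TRUE)
    }
  }
  structure(list(window_lengths = window_lengths,
                 hidden_sizes = hidden_sizes, loss = loss,
                 chosen_cell = choose_cell(loss, window_lengths,
                                           hidden_sizes, choose),
                 rule = choose),
            class = "error_surface")
}

choose_cell <- function(loss, ws, hs, rule) {
  if (all(is.na(loss))) return(NULL)
  if (rule == "min_loss") {
    ix <- which(loss == min(loss, na.rm = TRUE), arr.ind = TRUE)[1, ]
  } else {
    ok <- which(loss <= 1.1 * min(loss, na.rm = TRUE), arr.ind = TRUE)
    npar <- apply(ok, 1, function(ij)
      ws[ij[1]] * hs[ij[2]] + 2 * hs[ij[2]] + 1)
    ix <- ok[which.min(npar), ]
  }
  c(window_len = ws[ix[1]], hidden = hs[ix[2]])
}

#' @export
print.error_surface <- function(x, ...) {
  cat("<error_surface> validation binary cross entropy\n")
  print(round(x$loss, 4))
  if (!is.null(x$chosen_cell))
    cat(sprintf("chosen cell (%s): window %d, hidden %d\n", x$rule,
                x$chosen_cell[1], x$chosen_cell[2]))
  invisible(x)
}

#' @export
plot.error_surface <- function(x, ...) {
  graphics::image(x = seq_along(x$window_lengths),
                  y = seq_along(x$hidden_sizes), z = x$loss,
                  axes = FALSE, xlab = "window length",
                  ylab = "hidden units", main = "validation cross entropy",
                  ...)
  graphics::axis(1, at = seq_along(x$window_lengths),
                 labels = x$window_lengths)
  graphics::axis(2, at = seq_along(x$hidden_sizes), labels = x$hidden_sizes)
  invisible(x)
}
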