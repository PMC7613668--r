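# Shared fixtures, built lazily once per test run. Seeds are fixed so the
# whole suite is deterministic.

.fx <- new.env()

fixture <- function(name, expr) {
  if (!exists(name, envir = .fx, inherits = FALSE))
    assign(name, expr, envir = .fx)
  get(name, envir = .fx, inherits = FALSE)
}

# 10 min of synthetic LFP with 12 spike-wave events: the training material.
fx_train_recording <- function() {
  fixture("train_rec",
          synthesize_recording(synth_config(600, n_events = 12,
                                            count_mode = "fixed",
                                            seed = 101)))
}

# balanced 3:1, split 70:30 (stratified)
fx_split <- function() {
  fixture("split", {
    ds <- balance_dataset(window_dataset(fx_train_recording(), 20), 3,
                          seed = 7)
    split_dataset(ds, 0.70, seed = 8)
  })
}

# default 20x8 MLP trained for the full 200 epochs
fx_fit <- function() {
  fixture("fit", {
    sp <- fx_split()
    train_mlp(sp$train, sp$validation, config = train_config(seed = 9))
  })
}

# 40-minute held-out recording with 40 events: the evaluation material.
fx_eval_recording <- function() {
  fixture("eval_rec",
          synthesize_recording(synth_config(2400, n_events = 40,
                                            count_mode = "fixed",
                                            seed = 202)))
}

# A separable toy dataset: large-amplitude in-band bursts (common phase,
# small jitter) vs background noise windows, balanced, for quick training
# checks.
fx_toy_dataset <- function(n_each = 200, window_len = 20, seed = 55) {
  fixture(paste0("toy", n_each, "_", window_len, "_", seed), {
    set.seed(seed)
    t <- (0:(window_len - 1)) / 256
    pos <- t(replicate(n_each,
                       10 * sqrt(2) * sin(2 * pi * 14 * t + runif(1, 0, 0.3)) +
                         rnorm(window_len)))
    neg <- t(replicate(n_each, rnorm(window_len)))
    structure(list(windows = rbind(pos, neg),
                   labels = rep(c(1L, 0L), each = n_each), fs = 256,
                   window_len = window_len,
                   provenance = data.frame(recording_id = "toy",
                                           start_index = seq_len(2 * n_each))),
              class = "windowed_dataset")
  })
}
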