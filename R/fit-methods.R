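# S3 methods for the fitted-model object returned by train_mlp().

#' @export
print.mlp_fit <- function(x, ...) {
  cat("Windowed network seizure-state classifier\n")
  print(x$model)
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  %d epochs, final train BCE %.4f", last$epoch,
              last$train_loss))
  if (is.finite(last$val_loss))
    cat(sprintf(", validation BCE %.4f", last$val_loss))
  cat("\n")
  invisible(x)
}

#' @export
summary.mlp_fit <- function(object, ...) {
  last <- object$history[nrow(object$history), ]
  out <- list(
    topology = c(object$model$window_len, object$model$hidden_sizes, 1),
    has_conv = !is.null(object$model$conv),
    n_parameters = n_parameters(object$model),
    epochs = last$epoch,
    train_loss = last$train_loss,
    val_loss = last$val_loss,
    n_train = length(object$y),
    class_balance = table(factor(object$y, c(0, 1)))
  )
  class(out) <- "summary.mlp_fit"
  out
}

#' @export
print.summary.mlp_fit <- function(x, ...) {
  cat(sprintf("Topology: %s%s (%d parameters)\n",
              paste(x$topology, collapse = "-"),
              if (x$has_conv) " with conv front end" else "",
              x$n_parameters))
  cat(sprintf("Training: %d windows (%d neg / %d pos), %d epochs\n",
              x$n_train, x$class_balance[1], x$class_balance[2], x$epochs))
  cat(sprintf("Final binary cross entropy: train %.4f, validation %s\n",
              x$train_loss,
              if (is.finite(x$val_loss)) sprintf("%.4f", x$val_loss)
              else "-"))
  invisible(x)
}

#' @export
coef.mlp_fit <- function(object, ...) {
  m <- object$model
  out <- list()
  if (!is.null(m$conv)) out$conv <- list(K = m$conv$K, b = m$conv$b)
  for (i in seq_along(m$layers))
    out[[paste0("layer", i)]] <- m$layers[[i]]
  out
}

#' Predict from a fitted windowed network
#'
#' @param object an `mlp_fit` from [train_mlp()].
#' @param newdata an [lfp_recording] (scored window by window), a
#'   `windowed_dataset`, or a matrix with `window_len` columns.
#' @param type `"score"` returns raw per-window scores; `"label"` returns
#'   thresholded labels; `"trace"` (recordings only) returns the full
#'   consensus-adjusted [classifier_trace()].
#' @param threshold,consensus passed to [classify_windows()].
#' @param ... unused.
#' @return Numeric scores, integer labels, or a `classifier_trace`.
#' @export
predict.mlp_fit <- function(object, newdata, type = c("score", "label",
                                                      "trace"),
                            threshold = 0.5, consensus = 3, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "lfp_recording")) {
    tr <- classify_windows(object$model, newdata, threshold, consensus)
    return(switch(type, trace = tr, score = attr(tr, "raw_scores"),
                  label = tr$labels))
  }
  X <- if (inherits(newdata, "windowed_dataset")) newdata$windows
       else as.matrix(newdata)
  if (type == "trace")
    stop_arg("type = \"trace\" needs an lfp_recording")
  s <- forward_batch(object$model, X)$score
  if (type == "label") as.integer(s >= threshold) else s
}

#' @export
residuals.mlp_fit <- function(object, ...) object$y - object$fitted

#' @export
plot.mlp_fit <- function(x, ...) {
  h <- x$history
  rng <- range(c(h$train_loss, h$val_loss), na.rm = TRUE)
  graphics::plot(h$epoch, h$train_loss, type = "l", ylim = rng,
                 xlab = "epoch", ylab = "binary cross entropy", ...)
  if (any(is.finite(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::legend("topright", c("train", "validation"), lty = c(1, 2),
                   bty = "n")
  invisible(x)
}
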