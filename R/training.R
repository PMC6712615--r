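# Loss, learning-rate schedule, and the mini-batch SGD fit loop shared by
# RefineNet (inside the reverse-active-learning loop) and the atrous
# DenseNet (final classifier).

#' Softmax cross-entropy loss
#'
#' The mean over samples of `-log(exp(f_y) / sum_j exp(f_j))`, computed with
#' log-sum-exp stabilisation.  `scores` holds one row per sample and one
#' column per class; `labels` are 0-based class indices.
#'
#' @param scores N x K numeric matrix of class scores.
#' @param labels Integer vector of length N with values in `[0, K)`.
#' @return Non-negative scalar loss.
#' @examples
#' softmax_loss(matrix(0, 1, 4), 0L)        # log(4)
#' softmax_loss(matrix(c(2, 0), 1), 0L)     # log(1 + exp(-2))
#' @export
softmax_loss <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.integer(labels)
  if (!all(is.finite(scores))) abort("scores must be finite")
  if (length(labels) != nrow(scores))
    abort("one label per row of scores is required")
  if (any(labels < 0L) || any(labels >= ncol(scores)))
    abort(sprintf("labels must lie in [0, %d)", ncol(scores)))
  softmax_xent(t(scores), labels)$loss
}

#' Training configuration
#'
#' The learning rate starts large (0.05, viable because of batch
#' normalisation), drops to 0.01, and then decays by a factor of 10 per
#' further stage; see [lr_at()].  `epochs_per_stage` controls when the
#' drops happen.
#'
#' @param batch_size Mini-batch size (default 16).
#' @param lr_initial,lr_second First- and second-stage learning rates.
#' @param lr_decay Multiplicative decay applied per stage after the second.
#' @param epochs_per_stage Integer vector: epochs spent in each stage
#'   (recycled to `n_stages` if scalar).
#' @param n_stages Number of schedule stages to run.
#' @param momentum SGD momentum.
#' @param patience Early-stop patience, in epochs, on validation accuracy
#'   (`Inf` to disable).
#' @param seed Integer seed fixing initialisation and batch order.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 16L, lr_initial = 0.05,
                         lr_second = 0.01, lr_decay = 0.1,
                         epochs_per_stage = 10L, n_stages = 2L,
                         momentum = 0.9, patience = 3L, seed = 0L) {
  if (lr_second >= lr_initial || lr_decay >= 1)
    abort("learning rates must be strictly decreasing across stages")
  structure(list(batch_size = as.integer(batch_size),
                 lr_initial = lr_initial, lr_second = lr_second,
                 lr_decay = lr_decay,
                 epochs_per_stage = as.integer(epochs_per_stage),
                 n_stages = as.integer(n_stages), momentum = momentum,
                 patience = patience, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a schedule stage
#'
#' Stage 0 uses the large initial rate (default 0.05), stage 1 the second
#' rate (default 0.01), and each later stage multiplies by `lr_decay`
#' (default 0.1), so stage `s >= 2` gives `0.01 * 0.1^(s - 1)`.
#'
#' @param stage 0-based stage index.
#' @param config A [train_config()].
#' @return The learning rate.
#' @export
lr_at <- function(stage, config = train_config()) {
  stopifnot(stage >= 0)
  ifelse(stage == 0, config$lr_initial,
         config$lr_second * config$lr_decay^(stage - 1))
}

dataset_labels <- function(data, prefer_true = FALSE) {
  if (prefer_true && "true_label" %in% names(data) &&
      !anyNA(data$true_label))
    as.integer(data$true_label)
  else as.integer(data$assigned_label)
}

#' Fit a network to a patch dataset
#'
#' Mini-batch SGD with momentum under the staged learning-rate schedule of
#' [train_config()].  `x` may be a `model_graph` (fresh parameters) or an
#' existing `nn_fit` (warm start, as used when fine-tuning inside the
#' reverse-active-learning loop).  Training labels are the propagated
#' (`assigned_label`) ones; validation accuracy is measured against
#' `true_label` when the validation set carries it.
#'
#' The seed fixes initialisation and batch order; the contract is
#' statistical, not bitwise, reproducibility across platforms.
#'
#' @param object A `model_graph` or `nn_fit`.
#' @param data Patch tibble with `pixels` and `assigned_label` columns.
#' @param val Optional validation patch tibble.
#' @param config A [train_config()].
#' @param epochs Optional cap on total epochs (defaults to the schedule
#'   length).
#' @param ... Unused.
#' @return An `nn_fit`: the trained model plus a per-epoch `history`
#'   tibble (epoch, stage, lr, loss, val_aca).
#' @method fit model_graph
#' @export
fit.model_graph <- function(object, data, val = NULL,
                            config = train_config(), epochs = NULL, ...) {
  model <- init_model(object, seed = config$seed)
  fit_engine(model, data, val, config, epochs,
             history = NULL)
}

#' @rdname fit.model_graph
#' @method fit nn_fit
#' @export
fit.nn_fit <- function(object, data, val = NULL, config = object$config,
                       epochs = NULL, ...) {
  fit_engine(object$model, data, val, config, epochs,
             history = object$history, velocity = object$velocity)
}

fit_engine <- function(model, data, val, config, epochs, history,
                       velocity = NULL, Xall = NULL, Xval = NULL) {
  if (nrow(data) == 0L) abort("training set is empty")
  labels <- dataset_labels(data)
  if (any(labels >= model$n_classes))
    abort("training labels exceed the model's class count")
  stages <- rep_len(config$epochs_per_stage, config$n_stages)
  epoch0 <- if (is.null(history)) 0L else max(history$epoch)
  # warm starts continue the schedule where the previous fit left off;
  # epochs beyond the declared stages stay at the last stage's rate
  sched <- rep(seq_along(stages) - 1L, stages)
  stage_at <- function(i) sched[min(i, length(sched))]
  total <- if (is.null(epochs)) max(sum(stages) - epoch0, 0L) else epochs
  if (is.null(velocity)) velocity <- vector("list", length(model$params))
  input_size <- model$graph$input_size[1L]
  n <- nrow(data)
  best_aca <- -Inf; stall <- 0L
  hist_rows <- list()
  enc <- encode_graph(model$graph)
  if (is.null(Xall)) Xall <- build_input_matrix(data$pixels, input_size)
  if (is.null(Xval) && !is.null(val) && nrow(val) > 0L)
    Xval <- build_input_matrix(val$pixels, input_size)
  withr::with_seed(config$seed + epoch0, {
    for (ep in seq_len(total)) {
      stage <- stage_at(epoch0 + ep)
      lr <- lr_at(stage, config)
      ord <- sample.int(n) - 1L
      r <- cpp_run_epoch(enc, model$params, velocity, model$state,
                         Xall, labels, ord, config$batch_size, lr,
                         config$momentum, model$n_classes,
                         BN_EPS, BN_MOMENTUM)
      model$params <- r$params; model$state <- r$state
      velocity <- r$velocity
      model <- recalibrate_bn(model, enc, Xall)
      val_aca <- NA_real_
      if (!is.null(Xval)) {
        probs <- predict_matrix(model, Xval)
        val_aca <- mean(max.col(probs, ties.method = "first") - 1L ==
                          dataset_labels(val, prefer_true = TRUE))
      }
      hist_rows[[ep]] <- tibble::tibble(
        epoch = epoch0 + ep, stage = stage, lr = lr,
        loss = r$loss, val_aca = val_aca)
      if (!is.na(val_aca)) {
        if (val_aca > best_aca) { best_aca <- val_aca; stall <- 0L }
        else stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  })
  structure(list(model = model, config = config, velocity = velocity,
                 history = dplyr::bind_rows(history, hist_rows)),
            class = "nn_fit")
}

# class-probability matrix (N x K) from a prebuilt input matrix
predict_matrix <- function(model, X, batch_size = 256L) {
  if (inherits(model, "nn_fit")) model <- model$model
  cpp_predict_probs(encode_graph(model$graph), model$params, model$state,
                    X, batch_size, model$n_classes, BN_EPS)
}

# class-probability matrix (N x K) for a patch tibble
predict_proba <- function(model, data, batch_size = 256L) {
  if (inherits(model, "nn_fit")) model <- model$model
  X <- build_input_matrix(data$pixels, model$graph$input_size[1L])
  predict_matrix(model, X, batch_size)
}

#' Predict class probabilities or labels for patches
#'
#' @param object An `nn_fit` from [fit.model_graph()].
#' @param newdata Patch tibble with a `pixels` list column.
#' @param type `"prob"` for an N x K probability matrix, `"class"` for
#'   0-based label indices.
#' @param ... Unused.
#' @method predict nn_fit
#' @export
predict.nn_fit <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  probs <- predict_proba(object$model, newdata)
  if (type == "prob") probs
  else max.col(probs, ties.method = "first") - 1L
}

#' @method print nn_fit
#' @export
print.nn_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<nn_fit '%s'> %d epochs, final loss %.4f",
              x$model$graph$name, nrow(h), h$loss[nrow(h)]))
  if (!all(is.na(h$val_aca)))
    cat(sprintf(", best val ACA %.3f", max(h$val_aca, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' @method tidy nn_fit
#' @export
tidy.nn_fit <- function(x, ...) x$history

#' @method glance nn_fit
#' @export
glance.nn_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h), final_loss = h$loss[nrow(h)],
    best_val_aca = if (all(is.na(h$val_aca))) NA_real_
                   else max(h$val_aca, na.rm = TRUE),
    n_params = sum(vapply(x$model$params, function(p)
      if (is.null(p)) 0L else sum(lengths(p)), integer(1))))
}

#' @method autoplot nn_fit
#' @export
autoplot.nn_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("loss", "val_aca"),
                           names_to = "metric")
  ggplot2::ggplot(h[!is.na(h$value), ],
                  ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}
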