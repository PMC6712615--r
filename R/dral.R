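# Deep-reverse active learning: iteratively train a small confidence
# network, flag training patches whose maximum softmax confidence falls
# below a threshold, remove them with an augmentation-group consensus
# rule, fine-tune on the reduced pool, and monitor validation accuracy.
# This is the reverse of classical active learning: instead of selecting
# uncertain samples for annotation, uncertain samples are *expelled*
# because slide-label propagation makes them likely mislabeled.

#' Configuration for the reverse-active-learning loop
#'
#' @param confidence_threshold Flag a patch when its maximum class
#'   probability is strictly below this value (default 0.5).  For
#'   two-class problems the maximum softmax probability is always at
#'   least 0.5, so the default threshold can never fire; a warning is
#'   issued and a higher threshold should be chosen deliberately.
#' @param max_iterations Cap on removal/fine-tune iterations (>= 1).
#' @param stop_patience Iterations without validation-accuracy
#'   improvement before stopping (default 1: stop as soon as accuracy
#'   stops increasing).
#' @param target_aca Optional absolute validation accuracy considered
#'   satisfactory; the loop stops once reached.
#' @param removal_cap Optional maximum fraction of the current training
#'   set removable in one iteration (`NULL` = no cap).
#' @param initial_epochs Epochs used to train the confidence network
#'   before the first removal.
#' @param finetune_epochs Epochs of fine-tuning after each removal.
#' @param seed Integer seed.
#' @return A `dral_config` list.
#' @export
dral_config <- function(confidence_threshold = 0.5, max_iterations = 4L,
                        stop_patience = 1L, target_aca = NULL,
                        removal_cap = NULL, initial_epochs = 2L,
                        finetune_epochs = 1L, seed = 1L) {
  if (confidence_threshold <= 0 || confidence_threshold > 1)
    abort("confidence_threshold must lie in (0, 1]")
  if (max_iterations < 1) abort("max_iterations must be >= 1")
  structure(list(confidence_threshold = confidence_threshold,
                 max_iterations = as.integer(max_iterations),
                 stop_patience = as.integer(stop_patience),
                 target_aca = target_aca, removal_cap = removal_cap,
                 initial_epochs = as.integer(initial_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 seed = as.integer(seed)),
            class = "dral_config")
}

#' Flag low-confidence patches
#'
#' A patch is flagged when the maximum entry of its class-probability
#' vector is strictly below the threshold.
#'
#' @param probabilities N x K matrix; rows must be valid probability
#'   vectors (non-negative, summing to 1 within 1e-6).
#' @param threshold Confidence threshold in `(0, 1]`.
#' @return Logical vector of length N.
#' @export
flag_low_confidence <- function(probabilities, threshold = 0.5) {
  p <- as.matrix(probabilities)
  if (any(p < -1e-9) || any(abs(rowSums(p) - 1) > 1e-6))
    abort("rows of `probabilities` must be probability vectors summing to 1")
  if (ncol(p) == 2L && threshold <= 0.5)
    warn(paste("with 2 classes the maximum softmax probability is always",
               ">= 0.5; threshold", threshold, "can never flag a patch"))
  apply(p, 1L, max) < threshold
}

#' Augmentation-group consensus removal
#'
#' Within each augmentation group, if strictly more than half of the
#' nominal group size is flagged (more than four of eight), all remaining
#' members of the group are removed; otherwise only the flagged members
#' are removed.  Groups may hold fewer than `group_size` members when
#' earlier iterations already removed some; they may never hold more.
#'
#' @param flags Logical vector, one entry per patch.
#' @param group_ids Group identifier per patch; at most `group_size`
#'   members each.
#' @param group_size Nominal members per augmentation group (8 or 4).
#' @return Logical removal vector aligned with `flags`.
#' @export
consensus_removal <- function(flags, group_ids, group_size = 8L) {
  if (length(flags) != length(group_ids))
    abort("flags and group_ids must align")
  sizes <- table(group_ids)
  if (any(sizes > group_size))
    abort(sprintf("augmentation groups larger than group_size = %d: %s",
                  group_size,
                  paste(utils::head(names(sizes)[sizes > group_size], 5),
                        collapse = ", ")))
  n_flagged <- stats::ave(as.integer(flags), group_ids, FUN = sum)
  flags | (n_flagged > group_size / 2)
}

#' Precision/recall of a removal decision against ground truth
#'
#' Scores the set of removed patch ids against the ground-truth
#' mislabeled set (known exactly for synthetic corpora).
#'
#' @param removed_ids Character vector of removed patch ids.
#' @param truth_ids Character vector of truly mislabeled patch ids.
#' @return One-row tibble: `n_removed`, `n_truth`, `precision`, `recall`,
#'   `f_measure`.
#' @export
noise_detection_metrics <- function(removed_ids, truth_ids) {
  tp <- length(intersect(removed_ids, truth_ids))
  fp <- length(setdiff(removed_ids, truth_ids))
  fn <- length(setdiff(truth_ids, removed_ids))
  prf <- precision_recall_f(tp, fp, fn)
  tibble::tibble(n_removed = length(removed_ids),
                 n_truth = length(truth_ids),
                 precision = prf$precision, recall = prf$recall,
                 f_measure = prf$f_measure)
}

# predict probabilities with either an nn_fit/nn_model or a plain
# function(data) -> N x K matrix (used by tests with stub models);
# X is an optional prebuilt input matrix avoiding reconversion
model_probs <- function(model, data, X = NULL) {
  if (is.function(model)) model(data)
  else if (!is.null(X)) predict_matrix(model, X)
  else predict_proba(model, data)
}

model_val_aca <- function(model, val, Xval = NULL) {
  probs <- model_probs(model, val, Xval)
  mean(max.col(probs, ties.method = "first") - 1L ==
         dataset_labels(val, prefer_true = TRUE))
}

#' One removal/fine-tune iteration
#'
#' Predicts on every training patch, flags low-confidence ones, applies
#' the group-consensus rule, removes, fine-tunes the model on the
#' reduced set, and evaluates validation accuracy.
#'
#' @param model An `nn_fit` (or, for testing, a function mapping a patch
#'   tibble to an N x K probability matrix; fine-tuning is then skipped).
#' @param train Training patch tibble (complete augmentation groups).
#' @param val Validation patch tibble with trusted labels.
#' @param config A [dral_config()].
#' @param group_size Augmentation-group size.
#' @param X,Xval Optional prebuilt input matrices (one column per patch)
#'   so repeated iterations do not re-convert pixel arrays.
#' @return List: `model`, `train` (reduced), `keep` (logical), and
#'   `removed_ids`, `val_aca`, `row` (one-row log tibble).
#' @export
dral_iteration <- function(model, train, val, config = dral_config(),
                           group_size = 8L, X = NULL, Xval = NULL) {
  if (nrow(train) == 0L || nrow(val) == 0L)
    abort("train and val must be non-empty")
  probs <- model_probs(model, train, X)
  flags <- flag_low_confidence(probs, config$confidence_threshold)
  remove <- consensus_removal(flags, train$group_id, group_size)
  if (!is.null(config$removal_cap) && mean(remove) > config$removal_cap) {
    # retain only the lowest-confidence removals, up to the cap
    cap_n <- floor(config$removal_cap * nrow(train))
    if (cap_n < 1L) {
      remove[] <- FALSE
    } else {
      conf <- stats::ave(apply(probs, 1L, max), train$group_id, FUN = mean)
      cutoff <- sort(conf[remove])[cap_n]
      remove <- remove & conf <= cutoff
    }
  }
  if (all(remove))
    abort(paste("removal would empty the training set;",
                "raise the threshold or inspect the model"))
  reduced <- train[!remove, , drop = FALSE]
  if (!is.null(X)) X <- X[, !remove, drop = FALSE]
  if (!is.function(model) && config$finetune_epochs > 0L)
    model <- fit_engine(model$model, reduced, val = NULL,
                        config = model$config,
                        epochs = config$finetune_epochs,
                        history = model$history, velocity = model$velocity,
                        Xall = X)
  val_aca <- model_val_aca(model, val, Xval)
  row <- tibble::tibble(train_size = nrow(train),
                        n_flagged = sum(flags), n_removed = sum(remove),
                        train_size_after = nrow(reduced),
                        val_aca = val_aca)
  list(model = model, train = reduced, keep = !remove,
       removed_ids = train$patch_id[remove], val_aca = val_aca, row = row)
}

#' Run the full reverse-active-learning loop
#'
#' Trains the confidence network (RefineNet unless another graph is
#' given), then alternates patch removal and fine-tuning until
#' validation accuracy stops improving for `stop_patience` iterations,
#' reaches `target_aca`, or `max_iterations` is hit.  The returned
#' refined training set can be treated as correctly annotated data for
#' training a larger classifier.
#'
#' @param train Training patch tibble (complete augmentation groups,
#'   propagated labels).
#' @param val Validation patch tibble with trusted (true) labels.
#' @param config A [dral_config()].
#' @param graph Confidence-network graph; default RefineNet sized to the
#'   patch side.
#' @param train_cfg A [train_config()] for the initial training.
#' @param group_size Augmentation-group size.
#' @param X Optional prebuilt input matrix for `train` (one column per
#'   patch, already sized to the confidence network's input).
#' @return A `dral_run`: list with `refined` (tibble), `log` (tibble,
#'   one row per iteration), `removed_ids` (list per iteration), and
#'   `model` (final `nn_fit`).
#' @export
run_dral <- function(train, val, config = dral_config(), graph = NULL,
                     train_cfg = NULL, group_size = 8L, X = NULL) {
  if (nrow(train) == 0L) abort("training set is empty")
  validate_patch_dataset(train, group_size)
  n_classes <- max(train$assigned_label) + 1L
  if (n_classes == 2L && config$confidence_threshold <= 0.5)
    warn("2-class run: the default 0.5 threshold never flags any patch")
  if (is.null(graph)) {
    side <- if ("pixels" %in% names(train)) dim(train$pixels[[1L]])[1L]
            else as.integer(round(sqrt(nrow(X) / 3)))
    graph <- build_refinenet(n_classes, side)
  }
  if (is.null(train_cfg))
    train_cfg <- train_config(seed = config$seed, patience = Inf)
  input_size <- graph$input_size[1L]
  if (is.null(X)) X <- build_input_matrix(train$pixels, input_size)
  Xval <- build_input_matrix(val$pixels, input_size)
  model <- fit_engine(init_model(graph, train_cfg$seed), train, val = NULL,
                      config = train_cfg, epochs = config$initial_epochs,
                      history = NULL, Xall = X)
  aca0 <- model_val_aca(model, val, Xval)
  log <- tibble::tibble(iteration = 0L, train_size = nrow(train),
                        n_flagged = 0L, n_removed = 0L,
                        train_size_after = nrow(train), val_aca = aca0)
  removed <- list()
  best <- aca0; stall <- 0L
  for (k in seq_len(config$max_iterations)) {
    it <- dral_iteration(model, train, val, config, group_size,
                         X = X, Xval = Xval)
    model <- it$model; train <- it$train
    X <- X[, it$keep, drop = FALSE]
    removed[[k]] <- it$removed_ids
    log <- dplyr::bind_rows(log, dplyr::bind_cols(iteration = k, it$row))
    if (!is.null(config$target_aca) && it$val_aca >= config$target_aca)
      break
    if (it$val_aca > best) { best <- it$val_aca; stall <- 0L }
    else {
      stall <- stall + 1L
      if (stall >= config$stop_patience) break
    }
  }
  structure(list(refined = train, log = log, removed_ids = removed,
                 model = model, config = config),
            class = "dral_run")
}

#' @method print dral_run
#' @export
print.dral_run <- function(x, ...) {
  cat(sprintf("<dral_run> %d iterations, %d -> %d patches, final val ACA %.3f\n",
              nrow(x$log) - 1L, x$log$train_size[1L],
              x$log$train_size_after[nrow(x$log)],
              x$log$val_aca[nrow(x$log)]))
  print(x$log)
  invisible(x)
}

#' @method tidy dral_run
#' @export
tidy.dral_run <- function(x, ...) x$log

#' @method glance dral_run
#' @export
glance.dral_run <- function(x, ...) {
  tibble::tibble(
    iterations = nrow(x$log) - 1L,
    initial_size = x$log$train_size[1L],
    refined_size = x$log$train_size_after[nrow(x$log)],
    n_removed = x$log$train_size[1L] - x$log$train_size_after[nrow(x$log)],
    initial_val_aca = x$log$val_aca[1L],
    final_val_aca = x$log$val_aca[nrow(x$log)])
}

#' @method autoplot dral_run
#' @export
autoplot.dral_run <- function(object, ...) {
  lg <- object$log
  lg$train_size_end <- lg$train_size_after
  d <- tidyr::pivot_longer(
    lg[, c("iteration", "train_size_end", "val_aca")],
    c("train_size_end", "val_aca"), names_to = "metric")
  d$metric <- factor(d$metric, c("val_aca", "train_size_end"),
                     c("validation ACA", "training-set size"))
  ggplot2::ggplot(d, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL)
}
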