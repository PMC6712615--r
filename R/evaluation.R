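# Evaluation: confusion matrices, overall correct classification rate
# (ACA), per-class precision/recall/F-measure, and patch-to-slide
# majority-vote fusion.

#' Confusion matrix
#'
#' @param truth,pred Integer vectors of 0-based class labels.
#' @param n_classes Number of classes K.
#' @return K x K integer matrix of class `confusion_matrix`; rows are
#'   true classes, columns predicted.
#' @export
confusion <- function(truth, pred, n_classes) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (length(truth) != length(pred)) abort("truth and pred must align")
  if (any(c(truth, pred) < 0L) || any(c(truth, pred) >= n_classes))
    abort(sprintf("labels must lie in [0, %d)", n_classes))
  lv <- factor(integer(0), levels = 0:(n_classes - 1L))
  m <- as.matrix(table(factor(truth, levels = levels(lv)),
                       factor(pred, levels = levels(lv))))
  dimnames(m) <- list(true = levels(lv), predicted = levels(lv))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Overall correct classification rate (ACA)
#'
#' Trace of the confusion matrix divided by the total sample count.
#'
#' @param m A [confusion()] matrix.
#' @return Fraction in `[0, 1]`.
#' @export
aca <- function(m) {
  if (sum(m) == 0) abort("empty confusion matrix")
  sum(diag(m)) / sum(m)
}

#' Precision, recall and F-measure from error counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`,
#' `F = 2 P R / (P + R)`; any quantity whose denominator is zero is 0 by
#' convention.
#'
#' @param tp,fp,fn Non-negative counts (vectorised).
#' @return Tibble with columns `precision`, `recall`, `f_measure`.
#' @export
precision_recall_f <- function(tp, fp, fn) {
  stopifnot(all(tp >= 0), all(fp >= 0), all(fn >= 0))
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  tibble::tibble(precision = p, recall = r, f_measure = f)
}

#' Full classification metrics from labels
#'
#' Confusion matrix, ACA, and per-class TP/FP/FN with
#' precision/recall/F-measure; micro and macro averages are both
#' reported (micro-averaged recall equals ACA).
#'
#' @param truth,pred 0-based label vectors.
#' @param n_classes Number of classes.
#' @return A `classification_metrics` object: list with `confusion`,
#'   `aca`, `per_class` (tibble) and `summary` (tibble with micro/macro
#'   rows).
#' @export
classification_metrics <- function(truth, pred, n_classes) {
  m <- confusion(truth, pred, n_classes)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  per_class <- dplyr::bind_cols(
    tibble::tibble(class = 0:(n_classes - 1L), tp = as.integer(tp),
                   fp = as.integer(fp), fn = as.integer(fn),
                   support = as.integer(rowSums(m))),
    precision_recall_f(tp, fp, fn))
  micro <- precision_recall_f(sum(tp), sum(fp), sum(fn))
  macro <- tibble::tibble(precision = mean(per_class$precision),
                          recall = mean(per_class$recall),
                          f_measure = mean(per_class$f_measure))
  structure(list(confusion = m, aca = aca(m), per_class = per_class,
                 summary = dplyr::bind_cols(
                   tibble::tibble(average = c("micro", "macro")),
                   dplyr::bind_rows(micro, macro))),
            class = "classification_metrics")
}

#' @method print classification_metrics
#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("<classification_metrics> ACA %.4f over %d samples\n",
              x$aca, sum(x$confusion)))
  print(x$per_class)
  invisible(x)
}

#' @method tidy classification_metrics
#' @export
tidy.classification_metrics <- function(x, ...) x$per_class

#' @method glance classification_metrics
#' @export
glance.classification_metrics <- function(x, ...) {
  tibble::tibble(aca = x$aca, n = sum(x$confusion),
                 macro_f = x$summary$f_measure[x$summary$average == "macro"],
                 micro_f = x$summary$f_measure[x$summary$average == "micro"])
}

#' @method autoplot classification_metrics
#' @export
autoplot.classification_metrics <- function(object, ...) {
  d <- tibble::as_tibble(as.table(unclass(object$confusion)))
  names(d) <- c("true", "predicted", "count")
  ggplot2::ggplot(d, ggplot2::aes(.data$predicted, .data$true,
                                  fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted class", y = "true class")
}

#' Slide-level labels by patch majority vote
#'
#' Each patch votes for its most probable class; a slide's label is the
#' class with the most votes.  Vote ties are broken by the higher mean
#' probability across the slide's patches, then by the lower class
#' index, so the fusion is deterministic and independent of patch order.
#'
#' @param data Tibble with a `slide_id` column and a `probs` matrix
#'   column (or columns `p0 ... p{K-1}`), one row per patch.
#' @return Tibble with one row per slide: `slide_id`, `label`,
#'   `n_patches`.
#' @export
slice_vote <- function(data) {
  if (nrow(data) == 0L) abort("no patch predictions to fuse")
  probs <- if ("probs" %in% names(data)) as.matrix(data$probs)
           else as.matrix(data[, grep("^p[0-9]+$", names(data)), drop = FALSE])
  if (ncol(probs) < 2L) abort("need class probabilities per patch")
  votes <- max.col(probs, ties.method = "first") - 1L
  K <- ncol(probs)
  dplyr::bind_rows(purrr::imap(split(seq_len(nrow(data)), data$slide_id),
    function(ix, sid) {
      counts <- tabulate(votes[ix] + 1L, nbins = K)
      top <- which(counts == max(counts)) - 1L
      if (length(top) > 1L) {
        mp <- colMeans(probs[ix, top + 1L, drop = FALSE])
        top <- top[mp == max(mp)]
      }
      tibble::tibble(slide_id = sid, label = min(top),
                     n_patches = length(ix))
    }))
}
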