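# Selection-rule fidelity (flagging threshold, group consensus), the
# iteration contract, and a small end-to-end refinement run.

test_that("flagging uses a strict threshold on the maximum probability", {
  expect_true(flag_low_confidence(matrix(c(0.40, 0.30, 0.20, 0.10), 1), 0.5))
  # exactly at the boundary: not flagged (strict <); the 2-class warning
  # is expected here
  expect_false(suppressWarnings(
    flag_low_confidence(matrix(c(0.5, 0.5), 1), 0.5)))
  # with two classes the maximum is always >= 0.5
  withr::with_seed(1, {
    p <- matrix(runif(50), 50, 1); p <- cbind(p, 1 - p)
    expect_warning(fl <- flag_low_confidence(p, 0.5), "2 classes")
    expect_false(any(fl))
  })
  expect_error(flag_low_confidence(matrix(c(0.7, 0.6), 1), 0.5),
               "probability")
})

test_that("group consensus removes whole groups only past the strict majority", {
  gid <- rep("g1", 8)
  # 5 of 8 flagged: everything goes
  expect_equal(sum(consensus_removal(rep(c(TRUE, FALSE), c(5, 3)), gid)), 8L)
  # exactly 4 of 8: only the flagged 4
  r <- consensus_removal(rep(c(TRUE, FALSE), c(4, 4)), gid)
  expect_equal(r, rep(c(TRUE, FALSE), c(4, 4)))
  expect_equal(sum(consensus_removal(rep(FALSE, 8), gid)), 0L)
  # group size 4 generalisation: 3 of 4 is a strict majority
  expect_equal(sum(consensus_removal(c(TRUE, TRUE, TRUE, FALSE),
                                     rep("g", 4), 4L)), 4L)
  expect_equal(sum(consensus_removal(c(TRUE, TRUE, FALSE, FALSE),
                                     rep("g", 4), 4L)), 2L)
  # groups can be partial (members already removed) but never oversized
  expect_equal(sum(consensus_removal(rep(TRUE, 5), rep("g", 5), 8L)), 5L)
  expect_error(consensus_removal(rep(TRUE, 9), rep("g", 9), 8L), "larger")
})

test_that("selection is a pure function of the probabilities", {
  withr::with_seed(12, {
    p <- matrix(runif(64 * 4), 64, 4)
    p <- p / rowSums(p)
    gid <- rep(sprintf("g%d", 1:8), each = 8)
    a <- consensus_removal(flag_low_confidence(p, 0.5), gid)
    b <- consensus_removal(flag_low_confidence(p, 0.5), gid)
    expect_identical(a, b)
    # consensus only ever adds members of majority-flagged groups
    fl <- flag_low_confidence(p, 0.5)
    extra <- a & !fl
    counts <- tapply(fl, gid, sum)
    expect_true(all(counts[gid[extra]] > 4))
  })
})

test_that("iteration leaves a confident model's pool untouched and aborts on uniform", {
  train <- stub_patchset(4, n_classes = 4L)
  val <- stub_patchset(2, n_classes = 4L)
  confident <- function(data) probs_with_max(nrow(data), 4L, 0.9)
  it <- dral_iteration(confident, train, val,
                       dral_config(finetune_epochs = 0L))
  expect_equal(nrow(it$train), nrow(train))
  expect_equal(it$row$n_removed, 0L)
  uniform <- function(data) probs_with_max(nrow(data), 4L, 0.25)
  expect_error(dral_iteration(uniform, train, val,
                              dral_config(finetune_epochs = 0L)),
               "empty the training set")
})

test_that("removal metrics follow set arithmetic", {
  m <- noise_detection_metrics(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f_measure, 2 / 3)
  ident <- noise_detection_metrics(c("x", "y"), c("x", "y"))
  expect_equal(unlist(ident[, c("precision", "recall", "f_measure")]),
               c(precision = 1, recall = 1, f_measure = 1))
  none <- noise_detection_metrics(character(0), c("x"))
  expect_equal(none$recall, 0)
})

test_that("invalid loop configurations are rejected", {
  expect_error(dral_config(max_iterations = 0L), "max_iterations")
  expect_error(dral_config(confidence_threshold = 0), "confidence_threshold")
})

test_that("a small refinement run shrinks monotonically with disjoint removals", {
  corp <- generate_corpus(corpus_config(
    n_slides_per_class = 2L, slide_size = c(64L, 64L),
    tumor_fraction = 0.35, n_classes = 3L, seed = 31L))
  train <- extract_corpus_patches(corp, 32L, 0.5, 0.1, mode = "d4_8")
  valc <- generate_corpus(corpus_config(
    n_slides_per_class = 2L, slide_size = c(64L, 64L),
    tumor_fraction = 0.35, n_classes = 3L, seed = 32L))
  val <- extract_corpus_patches(valc, 32L, 0.5, 0.1, mode = "none")
  val$assigned_label <- val$true_label
  run <- run_dral(train, val,
                  dral_config(initial_epochs = 2L, finetune_epochs = 1L,
                              max_iterations = 2L, stop_patience = 2L,
                              seed = 1L))
  lg <- tidy(run)
  expect_true(all(diff(lg$train_size_after) <= 0))
  expect_true(all(lg$train_size_after <= lg$train_size))
  ids <- unlist(run$removed_ids)
  expect_equal(anyDuplicated(ids), 0L)
  expect_equal(nrow(run$refined) + length(ids), nrow(train))
  expect_s3_class(glance(run), "tbl_df")
  expect_s3_class(autoplot(run), "ggplot")
})

test_that("a noise-free pool loses almost nothing under refinement", {
  cfg <- corpus_config(n_slides_per_class = 2L, slide_size = c(64L, 64L),
                       tumor_fraction = 1.0, n_classes = 3L, seed = 41L)
  corp <- generate_corpus(cfg)
  train <- extract_corpus_patches(corp, 32L, 0.5, 0.1, mode = "d4_8")
  valc <- generate_corpus(corpus_config(
    n_slides_per_class = 2L, slide_size = c(64L, 64L), tumor_fraction = 1.0,
    n_classes = 3L, seed = 42L))
  val <- extract_corpus_patches(valc, 32L, 0.5, 0.1, mode = "none")
  val$assigned_label <- val$true_label
  run <- run_dral(train, val,
                  dral_config(initial_epochs = 3L, finetune_epochs = 1L,
                              max_iterations = 1L, seed = 2L))
  removal_fraction <- 1 - nrow(run$refined) / nrow(train)
  expect_lt(removal_fraction, 0.05)
})
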