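# End-to-end orchestration: simulate -> extract -> reverse-active-learning
# refinement -> train the atrous DenseNet on the noisy and refined pools ->
# evaluate both at patch and slide level.  One nested configuration (YAML
# loadable) drives all stages; per-stage seeds derive from one root seed.

#' Build an experiment configuration
#'
#' @param corpus A [corpus_config()] for the training corpus; a disjoint
#'   validation corpus is generated with `val_slides_per_class` slides
#'   per class from a derived seed.
#' @param patch_size,overlap,aug_mode,purity_threshold,roi Patch
#'   extraction settings (see [extract_corpus_patches()]).
#' @param val_slides_per_class Validation slides per class.
#' @param dral A [dral_config()].
#' @param adn An [adn_config()] for the final classifier.
#' @param adn_epochs Training epochs for each ADN arm.
#' @param batch_size Mini-batch size for all training.
#' @param seed Root seed; stage seeds are derived from it.
#' @param output_dir Where [run_experiment()] writes artifacts
#'   (versioned `run-NNN` subdirectories).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(corpus = corpus_config(),
                              patch_size = 64L, overlap = 0.5,
                              aug_mode = "d4_8", purity_threshold = 0.1,
                              roi = FALSE, val_slides_per_class = 4L,
                              dral = dral_config(),
                              adn = adn_config(input_size = 32L),
                              adn_epochs = 1L, batch_size = 16L,
                              seed = 1L, output_dir = tempfile("dralnet_")) {
  structure(list(corpus = corpus, patch_size = as.integer(patch_size),
                 overlap = overlap, aug_mode = aug_mode,
                 purity_threshold = purity_threshold, roi = roi,
                 val_slides_per_class = as.integer(val_slides_per_class),
                 dral = dral, adn = adn,
                 adn_epochs = as.integer(adn_epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "experiment_config")
}

#' Validate an experiment configuration
#'
#' @param config An `experiment_config`, or the path of a YAML file
#'   encoding one (see [read_experiment_config()]).
#' @return Tibble of violations (`field`, `problem`); zero rows when the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_experiment_config(config)
  v <- list()
  bad <- function(field, problem) v[[length(v) + 1L]] <<-
    tibble::tibble(field = field, problem = problem)
  cc <- config$corpus
  if (cc$tumor_fraction < 0 || cc$tumor_fraction > 1)
    bad("corpus.tumor_fraction", "must lie in [0, 1]")
  if (cc$n_classes < 2) bad("corpus.n_classes", "must be >= 2")
  if (any(cc$slide_size < config$patch_size))
    bad("corpus.slide_size", "smaller than patch_size")
  if (config$overlap < 0 || config$overlap >= 1)
    bad("patch.overlap", "must lie in [0, 1)")
  else if (round(config$patch_size * (1 - config$overlap)) < 1)
    bad("patch.overlap", "stride rounds to zero")
  if (!config$aug_mode %in% c("d4_8", "rot_4"))
    bad("patch.aug_mode", "must be d4_8 or rot_4")
  if (config$purity_threshold <= 0 || config$purity_threshold > 1)
    bad("patch.purity_threshold", "must lie in (0, 1]")
  if (config$dral$max_iterations < 1)
    bad("dral.max_iterations", "must be >= 1")
  if (config$dral$confidence_threshold <= 0 ||
      config$dral$confidence_threshold > 1)
    bad("dral.confidence_threshold", "must lie in (0, 1]")
  if (cc$n_classes == 2 && config$dral$confidence_threshold <= 0.5)
    bad("dral.confidence_threshold",
        "never fires for 2 classes; choose a value above 0.5")
  if (config$adn$n_classes != cc$n_classes)
    bad("adn.n_classes", "must match corpus.n_classes")
  if (length(v) == 0)
    tibble::tibble(field = character(), problem = character())
  else dplyr::bind_rows(v)
}

#' Read an experiment configuration from YAML
#'
#' Unknown fields are rejected; nested sections mirror the arguments of
#' [experiment_config()], [corpus_config()], [dral_config()] and
#' [adn_config()].
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$corpus)) args$corpus <- do.call(corpus_config, y$corpus)
  if (!is.null(y$dral)) args$dral <- do.call(dral_config, y$dral)
  if (!is.null(y$adn)) args$adn <- do.call(adn_config, y$adn)
  for (nm in setdiff(names(y), c("corpus", "dral", "adn")))
    args[[nm]] <- y[[nm]]
  do.call(experiment_config, args)
}

next_run_dir <- function(base) {
  dir.create(base, recursive = TRUE, showWarnings = FALSE)
  existing <- list.files(base, pattern = "^run-[0-9]+$")
  n <- if (length(existing) == 0) 1L
       else max(as.integer(sub("run-", "", existing))) + 1L
  d <- file.path(base, sprintf("run-%03d", n))
  dir.create(d)
  d
}

eval_arm <- function(model, val, slide_truth, n_classes, Xval = NULL) {
  probs <- if (is.null(Xval)) predict_proba(model, val)
           else predict_matrix(model, Xval)
  truth <- dataset_labels(val, prefer_true = TRUE)
  patch <- classification_metrics(
    truth, max.col(probs, ties.method = "first") - 1L, n_classes)
  pv <- val["slide_id"]
  pv$probs <- probs
  slide_pred <- slice_vote(pv)
  joined <- dplyr::left_join(slide_pred, slide_truth, by = "slide_id")
  slide <- classification_metrics(joined$truth, joined$label, n_classes)
  list(patch = patch, slide = slide)
}

metrics_json <- function(m) {
  list(aca = m$patch$aca, slide_aca = m$slide$aca,
       confusion = unclass(m$patch$confusion),
       per_class = m$patch$per_class[, c("class", "precision", "recall",
                                         "f_measure")],
       summary = m$patch$summary)
}

#' Run a full experiment from one configuration
#'
#' Generates the training and validation corpora, extracts and augments
#' patches, runs the reverse-active-learning refinement, trains the
#' atrous DenseNet separately on the noisy and refined pools, and
#' evaluates both arms on the validation patches (patch-level and
#' slide-level vote accuracy).  All artifacts are written to a fresh
#' versioned run directory: `corpus_manifest.csv`, `patch_manifest.csv`,
#' `dral_log.csv`, `removed_ids_K.txt`, `metrics_noisy.json`,
#' `metrics_refined.json`, and a `run_manifest.json` declaring every
#' file.  Reruns with the same seed reproduce manifests and removal
#' counts.
#'
#' @param config An [experiment_config()].
#' @param quiet Suppress progress messages.
#' @return A `dral_experiment`: list with `dral` (the [run_dral()]
#'   result), `noise_rate`, `removal_metrics`, `metrics_noisy`,
#'   `metrics_refined` and `run_dir`.
#' @export
run_experiment <- function(config = experiment_config(), quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  problems <- validate_config(config)
  if (nrow(problems) > 0)
    abort(c("invalid experiment configuration",
            stats::setNames(paste(problems$field, problems$problem),
                            rep("x", nrow(problems)))))
  say <- function(...) if (!quiet) message(sprintf(...))
  run_dir <- next_run_dir(config$output_dir)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            parent = e))
  }
  files <- character()
  emit <- function(name) files <<- c(files, name)

  say("simulating corpora (seed %d)", config$seed)
  corpus <- stage("simulate", generate_corpus(config$corpus))
  val_cfg <- config$corpus
  val_cfg$n_slides_per_class <- config$val_slides_per_class
  val_cfg$seed <- derive_seed(config$seed, 7L, 1L)
  val_corpus <- stage("simulate", generate_corpus(val_cfg))
  utils::write.csv(corpus$manifest, file.path(run_dir, "corpus_manifest.csv"),
                   row.names = FALSE)
  emit("corpus_manifest.csv")

  say("extracting %dpx patches (overlap %.2f, %s)", config$patch_size,
      config$overlap, config$aug_mode)
  train <- stage("extract", extract_corpus_patches(
    corpus, config$patch_size, config$overlap, config$purity_threshold,
    mode = config$aug_mode, roi = config$roi))
  val <- stage("extract", extract_corpus_patches(
    val_corpus, config$patch_size, config$overlap,
    config$purity_threshold, mode = "none", roi = config$roi))
  # slide-level truth is the slide label; patch-level trusted labels are
  # the mask-derived ground truth
  slide_truth <- dplyr::distinct(val, .data$slide_id,
                                 truth = .data$assigned_label)
  val$assigned_label <- val$true_label
  noise_rate <- expected_noise_rate(corpus, config$patch_size,
                                    config$overlap,
                                    config$purity_threshold)
  group_size <- if (config$aug_mode == "d4_8") 8L else 4L
  utils::write.csv(dplyr::select(train, -dplyr::any_of("pixels")),
                   file.path(run_dir, "patch_manifest.csv"),
                   row.names = FALSE)
  emit("patch_manifest.csv")

  say("running reverse-active-learning refinement (%d patches, noise rate %.3f)",
      nrow(train), noise_rate)
  Xtrain <- build_input_matrix(train$pixels, config$patch_size)
  # the stacked matrix now carries the pixel data; drop the per-record
  # arrays to halve peak memory on large corpora
  train$pixels <- NULL
  gc(verbose = FALSE)
  dcfg <- config$dral
  dcfg$seed <- derive_seed(config$seed, 11L, 1L)
  dral <- stage("dral", run_dral(train, val, dcfg,
                                 train_cfg = train_config(
                                   batch_size = config$batch_size,
                                   seed = dcfg$seed, patience = Inf),
                                 group_size = group_size, X = Xtrain))
  utils::write.csv(dral$log, file.path(run_dir, "dral_log.csv"),
                   row.names = FALSE)
  emit("dral_log.csv")
  for (k in seq_along(dral$removed_ids)) {
    fn <- sprintf("removed_ids_%d.txt", k)
    writeLines(dral$removed_ids[[k]], file.path(run_dir, fn))
    emit(fn)
  }
  truth_ids <- train$patch_id[train$true_label != train$assigned_label]
  removal_metrics <- noise_detection_metrics(unlist(dral$removed_ids),
                                             truth_ids)

  say("training the atrous DenseNet on both pools (%d epochs)",
      config$adn_epochs)
  # both arms share one seed so the noisy-vs-refined comparison is paired
  # (identical initialisation); only the training pool differs
  adn_in <- config$adn$input_size
  Xadn <- resize_input_matrix(Xtrain, config$patch_size, adn_in)
  rm(Xtrain); gc(verbose = FALSE)
  Xadn_val <- resize_input_matrix(
    build_input_matrix(val$pixels, config$patch_size),
    config$patch_size, adn_in)
  arm_seed <- derive_seed(config$seed, 13L, 1L)
  arms <- list(noisy = train, refined = dral$refined)
  Xarms <- list(noisy = Xadn,
                refined = Xadn[, match(dral$refined$patch_id,
                                       train$patch_id), drop = FALSE])
  metrics <- purrr::imap(arms, function(pool, nm) {
    g <- build_adn(config$adn)
    f <- stage(paste0("train_", nm), fit_engine(
      init_model(g, arm_seed), pool, val = NULL,
      config = train_config(batch_size = config$batch_size,
                            epochs_per_stage = 1L,
                            n_stages = max(2L, config$adn_epochs),
                            seed = arm_seed, patience = Inf),
      epochs = config$adn_epochs, history = NULL, Xall = Xarms[[nm]]))
    m <- stage(paste0("evaluate_", nm),
               eval_arm(f, val, slide_truth, config$adn$n_classes,
                        Xval = Xadn_val))
    fn <- sprintf("metrics_%s.json", nm)
    jsonlite::write_json(metrics_json(m), file.path(run_dir, fn),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit(fn)
    m
  })

  jsonlite::write_json(
    list(seed = config$seed, files = files,
         noise_rate = noise_rate,
         val_aca_noisy = metrics$noisy$patch$aca,
         val_aca_refined = metrics$refined$patch$aca),
    file.path(run_dir, "run_manifest.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)

  structure(list(dral = dral, noise_rate = noise_rate,
                 removal_metrics = removal_metrics,
                 metrics_noisy = metrics$noisy,
                 metrics_refined = metrics$refined,
                 run_dir = run_dir, config = config),
            class = "dral_experiment")
}

#' @method print dral_experiment
#' @export
print.dral_experiment <- function(x, ...) {
  cat(sprintf("<dral_experiment> run dir: %s\n", x$run_dir))
  cat(sprintf("  injected noise rate: %.3f\n", x$noise_rate))
  cat(sprintf("  removal precision:   %.3f (recall %.3f)\n",
              x$removal_metrics$precision, x$removal_metrics$recall))
  cat(sprintf("  val patch ACA:       noisy %.3f | refined %.3f\n",
              x$metrics_noisy$patch$aca, x$metrics_refined$patch$aca))
  cat(sprintf("  val slide ACA:       noisy %.3f | refined %.3f\n",
              x$metrics_noisy$slide$aca, x$metrics_refined$slide$aca))
  invisible(x)
}

#' @method glance dral_experiment
#' @export
glance.dral_experiment <- function(x, ...) {
  tibble::tibble(
    noise_rate = x$noise_rate,
    removal_precision = x$removal_metrics$precision,
    removal_recall = x$removal_metrics$recall,
    aca_noisy = x$metrics_noisy$patch$aca,
    aca_refined = x$metrics_refined$patch$aca,
    slide_aca_noisy = x$metrics_noisy$slide$aca,
    slide_aca_refined = x$metrics_refined$slide$aca)
}
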