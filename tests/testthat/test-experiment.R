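# End-to-end orchestration: config validation, artifact layout,
# rerun determinism, and the command-line wrapper.

tiny_experiment <- function(out, seed = 5L) {
  experiment_config(
    corpus = corpus_config(n_slides_per_class = 2L,
                           slide_size = c(64L, 64L),
                           tumor_fraction = 0.4, n_classes = 3L,
                           seed = seed),
    patch_size = 32L, val_slides_per_class = 2L,
    dral = dral_config(max_iterations = 2L, initial_epochs = 1L,
                       finetune_epochs = 1L),
    adn = adn_config(n_classes = 3L, input_size = 32L),
    adn_epochs = 1L, seed = seed, output_dir = out)
}

test_that("configuration validation reports field-level violations", {
  cfg <- tiny_experiment(withr::local_tempdir())
  expect_equal(nrow(validate_config(cfg)), 0L)
  cfg$overlap <- 1.0
  cfg$dral$max_iterations <- 0L
  cfg$adn$n_classes <- 4L
  v <- validate_config(cfg)
  expect_setequal(v$field, c("patch.overlap", "dral.max_iterations",
                             "adn.n_classes"))
  # a 2-class corpus with the default threshold is flagged loudly
  cfg2 <- tiny_experiment(withr::local_tempdir())
  cfg2$corpus$n_classes <- 2L
  cfg2$adn$n_classes <- 2L
  expect_true("dral.confidence_threshold" %in% validate_config(cfg2)$field)
})

test_that("experiment configs round-trip through YAML", {
  dir <- withr::local_tempdir()
  yaml::write_yaml(list(
    corpus = list(n_slides_per_class = 2, slide_size = c(64, 64),
                  tumor_fraction = 0.4, n_classes = 3, seed = 5),
    patch_size = 32, val_slides_per_class = 2,
    dral = list(max_iterations = 2, initial_epochs = 1),
    adn = list(n_classes = 3, input_size = 32),
    adn_epochs = 1, seed = 5, output_dir = dir),
    file.path(dir, "cfg.yaml"))
  cfg <- read_experiment_config(file.path(dir, "cfg.yaml"))
  expect_s3_class(cfg, "experiment_config")
  expect_equal(cfg$corpus$n_classes, 3L)
  expect_equal(cfg$dral$max_iterations, 2L)
  expect_equal(nrow(validate_config(cfg)), 0L)
})

test_that("a tiny experiment emits all artifacts and reruns identically", {
  out <- withr::local_tempdir()
  cfg <- tiny_experiment(out)
  ex <- run_experiment(cfg, quiet = TRUE)
  files <- list.files(ex$run_dir)
  for (f in c("corpus_manifest.csv", "patch_manifest.csv", "dral_log.csv",
              "metrics_noisy.json", "metrics_refined.json",
              "run_manifest.json"))
    expect_true(f %in% files, label = f)
  man <- jsonlite::read_json(file.path(ex$run_dir, "run_manifest.json"))
  expect_true(all(unlist(man$files) %in% files))
  lg <- utils::read.csv(file.path(ex$run_dir, "dral_log.csv"))
  expect_true(all(diff(lg$train_size_after) <= 0))
  # a rerun lands in a fresh versioned directory with identical
  # manifests and removal counts
  ex2 <- run_experiment(cfg, quiet = TRUE)
  expect_false(ex2$run_dir == ex$run_dir)
  expect_equal(utils::read.csv(file.path(ex2$run_dir, "dral_log.csv")), lg)
  expect_equal(utils::read.csv(file.path(ex2$run_dir, "patch_manifest.csv")),
               utils::read.csv(file.path(ex$run_dir, "patch_manifest.csv")))
  expect_s3_class(glance(ex), "tbl_df")
})

test_that("the command-line wrapper validates configs and reports errors", {
  cli <- system.file("cli", "dralnet.R", package = "dralnet")
  expect_true(nzchar(cli))
  dir <- withr::local_tempdir()
  yaml::write_yaml(list(
    corpus = list(n_slides_per_class = 2, slide_size = c(64, 64),
                  tumor_fraction = 0.4, n_classes = 3, seed = 5),
    patch_size = 32, adn = list(n_classes = 3, input_size = 32),
    output_dir = dir),
    file.path(dir, "ok.yaml"))
  libs <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ok <- system2("Rscript", c(cli, "validate", "--config",
                             file.path(dir, "ok.yaml")),
                stdout = TRUE, stderr = TRUE, env = libs)
  expect_null(attr(ok, "status"))
  yaml::write_yaml(list(
    corpus = list(n_slides_per_class = 2, slide_size = c(64, 64),
                  tumor_fraction = 0.4, n_classes = 3, seed = 5),
    patch_size = 32, overlap = 1.0,
    adn = list(n_classes = 3, input_size = 32), output_dir = dir),
    file.path(dir, "bad.yaml"))
  bad <- suppressWarnings(
    system2("Rscript", c(cli, "validate", "--config",
                         file.path(dir, "bad.yaml")),
            stdout = TRUE, stderr = TRUE, env = libs))
  expect_equal(attr(bad, "status"), 1L)
  expect_match(paste(bad, collapse = "\n"), "patch.overlap")
})
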