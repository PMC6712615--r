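# Synthetic slide generator: masks, determinism, corpus bookkeeping, and
# the ground-truth label-noise rate.

small_cfg <- function(...) {
  corpus_config(n_slides_per_class = 2L, slide_size = c(64L, 64L),
                tumor_fraction = 0.3, n_classes = 3L, seed = 11L, ...)
}

test_that("normal slides carry an empty tumor mask, full tumor fraction fills it", {
  cfg <- small_cfg()
  s0 <- generate_slide(0L, cfg, seed = 3L)
  expect_true(all(s0$tumor_mask == 0L))
  cfg1 <- small_cfg()
  cfg1$tumor_fraction <- 1.0
  s2 <- generate_slide(2L, cfg1, seed = 3L)
  expect_true(all(s2$tumor_mask == 1L))
  expect_error(generate_slide(5L, cfg), "label")
})

test_that("tumor coverage hits the target fraction within 0.05", {
  cfg <- corpus_config(n_slides_per_class = 1L, slide_size = c(512L, 512L),
                       tumor_fraction = 0.3, n_classes = 4L, seed = 7L)
  s <- generate_slide(1L, cfg, seed = 7L)
  expect_gte(mean(s$tumor_mask), 0.25)
  expect_lte(mean(s$tumor_mask), 0.35)
  # mask marks exactly the pixels painted with tumor texture: tumor and
  # background fields differ almost everywhere, so identical pixels
  # inside/outside the mask would be a bookkeeping error
  s0 <- generate_slide(0L, cfg, seed = 7L)
  expect_false(isTRUE(all.equal(s$pixels, s0$pixels)))
})

test_that("slides and corpora are deterministic in the seed", {
  cfg <- small_cfg()
  a <- generate_slide(1L, cfg, seed = 42L)
  b <- generate_slide(1L, cfg, seed = 42L)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$tumor_mask, b$tumor_mask)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(purrr::map(c1$slides, "pixels"),
                   purrr::map(c2$slides, "pixels"))
  expect_identical(c1$manifest, c2$manifest)
})

test_that("corpus size and manifest bookkeeping are correct", {
  cfg <- corpus_config(n_slides_per_class = 5L, slide_size = c(64L, 64L),
                       n_classes = 4L, seed = 2L)
  corp <- generate_corpus(cfg)
  expect_length(corp$slides, 20L)
  expect_equal(unname(table(corp$manifest$label)), rep(5L, 4L),
               ignore_attr = TRUE)
  cfg2 <- corpus_config(n_slides_per_class = 3L, slide_size = c(64L, 64L),
                        n_classes = 2L, seed = 1L)
  m <- generate_corpus(cfg2)$manifest
  expect_equal(nrow(m), 6L)
  expect_equal(unname(table(m$label)), c(3L, 3L), ignore_attr = TRUE)
})

test_that("corpus round-trips through PNG files on disk", {
  cfg <- small_cfg()
  dir <- withr::local_tempdir()
  corp <- generate_corpus(cfg, dir = dir)
  expect_true(all(file.exists(corp$manifest$path)))
  back <- png::readPNG(corp$manifest$path[5])
  expect_equal(back, corp$slides[[5]]$pixels, tolerance = 1e-9)
})

test_that("expected_noise_rate matches a brute-force per-patch enumeration", {
  corp <- generate_corpus(small_cfg())
  w <- 32L; thr <- 0.1
  got <- expected_noise_rate(corp, w, 0.5, thr)
  # independent oracle: nested loops over every window, counting mask
  # pixels directly
  tot <- 0L; mis <- 0L
  for (s in corp$slides) {
    stp <- as.integer(round(w * 0.5))
    for (y in seq(0L, nrow(s$tumor_mask) - w, by = stp)) {
      for (x in seq(0L, ncol(s$tumor_mask) - w, by = stp)) {
        tot <- tot + 1L
        pur <- mean(s$tumor_mask[(y + 1):(y + w), (x + 1):(x + w)])
        if (s$slide_label > 0L && pur < thr) mis <- mis + 1L
      }
    }
  }
  expect_equal(got, mis / tot)
})

test_that("noise rate is 0 for full tumors and maximal for empty ones", {
  cfg <- small_cfg(); cfg$tumor_fraction <- 1.0
  expect_equal(expected_noise_rate(generate_corpus(cfg), 32L, 0.5, 0.1), 0)
  cfg$tumor_fraction <- 0.0
  corp <- generate_corpus(cfg)
  # every patch of every non-normal slide is mislabeled
  expect_equal(expected_noise_rate(corp, 32L, 0.5, 0.1), 2 / 3)
})

test_that("noise rate is non-increasing in tumor fraction", {
  rates <- purrr::map_dbl(c(0.1, 0.3, 0.6), function(tf) {
    cfg <- small_cfg(); cfg$tumor_fraction <- tf
    expected_noise_rate(generate_corpus(cfg), 32L, 0.5, 0.1)
  })
  expect_true(all(diff(rates) <= 0))
})

test_that("invalid texture and corpus parameters are rejected", {
  expect_error(texture_spec(0, -1, 0.5, c(1, 0, 0)), "base_frequency")
  expect_error(texture_spec(0, 0.1, 1.5, c(1, 0, 0)), "contrast")
  expect_error(corpus_config(tumor_fraction = 1.2), "tumor_fraction")
  expect_error(corpus_config(n_classes = 1L), "n_classes")
})
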