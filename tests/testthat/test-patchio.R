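# Patch extraction: grid arithmetic, RoI masking, label propagation,
# dihedral augmentation, manifest round trips.

test_that("grid arithmetic reproduces the reference corpus patch counts", {
  g <- grid_positions(2048L, 1536L, 512L, 0.5)
  expect_equal(nrow(g), 35L)           # 7 x 5 windows per slide
  expect_equal(35L * 80L, 2800L)       # per-category count at 80 slides
  expect_equal(grid_positions(512L, 512L, 512L, 0.5),
               tibble::tibble(x = 0L, y = 0L))
  expect_equal(nrow(grid_positions(896L, 768L, 112L, 0.5)), 180L)
  expect_error(grid_positions(100L, 100L, 128L, 0.5), "larger")
  expect_error(grid_positions(100L, 100L, 32L, 1.0), "overlap")
})

test_that("grid positions agree with a brute-force oracle on random geometries", {
  withr::with_seed(99, {
    for (i in 1:200) {
      w <- sample(4:64, 1)
      W <- w + sample(0:200, 1); H <- w + sample(0:200, 1)
      ov <- runif(1, 0, 0.9)
      if (round(w * (1 - ov)) < 1) next
      got <- as.matrix(grid_positions(W, H, w, ov))
      oracle <- grid_oracle(W, H, w, ov)
      expect_equal(nrow(got), nrow(oracle))
      expect_setequal(paste(got[, "x"], got[, "y"]),
                      paste(oracle[, 1], oracle[, 2]))
    }
  })
})

test_that("RoI binarization finds dark tissue on bright background", {
  white <- array(1, c(32, 32, 3))
  expect_true(all(!binarize_roi(white)))
  dark <- array(0.05, c(32, 32, 3))
  expect_true(all(binarize_roi(dark)))
  # painted dark disc on white: recovered area within 10%
  img <- array(0.95, c(64, 64, 3))
  d <- sqrt(outer((1:64 - 32)^2, (1:64 - 32)^2, `+`)) <= 20
  for (ch in 1:3) { m <- img[, , ch]; m[d] <- 0.3; img[, , ch] <- m }
  got <- sum(binarize_roi(img))
  expect_lt(abs(got - sum(d)) / sum(d), 0.1)
  expect_error(binarize_roi(array(0, c(0, 4, 3))), "empty")
})

test_that("extraction propagates the slide label and honours RoI and purity", {
  slide <- list(pixels = array(0.5, c(128, 128, 3)), slide_label = 2L)
  ps <- extract_patches(slide, 32L, 0.5, slide_id = "s")
  expect_equal(nrow(ps), 49L)
  expect_true(all(ps$assigned_label == 2L))
  expect_true(all(is.na(ps$true_label)))
  # a slide fully outside the RoI yields nothing
  none <- extract_patches(slide, 32L, 0.5,
                          roi = matrix(FALSE, 128, 128), slide_id = "s")
  expect_equal(nrow(none), 0L)
  # purity rule against direct window counting
  mask <- matrix(0L, 128, 128); mask[1:40, 1:40] <- 1L
  pt <- extract_patches(slide, 32L, 0.5, true_mask = mask,
                        purity_threshold = 0.1, slide_id = "s")
  direct <- vapply(seq_len(nrow(pt)), function(i) {
    x <- pt$grid_x[i]; y <- pt$grid_y[i]
    mean(mask[(y + 1):(y + 32), (x + 1):(x + 32)])
  }, numeric(1))
  expect_equal(pt$true_label, ifelse(direct >= 0.1, 2L, 0L))
  expect_true(any(pt$true_label == 0L) && any(pt$true_label == 2L))
})

test_that("d4_8 augmentation yields the 8-element dihedral orbit", {
  p <- stub_patchset(1, w = 6L, group_size = 1L)[1, ]
  g <- augment_group(p, "d4_8")
  expect_equal(g$aug_index, 0:7)
  expect_equal(dplyr::n_distinct(g$group_id), 1L)
  # asymmetric pixels: all 8 variants distinct
  keys <- vapply(g$pixels, function(a) paste(a, collapse = ","),
                 character(1))
  expect_equal(dplyr::n_distinct(keys), 8L)
  # measure preserving: identical pixel multisets
  sorted <- purrr::map(g$pixels, ~sort(as.vector(.x)))
  for (s in sorted[-1]) expect_equal(s, sorted[[1]])
  # original is member 0
  expect_identical(g$pixels[[1]], p$pixels[[1]])
  # closure: transforming any member stays inside the orbit
  extra <- augment_group(dplyr::mutate(g[3, ], aug_index = 0L), "d4_8")
  for (px in extra$pixels)
    expect_true(paste(px, collapse = ",") %in% keys)
})

test_that("constant patches collapse pixels but not records; rot_4 has 4 members", {
  p <- stub_patchset(1, w = 4L, group_size = 1L)[1, ]
  p$pixels[[1]][] <- 0.5
  g <- augment_group(p, "d4_8")
  expect_equal(nrow(g), 8L)
  expect_equal(dplyr::n_distinct(g$aug_index), 8L)
  for (px in g$pixels) expect_equal(px, p$pixels[[1]])
  r <- augment_group(stub_patchset(1, w = 4L, group_size = 1L)[1, ], "rot_4")
  expect_equal(nrow(r), 4L)
  bad <- stub_patchset(1, w = 4L, group_size = 1L)[1, ]
  bad$pixels[[1]] <- array(0, c(4, 6, 3))
  expect_error(augment_group(bad, "rot_4"), "square")
})

test_that("augmented datasets have complete groups that validate", {
  base <- stub_patchset(3, w = 4L, group_size = 1L)
  aug <- augment_dataset(base, "d4_8")
  expect_equal(nrow(aug), 24L)
  expect_silent(validate_patch_dataset(aug, 8L))
  expect_error(validate_patch_dataset(aug[-1, ], 8L), "invalid")
})

test_that("manifests round-trip exactly and report defects", {
  dir <- withr::local_tempdir()
  base <- stub_patchset(2, w = 4L, group_size = 1L)
  # quantise pixels to 8 bits so PNG storage is lossless
  base$pixels <- purrr::map(base$pixels, ~round(.x * 255) / 255)
  aug <- augment_dataset(base, "d4_8")
  mp <- file.path(dir, "manifest.csv")
  write_manifest(aug, mp)
  back <- read_manifest(mp, group_size = 8L)
  ord <- dplyr::arrange(aug, group_id, aug_index)
  expect_equal(back$assigned_label, ord$assigned_label)
  expect_equal(back$group_id, ord$group_id)
  expect_equal(back$aug_index, ord$aug_index)
  for (i in seq_len(nrow(back)))
    expect_equal(back$pixels[[i]], ord$pixels[[i]], tolerance = 1e-9)
  # writing what was read reproduces the same manifest table
  mp2 <- file.path(dir, "again.csv")
  write_manifest(back, mp2)
  cols <- c("patch_path", "slide_id", "assigned_label", "true_label",
            "grid_x", "grid_y", "group_id", "aug_index")
  expect_equal(utils::read.csv(mp)[cols], utils::read.csv(mp2)[cols])
  # defects: missing column, dangling path, incomplete group
  m <- utils::read.csv(mp)
  utils::write.csv(m[, -3], file.path(dir, "m1.csv"), row.names = FALSE)
  expect_error(read_manifest(file.path(dir, "m1.csv")), "lacks columns")
  m2 <- m; m2$patch_path[3] <- "patches/nope.png"
  utils::write.csv(m2, file.path(dir, "m2.csv"), row.names = FALSE)
  expect_error(read_manifest(file.path(dir, "m2.csv")), "rows: 3")
  utils::write.csv(m[-1, ], file.path(dir, "m3.csv"), row.names = FALSE)
  expect_error(read_manifest(file.path(dir, "m3.csv"), group_size = 8L),
               "invalid")
  # empty manifest: empty dataset, no error
  utils::write.csv(m[0, ], file.path(dir, "m0.csv"), row.names = FALSE)
  expect_equal(nrow(read_manifest(file.path(dir, "m0.csv"))), 0L)
})
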