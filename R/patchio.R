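# Sliding-window patch extraction with slide-label propagation, RoI
# masking for sparse slides, dihedral augmentation groups, and manifest
# I/O.  A patch dataset is a tibble with one row per (augmented) patch:
#   pixels (list of w x w x 3 arrays), slide_id, assigned_label,
#   true_label, grid_x, grid_y, group_id, aug_index, patch_id.

#' Sliding-window grid positions
#'
#' Top-left corners `(i*s, j*s)` with stride `s = round(w * (1 - overlap))`,
#' keeping only windows that lie fully inside the image (no padding, so
#' partial windows at the right/bottom edges are dropped).  With the
#' 2048 x 1536 slide geometry, 512-pixel windows and 50% overlap this
#' yields 35 windows per image.
#'
#' @param W,H Image width and height in pixels.
#' @param w Window side in pixels (`w <= min(W, H)`).
#' @param overlap Fractional window overlap in `[0, 1)`.
#' @return Tibble with 0-based integer columns `x`, `y`.
#' @export
grid_positions <- function(W, H, w, overlap = 0.5) {
  if (w > W || w > H) abort("window larger than image")
  if (overlap < 0 || overlap >= 1) abort("overlap must lie in [0, 1)")
  s <- as.integer(round(w * (1 - overlap)))
  if (s < 1L) abort("stride rounds to zero; decrease overlap")
  xs <- seq.int(0L, by = s, length.out = (W - w) %/% s + 1L)
  ys <- seq.int(0L, by = s, length.out = (H - w) %/% s + 1L)
  tidyr::expand_grid(y = as.integer(ys), x = as.integer(xs))[, c("x", "y")]
}

#' Binarize a slide into a tissue (region-of-interest) mask
#'
#' Otsu threshold on the luminance channel; tissue is the darker side
#' (stained tissue absorbs light, background is bright), followed by a
#' 3x3 majority smoothing.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @return H x W logical matrix, `TRUE` on tissue.
#' @export
binarize_roi <- function(image) {
  if (length(dim(image)) != 3 || any(dim(image)[1:2] < 1))
    abort("image must be a non-empty H x W x 3 array")
  lum <- 0.2126 * image[, , 1] + 0.7152 * image[, , 2] +
    0.0722 * image[, , 3]
  thr <- if (stats::sd(lum) < 1e-8) 0.5 else EBImage::otsu(lum, range = c(0, 1))
  mask <- lum < thr
  # 3x3 majority vote smoothing
  counts <- window_counts_3x3(mask)
  counts >= 5
}

# neighbourhood count (incl. self) with edge replication
window_counts_3x3 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  m <- mask[c(1L, 1:H, H), c(1L, 1:W, W)]
  out <- matrix(0L, H, W)
  for (dy in 0:2) for (dx in 0:2)
    out <- out + m[(1:H) + dy, (1:W) + dx]
  out
}

#' Extract patches from one slide, propagating the slide label
#'
#' Every kept grid window becomes one un-augmented patch record whose
#' `assigned_label` is the slide's label.  If an RoI mask is given,
#' windows with less than 50% foreground are dropped.  If a tumor mask is
#' given, the ground-truth label is recorded: the slide label when the
#' window's tumor-pixel fraction reaches `purity_threshold`, class 0
#' (normal) otherwise.
#'
#' @param slide A `synthetic_slide`, or a list with `pixels` and
#'   `slide_label`.
#' @param w Patch side in pixels.
#' @param overlap Window overlap fraction.
#' @param roi Optional H x W logical RoI mask (see [binarize_roi()]).
#' @param true_mask Optional H x W 0/1 tumor mask.
#' @param purity_threshold Tumor-purity rule for the true label.
#' @param slide_id Identifier recorded on every patch.
#' @return Patch tibble (one row per kept window, `aug_index = 0`).
#' @export
extract_patches <- function(slide, w, overlap = 0.5, roi = NULL,
                            true_mask = NULL, purity_threshold = 0.1,
                            slide_id = "slide") {
  px <- slide$pixels
  H <- dim(px)[1]; W <- dim(px)[2]
  pos <- grid_positions(W, H, w, overlap)
  if (!is.null(roi)) {
    fg <- window_sums(roi + 0L, w, pos) / w^2
    pos <- pos[fg >= 0.5, , drop = FALSE]
  }
  n <- nrow(pos)
  true_label <- rep(NA_integer_, n)
  if (!is.null(true_mask) && n > 0) {
    purity <- window_sums(true_mask, w, pos) / w^2
    true_label <- ifelse(purity >= purity_threshold,
                         as.integer(slide$slide_label), 0L)
  }
  pixels <- purrr::map2(pos$x, pos$y, function(x, y)
    px[(y + 1):(y + w), (x + 1):(x + w), , drop = FALSE])
  pid <- sprintf("%s_x%04d_y%04d", slide_id, pos$x, pos$y)
  tibble::tibble(patch_id = pid, slide_id = slide_id,
                 assigned_label = as.integer(slide$slide_label),
                 true_label = true_label,
                 grid_x = pos$x, grid_y = pos$y,
                 group_id = pid, aug_index = 0L, pixels = pixels)
}

rot90_array <- function(a) {
  # 90 degrees counter-clockwise, exact re-indexing per channel
  out <- array(0, c(dim(a)[2], dim(a)[1], dim(a)[3]))
  for (ch in seq_len(dim(a)[3]))
    out[, , ch] <- t(a[, , ch])[dim(a)[2]:1, , drop = FALSE]
  out
}

flipv_array <- function(a) a[dim(a)[1]:1, , , drop = FALSE]

aug_transform <- function(a, aug_index, mode) {
  rot <- if (mode == "d4_8") aug_index %% 4L else aug_index
  flip <- mode == "d4_8" && aug_index >= 4L
  for (i in seq_len(rot)) a <- rot90_array(a)
  if (flip) a <- flipv_array(a)
  a
}

#' Expand one patch into its augmentation group
#'
#' Mode `"d4_8"` produces the 8 orientation variants of the square
#' (rotations by 0/90/180/270 degrees, then the vertical flip of each
#' rotation; the original is member 0) -- the dihedral group of the
#' square.  Mode `"rot_4"` produces the 4 rotations only.  All transforms
#' are exact array re-indexings; no interpolation.
#'
#' @param patch One-row patch tibble (as from [extract_patches()]).
#' @param mode `"d4_8"` or `"rot_4"`.
#' @return Patch tibble with `group_size` rows sharing `group_id`, with
#'   distinct `aug_index` `0 .. group_size - 1`.
#' @export
augment_group <- function(patch, mode = c("d4_8", "rot_4")) {
  mode <- match.arg(mode)
  stopifnot(nrow(patch) == 1L)
  a <- patch$pixels[[1L]]
  if (dim(a)[1] != dim(a)[2]) abort("rotation augmentation needs square patches")
  gs <- if (mode == "d4_8") 8L else 4L
  out <- patch[rep(1L, gs), ]
  out$aug_index <- 0:(gs - 1L)
  out$patch_id <- sprintf("%s_a%d", patch$group_id, out$aug_index)
  out$pixels <- purrr::map(out$aug_index, ~aug_transform(a, .x, mode))
  out
}

#' Augment every patch of a dataset
#'
#' @param data Un-augmented patch tibble (`aug_index` all 0).
#' @param mode See [augment_group()].
#' @return Augmented patch tibble, `group_size`-fold larger, ordered by
#'   group then `aug_index`.
#' @export
augment_dataset <- function(data, mode = c("d4_8", "rot_4")) {
  mode <- match.arg(mode)
  if (nrow(data) == 0L) return(data)
  out <- dplyr::bind_rows(purrr::map(seq_len(nrow(data)), function(i)
    augment_group(data[i, ], mode)))
  attr(out, "group_size") <- if (mode == "d4_8") 8L else 4L
  out
}

#' Extract (and optionally augment) patches from a whole corpus
#'
#' Convenience pipeline: [extract_patches()] over every slide of a
#' [generate_corpus()] result, recording ground-truth labels from the
#' tumor masks, then [augment_dataset()].
#'
#' @param corpus A `synthetic_corpus`.
#' @param w,overlap,purity_threshold See [extract_patches()].
#' @param mode Augmentation mode, or `"none"`.
#' @param roi If `TRUE`, apply [binarize_roi()] per slide.
#' @return Patch tibble.
#' @export
extract_corpus_patches <- function(corpus, w, overlap = 0.5,
                                   purity_threshold = 0.1,
                                   mode = c("d4_8", "rot_4", "none"),
                                   roi = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(corpus, "synthetic_corpus"))
  base <- dplyr::bind_rows(purrr::map2(
    corpus$slides, corpus$manifest$slide_id,
    function(s, id) extract_patches(
      s, w, overlap,
      roi = if (roi) binarize_roi(s$pixels) else NULL,
      true_mask = s$tumor_mask, purity_threshold = purity_threshold,
      slide_id = id)))
  if (mode == "none") base else augment_dataset(base, mode)
}

#' Validate patch-dataset invariants
#'
#' Checks that every augmentation group is complete (exactly
#' `group_size` members with distinct `aug_index` covering
#' `0 .. group_size - 1`) and shares `slide_id`, grid position and
#' `assigned_label`.
#'
#' @param data Patch tibble.
#' @param group_size Expected group size.
#' @return Invisibly `TRUE`; aborts with the offending group otherwise.
#' @export
validate_patch_dataset <- function(data, group_size) {
  bad <- data |>
    dplyr::summarise(
      n = dplyr::n(),
      ok_aug = identical(sort(.data$aug_index), 0:(group_size - 1L)),
      n_slide = dplyr::n_distinct(.data$slide_id),
      n_lab = dplyr::n_distinct(.data$assigned_label),
      .by = "group_id") |>
    dplyr::filter(.data$n != group_size | !.data$ok_aug |
                    .data$n_slide != 1L | .data$n_lab != 1L)
  if (nrow(bad) > 0)
    abort(c("invalid augmentation groups",
            stats::setNames(utils::head(bad$group_id, 5), rep("x", min(5, nrow(bad))))))
  invisible(TRUE)
}

MANIFEST_COLS <- c("patch_path", "slide_id", "assigned_label", "true_label",
                   "grid_x", "grid_y", "group_id", "aug_index")

#' Write a patch dataset to disk (PNG patches + CSV manifest)
#'
#' @param data Patch tibble.
#' @param path Manifest CSV path; patches are written next to it under
#'   `patches/`.
#' @return The manifest tibble, invisibly.
#' @export
write_manifest <- function(data, path) {
  dir <- file.path(dirname(path), "patches")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data <- dplyr::arrange(data, .data$group_id, .data$aug_index)
  man <- tibble::tibble(
    patch_path = file.path("patches", paste0(data$patch_id, ".png")),
    slide_id = data$slide_id, assigned_label = data$assigned_label,
    true_label = data$true_label, grid_x = data$grid_x,
    grid_y = data$grid_y, group_id = data$group_id,
    aug_index = data$aug_index)
  purrr::walk2(data$pixels, man$patch_path, function(px, p)
    png::writePNG(px, file.path(dirname(path), p)))
  utils::write.csv(man, path, row.names = FALSE)
  invisible(man)
}

#' Read a patch dataset from a manifest CSV
#'
#' Errors report missing columns and dangling patch paths with row
#' numbers.  Reading back a written dataset reproduces the records
#' (pixels are 8-bit exact).
#'
#' @param path Manifest CSV path.
#' @param group_size If given, group completeness is validated.
#' @return Patch tibble.
#' @export
read_manifest <- function(path, group_size = NULL) {
  man <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  missing <- setdiff(MANIFEST_COLS, names(man))
  if (length(missing) > 0)
    abort(sprintf("manifest lacks columns: %s",
                  paste(missing, collapse = ", ")))
  if (nrow(man) == 0L)
    return(tibble::tibble(patch_id = character(), slide_id = character(),
                          assigned_label = integer(), true_label = integer(),
                          grid_x = integer(), grid_y = integer(),
                          group_id = character(), aug_index = integer(),
                          pixels = list()))
  full <- file.path(dirname(path), man$patch_path)
  gone <- which(!file.exists(full))
  if (length(gone) > 0)
    abort(sprintf("dangling patch paths at manifest rows: %s",
                  paste(utils::head(gone, 10), collapse = ", ")))
  out <- tibble::tibble(
    patch_id = sub("\\.png$", "", basename(man$patch_path)),
    slide_id = man$slide_id,
    assigned_label = as.integer(man$assigned_label),
    true_label = suppressWarnings(as.integer(man$true_label)),
    grid_x = as.integer(man$grid_x), grid_y = as.integer(man$grid_y),
    group_id = man$group_id, aug_index = as.integer(man$aug_index),
    pixels = purrr::map(full, png::readPNG))
  if (!is.null(group_size)) validate_patch_dataset(out, group_size)
  out
}
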