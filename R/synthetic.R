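# Synthetic slide corpora with known tumor masks.  Slides are procedural
# band-limited noise textures: every class has its own spatial frequency
# band and colour palette, non-normal slides carry elliptical tumor lesions
# painted in the class texture over a normal-tissue background.  Because
# the tumor mask is known exactly, propagating the slide label to patches
# produces a *known* set of mislabeled normal-tissue patches -- the
# ground truth against which the reverse-active-learning removals are
# scored.

#' Texture specification for one tissue class
#'
#' @param class_id Integer class index (0 = normal tissue).
#' @param base_frequency Spatial frequency of the band-limited texture,
#'   in cycles/pixel (> 0).
#' @param contrast Texture amplitude in `[0, 1]`.
#' @param palette Length-3 RGB means in `[0, 1]`.
#' @return A `texture_spec` list.
#' @export
texture_spec <- function(class_id, base_frequency, contrast, palette) {
  if (base_frequency <= 0) abort("base_frequency must be > 0")
  if (contrast < 0 || contrast > 1) abort("contrast must lie in [0, 1]")
  if (length(palette) != 3 || any(palette < 0 | palette > 1))
    abort("palette must be 3 RGB values in [0, 1]")
  structure(list(class_id = as.integer(class_id),
                 base_frequency = base_frequency, contrast = contrast,
                 palette = palette),
            class = "texture_spec")
}

#' Default texture palette for up to eight classes
#'
#' Class 0 mimics pale eosinophilic normal tissue; the tumor classes use
#' adjacent hematoxylin-like hues and neighbouring frequency bands, so the
#' classes are separable by a small CNN but not trivially so -- real
#' tissue categories differ subtly.
#'
#' @param n_classes Number of classes (2--8).
#' @return List of [texture_spec()] objects.
#' @export
default_textures <- function(n_classes = 4L) {
  stopifnot(n_classes >= 2, n_classes <= 8)
  palettes <- list(c(0.91, 0.75, 0.79),  # normal: pale pink
                   c(0.62, 0.44, 0.66),  # violet
                   c(0.48, 0.40, 0.71),  # blue-violet
                   c(0.71, 0.42, 0.53),  # mauve
                   c(0.55, 0.55, 0.70),
                   c(0.75, 0.55, 0.45),
                   c(0.45, 0.60, 0.55),
                   c(0.65, 0.65, 0.45))
  freqs <- 0.035 * 1.6^(0:7)
  purrr::map(seq_len(n_classes) - 1L, function(k)
    texture_spec(k, freqs[k + 1], contrast = 0.35,
                 palette = palettes[[k + 1]]))
}

#' Corpus configuration
#'
#' @param n_slides_per_class Slides generated per class.
#' @param slide_size `(W, H)` slide size in pixels.
#' @param tumor_fraction Target fraction of slide area covered by tumor
#'   texture on non-normal slides, in `[0, 1]`.
#' @param n_classes Number of classes K (>= 2); class 0 is normal.
#' @param seed Integer master seed; per-slide seeds are derived from it
#'   by a fixed hash.
#' @param textures Optional list of [texture_spec()]; defaults to
#'   [default_textures()].
#' @return A `corpus_config` list.
#' @export
corpus_config <- function(n_slides_per_class = 8L, slide_size = c(256L, 256L),
                          tumor_fraction = 0.3, n_classes = 4L, seed = 1L,
                          textures = default_textures(n_classes)) {
  if (tumor_fraction < 0 || tumor_fraction > 1)
    abort("tumor_fraction must lie in [0, 1]")
  if (n_classes < 2) abort("n_classes must be >= 2")
  structure(list(n_slides_per_class = as.integer(n_slides_per_class),
                 slide_size = as.integer(slide_size),
                 tumor_fraction = tumor_fraction,
                 n_classes = as.integer(n_classes), seed = as.integer(seed),
                 textures = textures),
            class = "corpus_config")
}

# deterministic per-slide seed from (master seed, class, index)
derive_seed <- function(seed, class_id, index) {
  as.integer((as.double(seed) * 48271 + class_id * 2654435 + index * 9973) %%
               2147483647)
}

# band-limited Gaussian noise field via FFT annulus filtering
texture_field <- function(W, H, freq) {
  z <- matrix(rnorm(W * H), H, W)
  fz <- stats::fft(z)
  fy <- ifelse(seq_len(H) - 1 <= H / 2, seq_len(H) - 1, seq_len(H) - 1 - H) / H
  fx <- ifelse(seq_len(W) - 1 <= W / 2, seq_len(W) - 1, seq_len(W) - 1 - W) / W
  r <- sqrt(outer(fy^2, fx^2, `+`))
  g <- exp(-((r - freq) / (0.5 * freq))^2)
  f <- Re(stats::fft(fz * g, inverse = TRUE)) / (W * H)
  f / max(stats::sd(f), 1e-12)
}

# paint one class texture over the full slide; returns H x W x 3 array
paint_texture <- function(W, H, spec) {
  base <- texture_field(W, H, spec$base_frequency)
  # per-slide brightness jitter emulates scanner/stain variation
  shift <- runif(1, -0.05, 0.05)
  px <- array(0, c(H, W, 3))
  for (ch in 1:3)
    px[, , ch] <- spec$palette[ch] + shift + (spec$contrast / 3) * base
  pmin(pmax(px, 0), 1)
}

ellipse_mask <- function(W, H, cx, cy, a, b, theta) {
  xs <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  ys <- matrix(seq_len(H), H, W) - cy
  u <- xs * cos(theta) + ys * sin(theta)
  v <- -xs * sin(theta) + ys * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate one synthetic slide
#'
#' Non-normal slides accrete random ellipses of the class texture over a
#' normal-tissue background until the tumor mask covers
#' `tumor_fraction` (within 0.05) of the slide; the mask marks tumor
#' pixels exactly.  Normal (class 0) slides have an all-zero mask.
#' Pixels are quantised to 8-bit levels so PNG round trips are exact.
#'
#' @param label Class index in `[0, n_classes)`.
#' @param config A [corpus_config()].
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A `synthetic_slide`: list with `pixels` (H x W x 3 array in
#'   `[0, 1]`), `slide_label`, `tumor_mask` (H x W 0/1 matrix) and `seed`.
#' @export
generate_slide <- function(label, config, seed = config$seed) {
  stopifnot(inherits(config, "corpus_config"))
  label <- as.integer(label)
  if (label < 0 || label >= config$n_classes)
    abort(sprintf("label must lie in [0, %d)", config$n_classes))
  W <- config$slide_size[1]; H <- config$slide_size[2]
  tf <- config$tumor_fraction
  withr::with_seed(as.integer(seed), {
    px <- paint_texture(W, H, config$textures[[1L]])
    mask <- matrix(0L, H, W)
    if (label > 0L && tf > 0) {
      if (tf >= 0.999) {
        mask[] <- 1L
      } else {
        # lesion scale calibrated so the default corpus settings induce
        # roughly 20% patch-label noise under 64 px / 50% overlap
        # extraction with purity threshold 0.1
        rmax <- 0.11 * min(W, H)
        for (i in seq_len(500L)) {
          cur <- mean(mask)
          if (cur >= tf) break
          rem <- (tf - cur) * W * H
          r <- min(sqrt(rem / pi), rmax)
          a <- r * runif(1, 0.6, 1.1); b <- (r * r) / a
          e <- ellipse_mask(W, H, runif(1, 1, W), runif(1, 1, H), a, b,
                            runif(1, 0, pi))
          mask[e] <- 1L
        }
        if (abs(mean(mask) - tf) > 0.05)
          abort("tumor accretion failed to reach the target fraction")
      }
      tum <- paint_texture(W, H, config$textures[[label + 1L]])
      sel <- mask == 1L
      for (ch in 1:3) {
        pl <- px[, , ch]; tl <- tum[, , ch]
        pl[sel] <- tl[sel]
        px[, , ch] <- pl
      }
    }
    px <- round(px * 255) / 255
    structure(list(pixels = px, slide_label = label, tumor_mask = mask,
                   seed = as.integer(seed)),
              class = "synthetic_slide")
  })
}

#' Generate a synthetic slide corpus
#'
#' `n_slides_per_class * n_classes` slides with a tibble manifest
#' (`slide_id`, `label`, `seed`, and file paths when `dir` is given).
#' The whole corpus is reproducible from `config$seed`.
#'
#' @param config A [corpus_config()].
#' @param dir Optional directory: slides are written as 8-bit RGB PNG and
#'   masks as single-channel PNG, and the manifest gains `path` /
#'   `mask_path` columns.
#' @return A `synthetic_corpus`: list with `slides` (list of
#'   [generate_slide()] results) and `manifest` (tibble).
#' @export
generate_corpus <- function(config, dir = NULL) {
  stopifnot(inherits(config, "corpus_config"))
  grid <- tidyr::expand_grid(label = seq_len(config$n_classes) - 1L,
                             index = seq_len(config$n_slides_per_class))
  slides <- purrr::pmap(grid, function(label, index) {
    generate_slide(label, config,
                   seed = derive_seed(config$seed, label, index))
  })
  manifest <- tibble::tibble(
    slide_id = sprintf("s%02d_c%d", seq_len(nrow(grid)), grid$label),
    label = grid$label,
    seed = purrr::map_int(slides, "seed"),
    path = NA_character_, mask_path = NA_character_)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest$path <- file.path(dir, paste0(manifest$slide_id, ".png"))
    manifest$mask_path <- file.path(dir, paste0(manifest$slide_id,
                                                "_mask.png"))
    purrr::pwalk(list(slides, manifest$path, manifest$mask_path),
                 function(s, p, mp) {
                   png::writePNG(s$pixels, p)
                   png::writePNG(s$tumor_mask + 0, mp)
                 })
    utils::write.csv(manifest[, c("path", "label", "seed", "mask_path")],
                     file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  structure(list(slides = slides, manifest = manifest, config = config),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus> %d slides (%d classes x %d), %dx%d px, tumor fraction %.2f\n",
              length(x$slides), x$config$n_classes,
              x$config$n_slides_per_class, x$config$slide_size[1],
              x$config$slide_size[2], x$config$tumor_fraction))
  invisible(x)
}

# Windowed sums of a mask over the extraction grid, via an integral image.
# Masks are H x W matrices (rows = y); positions are 0-based (x, y).
window_sums <- function(mask, w, pos) {
  ii <- rbind(0, cbind(0, t(apply(apply(mask, 2, cumsum), 1, cumsum))))
  x0 <- pos$x; y0 <- pos$y
  ii[cbind(y0 + w + 1L, x0 + w + 1L)] - ii[cbind(y0 + 1L, x0 + w + 1L)] -
    ii[cbind(y0 + w + 1L, x0 + 1L)] + ii[cbind(y0 + 1L, x0 + 1L)]
}

#' Ground-truth fraction of mislabeled patches in a corpus
#'
#' Under slide-label propagation, a patch on a non-normal slide whose
#' tumor-pixel fraction falls below `purity_threshold` is really normal
#' tissue carrying a cancer label.  This returns the fraction of such
#' patches over the full extraction grid -- the injected label-noise rate
#' that the reverse-active-learning removals are later scored against.
#'
#' @param corpus A `synthetic_corpus`.
#' @param patch_size Patch side in pixels.
#' @param overlap Window overlap fraction in `[0, 1)`.
#' @param purity_threshold Minimum tumor-pixel fraction for a patch to
#'   genuinely carry its slide's label, in `(0, 1]`.
#' @return Fraction in `[0, 1]`.
#' @export
expected_noise_rate <- function(corpus, patch_size, overlap = 0.5,
                                purity_threshold = 0.1) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  if (purity_threshold <= 0 || purity_threshold > 1)
    abort("purity_threshold must lie in (0, 1]")
  total <- 0L; mislabeled <- 0L
  for (s in corpus$slides) {
    W <- ncol(s$tumor_mask); H <- nrow(s$tumor_mask)
    pos <- grid_positions(W, H, patch_size, overlap)
    total <- total + nrow(pos)
    if (s$slide_label > 0L) {
      purity <- window_sums(s$tumor_mask, patch_size, pos) / patch_size^2
      mislabeled <- mislabeled + sum(purity < purity_threshold)
    }
  }
  mislabeled / total
}
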