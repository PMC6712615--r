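# Fixture builders shared across test files.  Everything is generated in
# code; no stored data.

# random-pixel patch tibble with complete augmentation groups
stub_patchset <- function(n_groups, n_classes = 4L, w = 8L,
                          group_size = 8L, seed = 1L,
                          slides = paste0("sl", 1:4)) {
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(n_groups), function(g) {
      lab <- (g - 1L) %% n_classes
      sid <- slides[(g - 1L) %% length(slides) + 1L]
      gid <- sprintf("g%03d", g)
      tibble::tibble(
        patch_id = sprintf("%s_a%d", gid, 0:(group_size - 1L)),
        slide_id = sid, assigned_label = lab, true_label = lab,
        grid_x = g, grid_y = 0L, group_id = gid,
        aug_index = 0:(group_size - 1L),
        pixels = purrr::map(0:(group_size - 1L), function(i)
          array(runif(w * w * 3), c(w, w, 3))))
    })
    dplyr::bind_rows(rows)
  })
}

# a probability matrix with a fixed maximum per row
probs_with_max <- function(n, k, maxp) {
  rest <- (1 - maxp) / (k - 1)
  m <- matrix(rest, n, k)
  m[, 1] <- maxp
  m
}

# tiny two-texture separable patch set: class 0 dark-red-ish, class 1
# light-blue-ish, plus pixel noise
separable_patchset <- function(n_per_class, w = 32L, seed = 1L,
                               n_classes = 2L) {
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(n_per_class * n_classes), function(i) {
      lab <- (i - 1L) %% n_classes
      base <- c(0.2, 0.45, 0.7, 0.9)[lab + 1L]
      px <- array(pmin(pmax(base + rnorm(w * w * 3, sd = 0.08), 0), 1),
                  c(w, w, 3))
      tibble::tibble(patch_id = sprintf("p%04d", i), slide_id = "s1",
                     assigned_label = lab, true_label = lab,
                     grid_x = i, grid_y = 0L,
                     group_id = sprintf("p%04d", i), aug_index = 0L,
                     pixels = list(px))
    })
    dplyr::bind_rows(rows)
  })
}

# brute-force oracle for sliding-window corners
grid_oracle <- function(W, H, w, overlap) {
  s <- as.integer(round(w * (1 - overlap)))
  out <- list()
  for (y in seq(0L, H, by = s)) {
    if (y + w > H) next
    for (x in seq(0L, W, by = s)) {
      if (x + w > W) next
      out[[length(out) + 1L]] <- c(x, y)
    }
  }
  do.call(rbind, out)
}

# direct (unstabilised) evaluation of the softmax loss formula
naive_softmax_loss <- function(scores, labels) {
  n <- nrow(scores)
  mean(vapply(seq_len(n), function(i) {
    -log(exp(scores[i, labels[i] + 1]) / sum(exp(scores[i, ])))
  }, numeric(1)))
}
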