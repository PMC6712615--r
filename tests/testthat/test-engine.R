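# Numerical checks of the compute engine: convolution against a direct
# R implementation, finite-difference gradient checks through a graph
# containing every layer kind, and agreement between the per-layer
# reference path and the whole-epoch fast path.

# direct dilated 'same' convolution in plain R
naive_conv <- function(x, wt, k, dil, Cout) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  pad <- (k - 1) * dil / 2
  out <- array(0, c(H, W, Cout))
  for (co in 1:Cout) {
    for (oy in 1:H) for (ox in 1:W) {
      acc <- 0
      for (ci in 1:Cin) for (kw in 1:k) for (kh in 1:k) {
        iy <- oy + (kh - 1) * dil - pad
        ix <- ox + (kw - 1) * dil - pad
        if (iy >= 1 && iy <= H && ix >= 1 && ix <= W) {
          r <- (kh - 1) + k * (kw - 1) + k * k * (ci - 1) + 1
          acc <- acc + x[iy, ix, ci] * wt[r, co]
        }
      }
      out[oy, ox, co] <- acc
    }
  }
  out
}

test_that("the convolution kernel matches direct evaluation, incl. dilation", {
  withr::with_seed(5, {
    for (dil in 1:3) {
      H <- 9L; Cin <- 2L; Cout <- 3L; k <- 3L
      x <- array(rnorm(H * H * Cin), c(H, H, Cin))
      wt <- matrix(rnorm(k * k * Cin * Cout), k * k * Cin, Cout)
      got <- dralnet:::cpp_conv_fwd(matrix(as.double(x), ncol = 1),
                                    H, H, Cin, wt, numeric(Cout),
                                    k, dil, 1L, ((k - 1L) * dil) %/% 2L,
                                    FALSE)$Y
      want <- naive_conv(x, wt, k, dil, Cout)
      expect_equal(as.vector(got), as.vector(want), tolerance = 1e-5)
    }
  })
})

test_that("pooling kernels behave as tiled max / mean", {
  x <- matrix(as.double(1:16), ncol = 1)  # 4x4x1 image
  mp <- dralnet:::cpp_maxpool_fwd(x, 4L, 4L, 1L, 2L)
  expect_equal(as.vector(mp$Y), c(6, 8, 14, 16))
  ap <- dralnet:::cpp_avgpool_fwd(x, 4L, 4L, 1L, 2L, 2L)
  expect_equal(as.vector(ap), c(3.5, 5.5, 11.5, 13.5))
  gap <- dralnet:::cpp_avgpool_fwd(x, 4L, 4L, 1L, 4L, 4L)
  expect_equal(as.vector(gap), 8.5)
})

# builds a small graph that exercises conv, atrous conv, bn, prelu,
# max/avg pooling, dense concatenation, global pooling and the fc head
tiny_graph <- function() {
  cfg <- adn_config(n_classes = 3L, input_size = 8L, stem_channels = 4L,
                    growth_rates = c(2L, 3L), layers_per_module = 2L,
                    nin_channels = 4L)
  build_adn(cfg)
}

test_that("backpropagated gradients match central finite differences", {
  g <- tiny_graph()
  model <- dralnet:::init_model(g, seed = 7)
  withr::with_seed(8, {
    X <- matrix(runif(8 * 8 * 3 * 4), ncol = 4)
    y <- c(0L, 1L, 2L, 0L)
  })
  loss_at <- function(m) {
    fw <- dralnet:::forward_pass(m, X, training = TRUE)
    dralnet:::softmax_xent(fw$out, y)$loss
  }
  fw <- dralnet:::forward_pass(model, X, training = TRUE)
  ls <- dralnet:::softmax_xent(fw$out, y)
  grads <- dralnet:::backward_pass(model, fw, ls$dscores)
  # central differences cross max-pool/PReLU kinks for some entries, so
  # the check is robust: the bulk of sampled coordinates must agree well
  h <- 1e-3
  withr::with_seed(42, {
    rel <- c()
    for (id in seq_along(grads)) {
      if (is.null(grads[[id]])) next
      for (nm in names(grads[[id]])) {
        v <- model$params[[id]][[nm]]
        for (j in sample(seq_along(v), min(2, length(v)))) {
          mp <- model; mp$params[[id]][[nm]][j] <- v[j] + h
          mm <- model; mm$params[[id]][[nm]][j] <- v[j] - h
          fd <- (loss_at(mp) - loss_at(mm)) / (2 * h)
          an <- grads[[id]][[nm]][j]
          rel <- c(rel, abs(an - fd) / max(abs(an), abs(fd), 0.05))
        }
      }
    }
    expect_gt(length(rel), 40L)
    expect_lt(stats::median(rel), 0.01)
    expect_gte(mean(rel < 0.05), 0.9)
  })
})

test_that("the whole-epoch fast path agrees with the per-layer reference path", {
  g <- tiny_graph()
  model <- dralnet:::init_model(g, seed = 3)
  withr::with_seed(4, {
    X <- matrix(runif(8 * 8 * 3 * 12), ncol = 12)
    y <- sample(0:2, 12, TRUE)
  })
  # identical SGD trajectory, computed twice
  ref <- model; vel <- vector("list", length(model$params))
  losses_ref <- numeric(3)
  for (b in 1:3) {
    ix <- ((b - 1) * 4 + 1):(b * 4)
    fw <- dralnet:::forward_pass(ref, X[, ix], training = TRUE)
    ref <- fw$model
    ls <- dralnet:::softmax_xent(fw$out, y[ix])
    losses_ref[b] <- ls$loss
    gr <- dralnet:::backward_pass(ref, fw, ls$dscores)
    up <- dralnet:::sgd_step(ref, gr, vel, lr = 0.05)
    ref <- up$model; vel <- up$velocity
  }
  enc <- dralnet:::encode_graph(g)
  velocity <- vector("list", length(model$params))
  r <- dralnet:::cpp_run_epoch(enc, model$params, velocity, model$state,
                               X, y, 0:11, 4L, 0.05, 0.9, 3L, 1e-5, 0.9)
  expect_equal(r$loss, mean(losses_ref), tolerance = 1e-3)
  # parameters after one epoch agree across the two implementations
  for (id in seq_along(ref$params)) {
    for (nm in names(ref$params[[id]])) {
      expect_equal(as.vector(r$params[[id]][[nm]]),
                   as.vector(ref$params[[id]][[nm]]), tolerance = 1e-3)
    }
  }
  # and eval-mode predictions agree
  p_cpp <- dralnet:::cpp_predict_probs(enc, r$params, r$state, X, 5L, 3L,
                                       1e-5)
  ref$params <- r$params; ref$state <- r$state
  fw <- dralnet:::forward_pass(ref, X, training = FALSE)
  p_ref <- t(apply(fw$out, 2, function(s) exp(s - max(s)) /
                                            sum(exp(s - max(s)))))
  expect_equal(p_cpp, p_ref, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("input stacking downscales by exact block means", {
  px <- list(array(as.double(1:48), c(4, 4, 3)))
  M <- dralnet:::build_input_matrix(px, 2L)
  direct <- as.vector(vapply(1:3, function(ch) {
    a <- array(as.double(1:48), c(4, 4, 3))[, , ch]
    c(mean(a[1:2, 1:2]), mean(a[3:4, 1:2]), mean(a[1:2, 3:4]),
      mean(a[3:4, 3:4]))
  }, numeric(4)))
  expect_equal(as.vector(M), direct)
})
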