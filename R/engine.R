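# Execution engine for model graphs: parameter initialisation, forward and
# backward passes over the layer list, and SGD-with-momentum updates.  All
# heavy kernels (convolution, pooling, batch norm, PReLU) live in
# src/nn.cpp; this file only routes activations through the graph.
# Activations are matrices with one column per sample, rows ordered
# h-fastest, then w, then channel.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

init_model <- function(graph, seed = 0L) {
  stopifnot(inherits(graph, "model_graph"))
  params <- vector("list", length(graph$nodes))
  state <- vector("list", length(graph$nodes))
  withr::with_seed(as.integer(seed), {
    for (nd in graph$nodes) {
      params[[nd$id]] <- switch(nd$kind,
        conv = , atrous_conv = , nin_conv1x1 = {
          fan_in <- nd$kernel^2 * nd$c_in
          list(W = matrix(rnorm(fan_in * nd$out_channels,
                                sd = sqrt(2 / fan_in)),
                          nrow = fan_in),
               b = numeric(nd$out_channels))
        },
        fully_connected =
          list(W = matrix(rnorm(nd$in_features * nd$out_channels,
                                sd = sqrt(2 / nd$in_features)),
                          nrow = nd$out_channels),
               b = numeric(nd$out_channels)),
        batch_norm = list(gamma = rep(1, nd$c_in), beta = numeric(nd$c_in)),
        activation = list(a = rep(0.25, nd$c_in)),
        NULL)
      if (nd$kind == "batch_norm")
        state[[nd$id]] <- list(mean = numeric(nd$c_in), var = rep(1, nd$c_in),
                               steps = 0)
    }
  })
  structure(list(graph = graph, params = params, state = state,
                 n_classes = graph$n_classes),
            class = "nn_model")
}

forward_pass <- function(model, X, training = FALSE) {
  nodes <- model$graph$nodes
  acts <- vector("list", length(nodes) + 1L)
  caches <- vector("list", length(nodes))
  acts[[1L]] <- X
  for (nd in nodes) {
    xin <- if (nd$kind == "concat" && length(nd$inputs) > 1L)
      do.call(rbind, acts[nd$inputs + 1L])
    else acts[[nd$inputs[1L] + 1L]]
    p <- model$params[[nd$id]]
    hw <- nd$h_in * nd$w_in
    y <- switch(nd$kind,
      conv = , atrous_conv = , nin_conv1x1 = {
        r <- cpp_conv_fwd(xin, nd$h_in, nd$w_in, nd$c_in, p$W, p$b,
                          nd$kernel, nd$dilation, nd$stride, nd$pad,
                          keep_cols = training)
        caches[[nd$id]] <- r$cols
        r$Y
      },
      max_pool = {
        r <- cpp_maxpool_fwd(xin, nd$h_in, nd$w_in, nd$c_in, nd$kernel)
        caches[[nd$id]] <- r$idx
        r$Y
      },
      avg_pool =
        cpp_avgpool_fwd(xin, nd$h_in, nd$w_in, nd$c_in, nd$kernel, nd$kernel),
      global_avg_pool =
        cpp_avgpool_fwd(xin, nd$h_in, nd$w_in, nd$c_in,
                        nd$kernel_h, nd$kernel_w),
      fully_connected = p$W %*% xin + p$b,
      batch_norm = {
        st <- model$state[[nd$id]]
        # debiased running statistics: cumulative average first, then
        # exponential with BN_MOMENTUM
        mom <- min(BN_MOMENTUM, st$steps / (st$steps + 1))
        r <- cpp_bn_fwd(xin, hw, nd$c_in, p$gamma, p$beta,
                        st$mean, st$var, training, BN_EPS, mom)
        if (training)
          model$state[[nd$id]] <- list(mean = r$mean, var = r$var,
                                       steps = st$steps + 1)
        caches[[nd$id]] <- list(mu = r$mu, invstd = r$invstd,
                                batch_stats = training)
        r$Y
      },
      activation = cpp_prelu_fwd(xin, hw, nd$c_in, p$a),
      concat = xin)
    acts[[nd$id + 1L]] <- y
  }
  list(out = acts[[length(nodes) + 1L]], acts = acts, caches = caches,
       model = model)
}

backward_pass <- function(model, fw, dOut) {
  nodes <- model$graph$nodes
  acts <- fw$acts
  grads <- vector("list", length(nodes))
  gacc <- vector("list", length(nodes) + 1L)
  gacc[[length(nodes) + 1L]] <- dOut
  add_grad <- function(slot, g) {
    gacc[[slot]] <<- if (is.null(gacc[[slot]])) g else gacc[[slot]] + g
  }
  for (nd in rev(nodes)) {
    dY <- gacc[[nd$id + 1L]]
    if (is.null(dY)) next
    gacc[[nd$id + 1L]] <- NA  # free
    xin <- acts[[nd$inputs[1L] + 1L]]
    p <- model$params[[nd$id]]
    hw <- nd$h_in * nd$w_in
    switch(nd$kind,
      conv = , atrous_conv = , nin_conv1x1 = {
        r <- cpp_conv_bwd(fw$caches[[nd$id]], dY, nd$h_in, nd$w_in,
                          nd$c_in, p$W, nd$kernel, nd$dilation, nd$stride,
                          nd$pad)
        grads[[nd$id]] <- list(W = r$dW, b = r$db)
        add_grad(nd$inputs + 1L, r$dX)
      },
      max_pool =
        add_grad(nd$inputs + 1L,
                 cpp_maxpool_bwd(dY, fw$caches[[nd$id]], hw * nd$c_in)),
      avg_pool =
        add_grad(nd$inputs + 1L,
                 cpp_avgpool_bwd(dY, nd$h_in, nd$w_in, nd$c_in,
                                 nd$kernel, nd$kernel)),
      global_avg_pool =
        add_grad(nd$inputs + 1L,
                 cpp_avgpool_bwd(dY, nd$h_in, nd$w_in, nd$c_in,
                                 nd$kernel_h, nd$kernel_w)),
      fully_connected = {
        grads[[nd$id]] <- list(W = dY %*% t(xin),
                               b = .rowSums(dY, nrow(dY), ncol(dY)))
        add_grad(nd$inputs + 1L, crossprod(p$W, dY))
      },
      batch_norm = {
        cache <- fw$caches[[nd$id]]
        r <- cpp_bn_bwd(xin, dY, hw, nd$c_in, p$gamma, cache$mu,
                        cache$invstd, cache$batch_stats)
        grads[[nd$id]] <- list(gamma = r$dgamma, beta = r$dbeta)
        add_grad(nd$inputs + 1L, r$dX)
      },
      activation = {
        r <- cpp_prelu_bwd(xin, dY, hw, nd$c_in, p$a)
        grads[[nd$id]] <- list(a = r$da)
        add_grad(nd$inputs + 1L, r$dX)
      },
      concat = {
        if (length(nd$inputs) == 1L) {
          add_grad(nd$inputs + 1L, dY)
        } else {
          sizes <- vapply(nd$inputs + 1L, function(i) nrow(acts[[i]]),
                          integer(1))
          off <- cumsum(c(0L, sizes))
          for (j in seq_along(nd$inputs))
            add_grad(nd$inputs[j] + 1L,
                     dY[(off[j] + 1L):off[j + 1L], , drop = FALSE])
        }
      })
  }
  grads
}

# cross-entropy over softmax scores; labels are 0-based class indices
softmax_xent <- function(scores, labels) {
  K <- nrow(scores); N <- ncol(scores)
  mx <- apply(scores, 2L, max)
  sh <- sweep(scores, 2L, mx)
  lse <- log(.colSums(exp(sh), K, N))
  idx <- cbind(labels + 1L, seq_len(N))
  loss <- mean(lse - sh[idx])
  probs <- exp(sweep(sh, 2L, lse))
  dscores <- probs
  dscores[idx] <- dscores[idx] - 1
  list(loss = loss, dscores = dscores / N, probs = probs)
}

sgd_step <- function(model, grads, velocity, lr, momentum = 0.9) {
  for (id in seq_along(grads)) {
    g <- grads[[id]]
    if (is.null(g)) next
    for (nm in names(g)) {
      v <- velocity[[id]][[nm]]
      if (is.null(v)) v <- 0
      v <- momentum * v - lr * g[[nm]]
      velocity[[id]][[nm]] <- v
      model$params[[id]][[nm]] <- model$params[[id]][[nm]] + v
    }
  }
  list(model = model, velocity = velocity)
}

# Integer-coded graph layout consumed by the C++ fast path (one call per
# training epoch).  Kind codes: 1 conv (any dilation), 2 max pool,
# 3 avg pool (incl. global), 4 fully connected, 5 batch norm, 6 PReLU,
# 7 concat.
encode_graph <- function(graph) {
  code <- c(conv = 1L, atrous_conv = 1L, nin_conv1x1 = 1L, max_pool = 2L,
            avg_pool = 3L, global_avg_pool = 3L, fully_connected = 4L,
            batch_norm = 5L, activation = 6L, concat = 7L)
  lapply(graph$nodes, function(nd) {
    kh <- if (nd$kind == "global_avg_pool") nd$kernel_h
          else if (nd$kind == "avg_pool") nd$kernel else 0L
    kw <- if (nd$kind == "global_avg_pool") nd$kernel_w
          else if (nd$kind == "avg_pool") nd$kernel else 0L
    z <- function(x) if (is.null(x) || is.na(x)) 0L else as.integer(x)
    list(geom = c(code[[nd$kind]], z(nd$h_in), z(nd$w_in), z(nd$c_in),
                  z(nd$h_out), z(nd$w_out), z(nd$c_out), z(nd$kernel),
                  z(nd$dilation), z(nd$stride), z(nd$pad), z(kh), z(kw),
                  z(nd$in_features)),
         inputs = as.integer(nd$inputs))
  })
}

# Refresh batch-norm running statistics at the current weights.  During
# short trainings with a large learning rate the exponential running
# averages lag the fast-moving weights, so eval-mode normalisation (and
# with it every confidence estimate) would be stale.  One forward-only
# sweep over (a class-spanning sample of) the training inputs rebuilds
# the statistics as plain cumulative averages.
recalibrate_bn <- function(model, enc, Xall, n_cal = 2048L) {
  for (id in seq_along(model$state)) {
    if (!is.null(model$state[[id]]))
      model$state[[id]] <- list(mean = 0 * model$state[[id]]$mean,
                                var = 0 * model$state[[id]]$var + 1,
                                steps = 0)
  }
  n <- ncol(Xall)
  idx <- unique(round(seq(1L, n, length.out = min(n, n_cal))))
  r <- cpp_update_stats(enc, model$params, model$state,
                        Xall[, idx, drop = FALSE], 64L, BN_EPS,
                        BN_MOMENTUM)
  model$state <- r$state
  model
}

# Downscale a stacked input matrix from side `from` to side `to` by block
# averaging (integer factors only).
resize_input_matrix <- function(X, from, to) {
  if (from == to) return(X)
  if (from %% to != 0L)
    abort("input side must be an integer multiple of the model input")
  f <- from %/% to
  cpp_avgpool_fwd(X, from, from, 3L, f, f)
}

# Stack a list of h x w x 3 pixel arrays into an input matrix, downscaling
# by block averaging when the patch side is an integer multiple of the
# model input side (bilinear resampling otherwise).
build_input_matrix <- function(pixels, input_size) {
  w <- dim(pixels[[1L]])[1L]
  M <- vapply(pixels, as.double, numeric(length(pixels[[1L]])))
  if (!is.matrix(M)) M <- matrix(M, ncol = length(pixels))
  if (w == input_size) return(M)
  if (w %% input_size == 0L) {
    f <- w %/% input_size
    return(cpp_avgpool_fwd(M, w, w, 3L, f, f))
  }
  M2 <- vapply(pixels, function(p) {
    as.double(EBImage::resize(p, w = input_size, h = input_size))
  }, numeric(input_size^2 * 3L))
  if (!is.matrix(M2)) M2 <- matrix(M2, ncol = length(pixels))
  M2
}
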