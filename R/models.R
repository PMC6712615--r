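# Layer-graph construction for the two classifier architectures:
#   * RefineNet -- the small six-convolution CNN that scores patch confidence
#     inside the reverse-active-learning loop;
#   * the atrous DenseNet (ADN) -- dense blocks whose layers pair a dilated
#     3x3 convolution (dilation 2 or 3) with a fusing 3x3 convolution,
#     growth rates 8/16/32, and a network-in-network (1x1 conv) head.
#
# A model graph is data, not code: a list of layer nodes with connectivity,
# over which channel and spatial-shape arithmetic is asserted before any
# training happens.

WEIGHTED_KINDS <- c("conv", "atrous_conv", "nin_conv1x1", "fully_connected")

new_layer_node <- function(id, kind, inputs, kernel = NA_integer_,
                           dilation = 1L, stride = 1L,
                           out_channels = NA_integer_) {
  kind <- match.arg(kind, c(WEIGHTED_KINDS, "max_pool", "avg_pool",
                            "global_avg_pool", "concat", "activation",
                            "batch_norm"))
  if (kind == "atrous_conv" && dilation < 2L)
    abort("atrous_conv requires dilation >= 2; use kind = 'conv' for dilation 1")
  if (kind == "conv" && dilation != 1L)
    abort("conv requires dilation = 1; use kind = 'atrous_conv'")
  list(id = id, kind = kind, inputs = as.integer(inputs),
       kernel = as.integer(kernel), dilation = as.integer(dilation),
       stride = as.integer(stride), out_channels = as.integer(out_channels))
}

graph_builder <- function() {
  gb <- new.env(parent = emptyenv())
  gb$nodes <- list()
  gb$last <- 0L  # id 0 is the network input
  gb
}

gb_add <- function(gb, kind, inputs = gb$last, ...) {
  id <- length(gb$nodes) + 1L
  gb$nodes[[id]] <- new_layer_node(id, kind, inputs, ...)
  gb$last <- id
  id
}

# conv (+ optional dilation) followed by batch norm and PReLU
gb_conv_block <- function(gb, out_channels, kernel = 3L, dilation = 1L,
                          kind = if (dilation > 1L) "atrous_conv" else "conv") {
  gb_add(gb, kind, kernel = kernel, dilation = dilation,
         out_channels = out_channels)
  gb_add(gb, "batch_norm")
  gb_add(gb, "activation")
  gb$last
}

new_model_graph <- function(nodes, input_size, n_classes, name = "model") {
  g <- structure(list(nodes = nodes, input_size = as.integer(input_size),
                      n_classes = as.integer(n_classes), name = name),
                 class = "model_graph")
  infer_shapes(g)
}

#' Spatial extent of a dilated kernel
#'
#' A k-by-k kernel with dilation rate `dilation` has `dilation - 1` holes
#' between taps, so it spans `kernel + (kernel - 1) * (dilation - 1)` pixels.
#' Dilation 1 is an ordinary convolution.
#'
#' @param kernel Kernel side length (>= 1).
#' @param dilation Dilation rate (>= 1).
#' @return Effective extent in pixels.
#' @examples
#' effective_kernel_extent(3, 1)  # 3
#' effective_kernel_extent(3, 2)  # 5
#' effective_kernel_extent(3, 3)  # 7
#' @export
effective_kernel_extent <- function(kernel, dilation) {
  stopifnot(kernel >= 1, dilation >= 1)
  kernel + (kernel - 1) * (dilation - 1)
}

#' Input channels of a densely connected layer
#'
#' In a dense block where every layer emits `growth_rate` feature maps and
#' receives the concatenation of the block input and all previous layer
#' outputs, layer `l` (1-based) sees `k0 + growth_rate * (l - 1)` channels.
#'
#' @param k0 Channels entering the block.
#' @param growth_rate Feature maps added per dense layer.
#' @param l Dense-layer index, starting at 1.
#' @return Channel count entering layer `l`.
#' @export
dense_input_channels <- function(k0, growth_rate, l) {
  stopifnot(l >= 1)
  k0 + growth_rate * (l - 1)
}

# ---- shape inference --------------------------------------------------------

# Walks the graph once, filling h/w/c in and out per node.  Errors carry the
# full shape trace so an incompatible input size is diagnosable.
infer_shapes <- function(graph) {
  nodes <- graph$nodes
  h <- integer(length(nodes) + 1L); w <- h; ch <- h
  h[1] <- graph$input_size[1]; w[1] <- graph$input_size[2]
  ch[1] <- graph$input_size[3]
  trace <- sprintf("input: %dx%dx%d", h[1], w[1], ch[1])
  fail <- function(node, msg) {
    abort(c(sprintf("shape inference failed at node %d (%s): %s",
                    node$id, node$kind, msg),
            stats::setNames(trace, rep("i", length(trace)))))
  }
  for (nd in nodes) {
    i <- nd$inputs + 1L
    hi <- h[i[1]]; wi <- w[i[1]]
    if (nd$kind == "concat") {
      if (any(h[i] != hi) || any(w[i] != wi))
        fail(nd, "concat inputs differ spatially")
      ci <- sum(ch[i])
    } else {
      if (length(i) != 1L) fail(nd, "multiple inputs on a non-concat node")
      ci <- ch[i]
    }
    out <- switch(nd$kind,
      conv = , atrous_conv = , nin_conv1x1 = {
        pad <- (nd$kernel - 1L) * nd$dilation / 2L
        if (pad != floor(pad)) fail(nd, "no symmetric 'same' padding exists")
        eff <- effective_kernel_extent(nd$kernel, nd$dilation)
        ho <- (hi + 2L * pad - eff) %/% nd$stride + 1L
        wo <- (wi + 2L * pad - eff) %/% nd$stride + 1L
        if (ho < 1L || wo < 1L) fail(nd, "kernel larger than padded input")
        list(h = ho, w = wo, c = nd$out_channels, pad = as.integer(pad))
      },
      max_pool = , avg_pool = {
        s <- nd$kernel
        if (hi %% s != 0L || wi %% s != 0L)
          fail(nd, sprintf("%dx%d not divisible by pool size %d", hi, wi, s))
        list(h = hi %/% s, w = wi %/% s, c = ci, pad = 0L)
      },
      global_avg_pool = list(h = 1L, w = 1L, c = ci, pad = 0L,
                             kernel_h = hi, kernel_w = wi),
      fully_connected = list(h = 1L, w = 1L, c = nd$out_channels, pad = 0L,
                             in_features = hi * wi * ci),
      concat = , activation = , batch_norm =
        list(h = hi, w = wi, c = ci, pad = 0L)
    )
    j <- nd$id + 1L
    h[j] <- out$h; w[j] <- out$w; ch[j] <- out$c
    nodes[[nd$id]]$h_in <- hi; nodes[[nd$id]]$w_in <- wi
    nodes[[nd$id]]$c_in <- ci
    nodes[[nd$id]]$h_out <- out$h; nodes[[nd$id]]$w_out <- out$w
    nodes[[nd$id]]$c_out <- ch[j]
    nodes[[nd$id]]$pad <- out$pad
    if (nd$kind == "global_avg_pool") {
      nodes[[nd$id]]$kernel_h <- out$kernel_h
      nodes[[nd$id]]$kernel_w <- out$kernel_w
    }
    if (nd$kind == "fully_connected")
      nodes[[nd$id]]$in_features <- out$in_features
    trace <- c(trace, sprintf("node %d %s -> %dx%dx%d", nd$id, nd$kind,
                              out$h, out$w, ch[j]))
  }
  graph$nodes <- nodes
  graph
}

layer_param_count <- function(node) {
  switch(node$kind,
    conv = , atrous_conv = , nin_conv1x1 =
      node$kernel^2 * node$c_in * node$out_channels + node$out_channels,
    fully_connected = node$in_features * node$out_channels + node$out_channels,
    batch_norm = 2L * node$c_in,
    activation = node$c_in,
    0L)
}

#' Count layers with trainable kernels
#'
#' Convolutions (ordinary, dilated and 1x1) and fully connected layers are
#' weighted; pooling, activation, normalisation and concatenation are not.
#'
#' @param graph A `model_graph`.
#' @return Integer count.
#' @export
count_weighted_layers <- function(graph) {
  stopifnot(inherits(graph, "model_graph"))
  sum(vapply(graph$nodes, function(n) n$kind %in% WEIGHTED_KINDS, logical(1)))
}

#' Tabulate a model graph layer by layer
#'
#' @param graph A `model_graph`.
#' @param skeleton If `TRUE`, drop batch-norm, activation and concatenation
#'   nodes so the table reads like a classical pipeline listing
#'   (convolutions, pools and fully connected stages only).
#' @return A tibble with one row per layer: kind, kernel, dilation,
#'   output channels, output spatial size and trainable-parameter count.
#' @export
describe_graph <- function(graph, skeleton = FALSE) {
  stopifnot(inherits(graph, "model_graph"))
  tb <- purrr::map_dfr(graph$nodes, function(n) tibble::tibble(
    id = n$id, kind = n$kind, kernel = n$kernel, dilation = n$dilation,
    out_channels = n$c_out, h_out = n$h_out, w_out = n$w_out,
    n_params = as.integer(layer_param_count(n))))
  if (skeleton)
    tb <- dplyr::filter(tb, !.data$kind %in%
                              c("batch_norm", "activation", "concat"))
  tb
}

#' @export
print.model_graph <- function(x, ...) {
  cat(sprintf("<model_graph '%s'> input %dx%dx%d, %d classes, %d weighted layers\n",
              x$name, x$input_size[1], x$input_size[2], x$input_size[3],
              x$n_classes, count_weighted_layers(x)))
  print(describe_graph(x, skeleton = TRUE), n = Inf)
  invisible(x)
}

# ---- RefineNet --------------------------------------------------------------

#' Build the RefineNet patch-confidence CNN
#'
#' A deliberately small network -- six 3x3 convolutions (16, 32, 64, 64,
#' 128, 128 channels), each of the first five followed by a 2x2 max pool,
#' then an average pool over the remaining spatial extent (7x7 at the
#' reference 224x224 input) and two fully connected layers (256, then the
#' class scores).  Its low capacity is the point: it underfits mislabeled
#' patches, so their softmax confidence stays low and they can be flagged.
#' Each weighted layer except the output is followed by batch
#' normalisation and PReLU.
#'
#' @param n_classes Number of output classes.
#' @param input_size Square input side in pixels; must be divisible by 32
#'   (five 2x2 pools).
#' @return A `model_graph`.
#' @export
build_refinenet <- function(n_classes = 4L, input_size = 224L) {
  gb <- graph_builder()
  widths <- c(16L, 32L, 64L, 64L, 128L, 128L)
  for (i in seq_along(widths)) {
    gb_conv_block(gb, widths[i])
    if (i < 6L) gb_add(gb, "max_pool", kernel = 2L, stride = 2L)
  }
  # the trailing average pool always covers the full remaining extent
  # (7x7 for the 224 reference); sizes that do not survive the five
  # halvings fail shape inference with a trace.
  ap <- input_size %/% 32L
  if (input_size %% 32L != 0L || ap < 1L) {
    # still build so the error carries the shape trace
    ap <- 7L
  }
  gb_add(gb, "avg_pool", kernel = ap, stride = ap)
  gb_add(gb, "fully_connected", out_channels = 256L)
  gb_add(gb, "batch_norm")
  gb_add(gb, "activation")
  gb_add(gb, "fully_connected", out_channels = as.integer(n_classes))
  new_model_graph(gb$nodes, c(input_size, input_size, 3L), n_classes,
                  name = "refinenet")
}

# ---- atrous DenseNet --------------------------------------------------------

#' Configuration of one atrous dense connection (ADC) block
#'
#' Each dense layer is a dilated 3x3 convolution (dilation alternating over
#' `dilations`, default 2, 3, 2, 3, ...) followed by an ordinary 3x3
#' convolution that fuses the multiscale features; both emit `growth_rate`
#' channels, and the fused output is concatenated onto the running feature
#' stack, so layer `l` receives `input_channels + growth_rate * (l - 1)`
#' channels.
#'
#' @param n_dense_layers Dense layers in the block.
#' @param growth_rate Feature maps added per dense layer (k).
#' @param dilations Dilation rates cycled across dense layers; values must
#'   be 2 or 3.
#' @param input_channels Channels entering the block (k0).
#' @return An `adc_config` list.
#' @export
adc_config <- function(n_dense_layers = 4L, growth_rate = 8L,
                       dilations = c(2L, 3L), input_channels = 16L) {
  if (length(dilations) == 0 || !all(dilations %in% c(2L, 3L)))
    abort("dilations must be a non-empty subset of {2, 3}")
  if (growth_rate <= 0) abort("growth_rate must be positive")
  structure(list(n_dense_layers = as.integer(n_dense_layers),
                 growth_rate = as.integer(growth_rate),
                 dilations = as.integer(dilations),
                 input_channels = as.integer(input_channels)),
            class = "adc_config")
}

# Append one ADC block to a builder whose current output has k0 channels.
gb_adc <- function(gb, config) {
  stack <- gb$last  # running concatenation input
  members <- stack
  for (l in seq_len(config$n_dense_layers)) {
    xin <- if (length(members) > 1L) gb_add(gb, "concat", inputs = members)
           else members
    dil <- config$dilations[(l - 1L) %% length(config$dilations) + 1L]
    gb$last <- xin
    gb_conv_block(gb, config$growth_rate, kernel = 3L, dilation = dil)
    gb_conv_block(gb, config$growth_rate, kernel = 3L)  # fusing conv
    members <- c(members, gb$last)
  }
  gb_add(gb, "concat", inputs = members)
}

#' Build a standalone ADC block graph
#'
#' Mostly useful for structural checks; [build_adn()] assembles the full
#' network.
#'
#' @param config An [adc_config()].
#' @param input_size Spatial side of the block input.
#' @return A `model_graph` whose input has `config$input_channels` channels
#'   and whose output carries `input_channels + n_dense_layers * growth_rate`
#'   channels.
#' @export
build_adc_module <- function(config, input_size = 32L) {
  stopifnot(inherits(config, "adc_config"))
  gb <- graph_builder()
  gb_adc(gb, config)
  new_model_graph(gb$nodes,
                  c(input_size, input_size, config$input_channels),
                  n_classes = NA_integer_, name = "adc_block")
}

#' Configuration of the atrous DenseNet
#'
#' The reference configuration has a 3x3 stem convolution, three ADC blocks
#' of four dense layers with growth rates 8, 16 and 32 (average-pool
#' transitions between blocks), a network-in-network head of two 1x1
#' convolutions, global average pooling and one fully connected output:
#' 1 + 3*4*2 + 2 + 1 = 28 weighted layers.
#'
#' @param n_classes Output classes.
#' @param input_size Square input side in pixels (divisible by 8: one max
#'   pool and two transition pools).
#' @param stem_channels Channels of the stem convolution.
#' @param growth_rates Growth rate per ADC block; must be strictly
#'   increasing.
#' @param layers_per_module Dense layers in each ADC block.
#' @param dilations Dilation cycle inside every block.
#' @param nin_channels Widths of the two 1x1 convolutions in the head.
#' @return An `adn_config` list.
#' @export
adn_config <- function(n_classes = 4L, input_size = 64L,
                       stem_channels = 16L, growth_rates = c(8L, 16L, 32L),
                       layers_per_module = 4L, dilations = c(2L, 3L),
                       nin_channels = c(128L, 64L)) {
  if (any(diff(growth_rates) <= 0))
    abort("growth_rates must be strictly increasing across ADC modules")
  if (length(dilations) == 0 || !all(dilations %in% c(2L, 3L)))
    abort("dilations must be a non-empty subset of {2, 3}")
  structure(list(n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 stem_channels = as.integer(stem_channels),
                 growth_rates = as.integer(growth_rates),
                 layers_per_module = as.integer(layers_per_module),
                 dilations = as.integer(dilations),
                 nin_channels = as.integer(nin_channels)),
            class = "adn_config")
}

#' Build the atrous DenseNet (ADN)
#'
#' Stem convolution and 2x2 max pool, `length(growth_rates)` ADC blocks
#' separated by 2x2 average-pool transitions, a network-in-network head of
#' 1x1 convolutions, global average pooling, and a fully connected softmax
#' head.  Every weighted layer except the output is followed by batch
#' normalisation and PReLU.  Transitions carry no convolution so that the
#' reference configuration has exactly 28 weighted layers.
#'
#' @param config An [adn_config()].
#' @param strict_reference If `TRUE`, reject any configuration whose
#'   weighted-layer count differs from the reference 28.
#' @return A `model_graph`.
#' @export
build_adn <- function(config = adn_config(), strict_reference = FALSE) {
  stopifnot(inherits(config, "adn_config"))
  gb <- graph_builder()
  gb_conv_block(gb, config$stem_channels)          # stem
  gb_add(gb, "max_pool", kernel = 2L, stride = 2L)
  k0 <- config$stem_channels
  for (m in seq_along(config$growth_rates)) {
    if (m > 1L) gb_add(gb, "avg_pool", kernel = 2L, stride = 2L)
    cfg <- adc_config(config$layers_per_module, config$growth_rates[m],
                      config$dilations, k0)
    gb_adc(gb, cfg)
    k0 <- k0 + config$layers_per_module * config$growth_rates[m]
  }
  for (w in config$nin_channels) {
    gb_add(gb, "nin_conv1x1", kernel = 1L, out_channels = as.integer(w))
    gb_add(gb, "batch_norm")
    gb_add(gb, "activation")
  }
  gb_add(gb, "global_avg_pool")
  gb_add(gb, "fully_connected", out_channels = config$n_classes)
  g <- new_model_graph(gb$nodes,
                       c(config$input_size, config$input_size, 3L),
                       config$n_classes, name = "adn")
  if (strict_reference && count_weighted_layers(g) != 28L)
    abort(sprintf("reference ADN must have 28 weighted layers, got %d",
                  count_weighted_layers(g)))
  g
}
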