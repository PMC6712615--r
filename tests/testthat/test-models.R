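# Architecture graphs: kernel-extent and dense-channel arithmetic, the
# RefineNet pipeline table, ADC/ADN structure, weighted-layer counts.

test_that("dilated kernel extents follow kernel + (kernel-1)(dilation-1)", {
  expect_equal(effective_kernel_extent(3, 1), 3)
  expect_equal(effective_kernel_extent(3, 2), 5)
  expect_equal(effective_kernel_extent(3, 3), 7)
  expect_equal(effective_kernel_extent(1, 5), 1)
})

test_that("dense-layer input channels follow k0 + k(l-1)", {
  expect_equal(dense_input_channels(7, 8, 1), 7)
  expect_equal(dense_input_channels(16, 8, 4), 40)
})

test_that("RefineNet matches its reference pipeline stage by stage", {
  g <- build_refinenet(4L, 224L)
  sk <- describe_graph(g, skeleton = TRUE)
  expect_equal(sk$kind,
               c(rep(c("conv", "max_pool"), 5), "conv", "avg_pool",
                 "fully_connected", "fully_connected"))
  expect_equal(sk$kernel[sk$kind == "conv"], rep(3L, 6))
  expect_equal(sk$out_channels[sk$kind == "conv"],
               c(16L, 32L, 64L, 64L, 128L, 128L))
  expect_equal(sk$kernel[sk$kind == "avg_pool"], 7L)
  expect_equal(sk$out_channels[sk$kind == "fully_connected"], c(256L, 4L))
  expect_equal(nrow(sk), 14L)
  expect_equal(sum(sk$kind == "conv"), 6L)
  expect_equal(count_weighted_layers(g), 8L)
})

test_that("shape inference rejects inputs that cannot survive the pooling chain", {
  expect_error(build_refinenet(4L, 223L), "shape inference failed")
  # the error carries a trace of the shapes computed so far
  err <- tryCatch(build_refinenet(4L, 223L), error = identity)
  trace <- c(conditionMessage(err), as.character(err$body))
  expect_match(paste(trace, collapse = " "), "input: 223x223x3")
})

test_that("ADC blocks concatenate to k0 + l*k channels with alternating dilation", {
  cfg <- adc_config(n_dense_layers = 4L, growth_rate = 8L,
                    dilations = c(2L, 3L), input_channels = 16L)
  g <- build_adc_module(cfg, input_size = 32L)
  last <- g$nodes[[length(g$nodes)]]
  expect_equal(last$kind, "concat")
  expect_equal(last$c_out, 16L + 4L * 8L)
  at <- purrr::keep(g$nodes, ~.x$kind == "atrous_conv")
  expect_equal(purrr::map_int(at, "dilation"), c(2L, 3L, 2L, 3L))
  # every atrous conv is followed (after bn + activation) by a plain 3x3
  fuse <- purrr::keep(g$nodes, ~.x$kind == "conv")
  expect_length(fuse, 4L)
  expect_true(all(purrr::map_int(fuse, "dilation") == 1L))
  expect_error(adc_config(dilations = c(2L, 4L)), "subset")
})

test_that("dilation changes the receptive field but never the parameter count", {
  mk <- function(dil) {
    gb <- dralnet:::graph_builder()
    dralnet:::gb_add(gb, if (dil > 1) "atrous_conv" else "conv",
                     kernel = 3L, dilation = dil, out_channels = 8L)
    dralnet:::new_model_graph(gb$nodes, c(16L, 16L, 4L), 2L)
  }
  counts <- purrr::map_int(1:3, function(d)
    describe_graph(mk(d))$n_params[1])
  expect_equal(counts, rep(3L * 3L * 4L * 8L + 8L, 3))
})

test_that("the reference atrous DenseNet has 28 weighted layers and growth 8/16/32", {
  g <- build_adn(adn_config(), strict_reference = TRUE)
  expect_equal(count_weighted_layers(g), 28L)
  # growth rates read off the built blocks: the atrous convs of the three
  # blocks emit 8, 16 and 32 channels
  at <- purrr::keep(g$nodes, ~.x$kind == "atrous_conv")
  expect_equal(unique(purrr::map_int(at, "out_channels")), c(8L, 16L, 32L))
  expect_equal(sum(purrr::map_int(at, "out_channels") == 8L), 4L)
  # a non-reference configuration is rejected under strict_reference
  expect_error(build_adn(adn_config(layers_per_module = 3L),
                         strict_reference = TRUE), "28")
  expect_error(adn_config(growth_rates = c(8L, 8L, 32L)), "increasing")
})

test_that("every dense-layer input obeys the concatenation channel formula", {
  g <- build_adn(adn_config(), strict_reference = TRUE)
  k0s <- c(16L, 48L, 112L); ks <- c(8L, 16L, 32L)
  at <- purrr::keep(g$nodes, ~.x$kind == "atrous_conv")
  module <- rep(1:3, each = 4)
  layer <- rep(1:4, times = 3)
  for (i in seq_along(at))
    expect_equal(at[[i]]$c_in,
                 dense_input_channels(k0s[module[i]], ks[module[i]],
                                      layer[i]))
})

test_that("forward shapes are consistent and end at n_classes", {
  for (cfg in list(adn_config(n_classes = 3L, input_size = 32L),
                   adn_config(n_classes = 5L, input_size = 64L,
                              layers_per_module = 2L))) {
    g <- build_adn(cfg)
    out <- g$nodes[[length(g$nodes)]]
    expect_equal(out$c_out, cfg$n_classes)
    expect_equal(c(out$h_out, out$w_out), c(1L, 1L))
  }
  g <- build_refinenet(4L, 64L)
  out <- g$nodes[[length(g$nodes)]]
  expect_equal(out$c_out, 4L)
})
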