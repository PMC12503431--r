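test_that("every architecture builds and emits finite binary logits", {
  set.seed(5)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  params <- c(baseline_cnn = NA, resnet50 = NA, mobilenet_v2 = NA,
              ghostnet = NA)
  for (name in names(params)) {
    m <- build_classifier(arch_spec(name, input_size = c(64, 64)), seed = 1)
    out <- endoscreen:::nn_forward(m$graph, x)$out
    expect_equal(dim(out), c(2L, 2L))
    expect_true(all(is.finite(out)))
    params[name] <- m$n_params
  }
  # the ghost-module network is far lighter than the residual one
  expect_lt(params["ghostnet"], params["resnet50"])
  expect_lt(params["mobilenet_v2"], params["resnet50"])
})

test_that("the baseline CNN has exactly six convolutional layers", {
  m <- build_classifier(arch_spec("baseline_cnn", input_size = c(64, 64)),
                        seed = 1)
  ops <- vapply(m$graph$nodes, function(n) n$op, character(1))
  expect_equal(sum(ops == "conv"), 6L)
  expect_equal(sum(ops == "maxpool2"), 3L) # pool after every second block
  expect_equal(sum(ops == "dropout"), 2L)  # on the last two blocks
})

test_that("ghost module bookkeeping conserves channels", {
  gm <- ghost_module(16, 64, ratio = 2)
  expect_equal(gm$intrinsic_channels, 32L)
  expect_equal(gm$ghost_channels, 32L)
  expect_equal(gm$intrinsic_channels + gm$ghost_channels, gm$out_channels)
  # ratio 1 degenerates to a plain convolution: no ghost maps
  gm1 <- ghost_module(16, 64, ratio = 1)
  expect_equal(gm1$ghost_channels, 0L)
  expect_equal(ghost_module_macs(gm1, c(32, 32))$total,
               ghost_module_macs(gm1, c(32, 32))$dense_equivalent)
  expect_error(ghost_module(16, 63, ratio = 2), "divisible")
  # channel conservation across a range of widths and ratios
  for (s in 2:4) for (out in c(24, 48, 96)) {
    if (out %% s != 0) next
    gmx <- ghost_module(32, out, ratio = s)
    expect_equal(gmx$intrinsic_channels + gmx$ghost_channels, as.integer(out))
  }
})

test_that("a ghost module is analytically cheaper than its dense equivalent", {
  # concrete layer: 1x1 conv 128 -> 128 over a 28x28 map, ratio 2
  gm <- ghost_module(128, 128, ratio = 2)
  mc <- ghost_module_macs(gm, c(28, 28))
  expect_equal(mc$primary, 128 * 64 * 28 * 28)            # dense part
  expect_equal(mc$cheap, 64 * 9 * 28 * 28)                # depthwise part
  expect_equal(mc$total, mc$primary + mc$cheap)
  # <= (1/s + small depthwise term) x dense cost
  s <- 2
  bound <- (1 / s + 9 / 128) * mc$dense_equivalent
  expect_lte(mc$total, bound + 1e-9)
  expect_lt(mc$total, mc$dense_equivalent)
})

test_that("ghost modules inside the network concatenate to the stated width", {
  m <- build_classifier(arch_spec("ghostnet", input_size = c(64, 64)),
                        seed = 1)
  cats <- Filter(function(n) n$op == "concat", m$graph$nodes)
  expect_gt(length(cats), 10)
  for (n in cats) {
    sh <- m$graph$shapes[[n$id]]
    expect_equal(sh[3], n$hyper$c1 + n$hyper$c2)
  }
})

test_that("unknown architecture names are rejected", {
  expect_error(arch_spec("vit_base"), "arg")
  expect_error(arch_spec("ghostnet", input_size = c(50, 50)), "divisible")
})
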