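## Classifier architectures: a six-layer baseline CNN, ResNet50,
## MobileNetV2 and GhostNet, all emitted as graphs for the engine in
## nn_engine.R. The same graph definitions drive both the forward pass and
## the analytic FLOP profiler, so the cost that is reported is the cost that
## runs.

ARCH_NAMES <- c("baseline_cnn", "resnet50", "mobilenet_v2", "ghostnet")

#' Architecture specification for a frame classifier
#'
#' @param name one of `"baseline_cnn"`, `"resnet50"`, `"mobilenet_v2"`,
#'   `"ghostnet"`.
#' @param input_size integer `c(H, W)`; 224x224 matches the profiling
#'   convention, smaller sizes (divisible by 32) are used for desk-scale
#'   training.
#' @param n_classes number of output classes (2 for good/poor or
#'   referral/non-referral).
#' @param width_multiplier channel-width scale for `ghostnet`,
#'   `mobilenet_v2` and `baseline_cnn` (reduced widths for CPU training).
#' @param ghost_ratio ghost-module ratio `s >= 1` (GhostNet only); each block
#'   emits `out/s` intrinsic maps by dense convolution and the rest by cheap
#'   depthwise operations.
#' @param dropout_rate dropout on the last two convolution blocks of the
#'   baseline CNN.
#' @return an object of class `arch_spec`.
#' @export
arch_spec <- function(name, input_size = c(224, 224), n_classes = 2,
                      width_multiplier = 1, ghost_ratio = 2,
                      dropout_rate = 0.5) {
  name <- match.arg(name, ARCH_NAMES)
  input_size <- as.integer(rep(input_size, length.out = 2))
  if (n_classes < 2) stop("n_classes must be >= 2")
  div <- if (name == "baseline_cnn") 8L else 32L
  if (any(input_size %% div != 0))
    stop("input_size must be divisible by ", div, " for ", name)
  if (ghost_ratio < 1) stop("ghost_ratio must be >= 1")
  structure(list(name = name, input_size = input_size,
                 n_classes = as.integer(n_classes),
                 width_multiplier = width_multiplier,
                 ghost_ratio = as.integer(ghost_ratio),
                 dropout_rate = dropout_rate),
            class = "arch_spec")
}

#' @export
print.arch_spec <- function(x, ...) {
  cat(sprintf("<arch_spec> %s  input %dx%d  classes %d  width x%.2f\n",
              x$name, x$input_size[1], x$input_size[2], x$n_classes,
              x$width_multiplier))
  invisible(x)
}

## Round a scaled channel count to a multiple of `divisor`, never shrinking
## by more than 10% (the convention used by the mobile architectures).
make_divisible <- function(v, divisor = 4L) {
  new_v <- max(divisor, as.integer(v + divisor / 2) %/% divisor * divisor)
  if (new_v < 0.9 * v) new_v <- new_v + divisor
  as.integer(new_v)
}

## ---- ghost module ----------------------------------------------------------

#' Ghost module layer contract
#'
#' A ghost module replaces a dense convolution producing `out_channels` maps
#' with (1) a primary convolution that produces only `m = out_channels /
#' ratio` intrinsic maps and (2) a cheap depthwise operation that derives the
#' remaining `(ratio - 1) * m` "ghost" maps from the intrinsic ones; the two
#' sets are concatenated. `ratio = 1` degenerates to a plain convolution.
#'
#' @param in_channels,out_channels channel widths; `out_channels` must be
#'   divisible by `ratio`.
#' @param ratio integer `s >= 1`.
#' @param primary_kernel,cheap_kernel kernel sizes of the primary convolution
#'   and of the depthwise cheap operation.
#' @return object of class `ghost_module` with the channel bookkeeping; use
#'   [ghost_module_macs()] for its analytic multiply-accumulate count.
#' @export
ghost_module <- function(in_channels, out_channels, ratio = 2,
                         primary_kernel = 1, cheap_kernel = 3) {
  if (ratio < 1) stop("ratio must be >= 1")
  if (out_channels %% ratio != 0)
    stop("out_channels must be divisible by ratio")
  m <- as.integer(out_channels / ratio)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 ratio = as.integer(ratio),
                 intrinsic_channels = m,
                 ghost_channels = as.integer(out_channels - m),
                 primary_kernel = as.integer(primary_kernel),
                 cheap_kernel = as.integer(cheap_kernel)),
            class = "ghost_module")
}

#' @export
print.ghost_module <- function(x, ...) {
  cat(sprintf(
    "<ghost_module> %d -> %d (ratio %d: %d intrinsic + %d ghost maps)\n",
    x$in_channels, x$out_channels, x$ratio, x$intrinsic_channels,
    x$ghost_channels))
  invisible(x)
}

#' Multiply-accumulate count of a ghost module at a given output size
#'
#' @param mod a [ghost_module()].
#' @param out_hw integer `c(H, W)` of the output feature map.
#' @return list with `primary`, `cheap` and `total` MAC counts, plus
#'   `dense_equivalent`, the cost of the plain convolution it replaces
#'   (same `in -> out` width, kernel = `primary_kernel`).
#' @export
ghost_module_macs <- function(mod, out_hw) {
  hw <- prod(as.integer(rep(out_hw, length.out = 2)))
  primary <- mod$in_channels * mod$intrinsic_channels *
    mod$primary_kernel^2 * hw
  cheap <- mod$ghost_channels * mod$cheap_kernel^2 * hw
  dense <- mod$in_channels * mod$out_channels * mod$primary_kernel^2 * hw
  list(primary = primary, cheap = cheap, total = primary + cheap,
       dense_equivalent = dense)
}

## Emit a ghost module into a graph: primary conv-BN(-ReLU) producing the
## intrinsic maps, depthwise cheap op-BN(-ReLU) producing the ghosts, concat.
ng_ghost <- function(g, input, out_channels, ratio = 2, relu = TRUE,
                     primary_kernel = 1, cheap_kernel = 3) {
  cin <- ng_shape(g, input)[3]
  mod <- ghost_module(cin, out_channels, ratio, primary_kernel, cheap_kernel)
  prim <- ng_conv(g, input, mod$intrinsic_channels, primary_kernel)
  prim <- ng_bn(g, prim)
  if (relu) prim <- ng_act(g, prim, "relu")
  if (mod$ratio == 1L) return(prim)
  ## depthwise with channel multiplier (ratio - 1): grouped conv where each
  ## intrinsic map spawns (ratio - 1) ghosts
  cheap <- ng_conv(g, prim, mod$ghost_channels, cheap_kernel,
                   groups = mod$intrinsic_channels)
  cheap <- ng_bn(g, cheap)
  if (relu) cheap <- ng_act(g, cheap, "relu")
  ng_concat(g, prim, cheap)
}

## Squeeze-and-excite gate (reduction 4, hard-sigmoid), as used by GhostNet.
ng_se <- function(g, input, reduction = 4) {
  cc <- ng_shape(g, input)[3]
  hidden <- make_divisible(cc / reduction, 4L)
  s <- ng_gap(g, input)
  s <- ng_linear(g, s, hidden)
  s <- ng_act(g, s, "relu")
  s <- ng_linear(g, s, cc)
  s <- ng_act(g, s, "hardsigmoid")
  ng_sescale(g, input, s)
}

## ---- architecture graphs ---------------------------------------------------

build_baseline_cnn <- function(g, spec) {
  w <- spec$width_multiplier
  ch <- pmax(4L, as.integer(round(c(32, 32, 64, 64, 128, 128) * w)))
  x <- "input"
  for (i in seq_along(ch)) {
    x <- ng_conv(g, x, ch[i], 3)
    x <- ng_bn(g, x)
    x <- ng_act(g, x, "relu")
    if (i >= 5 && spec$dropout_rate > 0)
      x <- ng_dropout(g, x, spec$dropout_rate)
    if (i %% 2 == 0) x <- ng_maxpool2(g, x)
  }
  x <- ng_gap(g, x)
  ng_linear(g, x, spec$n_classes)
}

resnet_bottleneck <- function(g, x, mid, out, stride) {
  cin <- ng_shape(g, x)[3]
  y <- ng_conv(g, x, mid, 1)
  y <- ng_bn(g, y); y <- ng_act(g, y, "relu")
  y <- ng_conv(g, y, mid, 3, stride = stride)
  y <- ng_bn(g, y); y <- ng_act(g, y, "relu")
  y <- ng_conv(g, y, out, 1)
  y <- ng_bn(g, y)
  sc <- x
  if (cin != out || stride != 1) {
    sc <- ng_conv(g, x, out, 1, stride = stride)
    sc <- ng_bn(g, sc)
  }
  ng_act(g, ng_add2(g, y, sc), "relu")
}

build_resnet50 <- function(g, spec) {
  x <- ng_conv(g, "input", 64, 7, stride = 2)
  x <- ng_bn(g, x); x <- ng_act(g, x, "relu")
  x <- ng_maxpool2(g, x)
  blocks <- c(3, 4, 6, 3)
  mids <- c(64, 128, 256, 512)
  for (stage in 1:4) {
    for (b in seq_len(blocks[stage])) {
      stride <- if (b == 1 && stage > 1) 2 else 1
      x <- resnet_bottleneck(g, x, mids[stage], mids[stage] * 4, stride)
    }
  }
  x <- ng_gap(g, x)
  ng_linear(g, x, spec$n_classes)
}

mbv2_block <- function(g, x, t, out, stride) {
  cin <- ng_shape(g, x)[3]
  hidden <- cin * t
  y <- x
  if (t != 1) {
    y <- ng_conv(g, y, hidden, 1)
    y <- ng_bn(g, y); y <- ng_act(g, y, "relu6")
  }
  y <- ng_conv(g, y, hidden, 3, stride = stride, groups = hidden)
  y <- ng_bn(g, y); y <- ng_act(g, y, "relu6")
  y <- ng_conv(g, y, out, 1)
  y <- ng_bn(g, y)
  if (stride == 1 && cin == out) y <- ng_add2(g, y, x) else y
}

build_mobilenet_v2 <- function(g, spec) {
  w <- spec$width_multiplier
  cfg <- list( # (expansion t, channels c, repeats n, first stride s)
    c(1, 16, 1, 1), c(6, 24, 2, 2), c(6, 32, 3, 2), c(6, 64, 4, 2),
    c(6, 96, 3, 1), c(6, 160, 3, 2), c(6, 320, 1, 1))
  stem <- make_divisible(32 * w, 8L)
  x <- ng_conv(g, "input", stem, 3, stride = 2)
  x <- ng_bn(g, x); x <- ng_act(g, x, "relu6")
  for (row in cfg) {
    out <- make_divisible(row[2] * w, 8L)
    for (b in seq_len(row[3])) {
      stride <- if (b == 1) row[4] else 1
      x <- mbv2_block(g, x, row[1], out, stride)
    }
  }
  head <- if (w > 1) make_divisible(1280 * w, 8L) else 1280L
  x <- ng_conv(g, x, head, 1)
  x <- ng_bn(g, x); x <- ng_act(g, x, "relu6")
  x <- ng_gap(g, x)
  ng_linear(g, x, spec$n_classes)
}

ghost_bottleneck <- function(g, x, k, exp_ch, out, use_se, stride, ratio) {
  cin <- ng_shape(g, x)[3]
  y <- ng_ghost(g, x, exp_ch, ratio = ratio, relu = TRUE)
  if (stride == 2) {
    y <- ng_conv(g, y, exp_ch, k, stride = 2, groups = exp_ch)
    y <- ng_bn(g, y)
  }
  if (use_se) y <- ng_se(g, y)
  y <- ng_ghost(g, y, out, ratio = ratio, relu = FALSE)
  if (stride == 1 && cin == out) return(ng_add2(g, y, x))
  sc <- ng_conv(g, x, cin, k, stride = stride, groups = cin)
  sc <- ng_bn(g, sc)
  sc <- ng_conv(g, sc, out, 1)
  sc <- ng_bn(g, sc)
  ng_add2(g, y, sc)
}

build_ghostnet <- function(g, spec) {
  w <- spec$width_multiplier
  ratio <- spec$ghost_ratio
  cfg <- list( # (kernel k, expansion width, output width, SE flag, stride)
    c(3, 16, 16, 0, 1),
    c(3, 48, 24, 0, 2),
    c(3, 72, 24, 0, 1),
    c(5, 72, 40, 1, 2),
    c(5, 120, 40, 1, 1),
    c(3, 240, 80, 0, 2),
    c(3, 200, 80, 0, 1),
    c(3, 184, 80, 0, 1),
    c(3, 184, 80, 0, 1),
    c(3, 480, 112, 1, 1),
    c(3, 672, 112, 1, 1),
    c(5, 672, 160, 1, 2),
    c(5, 960, 160, 0, 1),
    c(5, 960, 160, 1, 1),
    c(5, 960, 160, 0, 1),
    c(5, 960, 160, 1, 1))
  stem <- make_divisible(16 * w, 4L)
  x <- ng_conv(g, "input", stem, 3, stride = 2)
  x <- ng_bn(g, x); x <- ng_act(g, x, "relu")
  for (row in cfg) {
    exp_ch <- make_divisible(row[2] * w, 4L)
    out <- make_divisible(row[3] * w, 4L)
    ## keep widths divisible by the ghost ratio
    exp_ch <- as.integer(ceiling(exp_ch / ratio) * ratio)
    out <- as.integer(ceiling(out / ratio) * ratio)
    x <- ghost_bottleneck(g, x, row[1], exp_ch, out, row[4] == 1, row[5],
                          ratio)
  }
  last <- make_divisible(960 * w, 4L)
  x <- ng_conv(g, x, last, 1)
  x <- ng_bn(g, x); x <- ng_act(g, x, "relu")
  x <- ng_gap(g, x)
  x <- ng_linear(g, x, 1280L)
  x <- ng_act(g, x, "relu")
  ng_linear(g, x, spec$n_classes)
}

## Build the graph for a spec; init_params = FALSE gives a shape-only graph
## for profiling.
arch_graph <- function(spec, init_params = TRUE) {
  g <- ng_new(c(spec$input_size, 3L), init_params = init_params)
  switch(spec$name,
         baseline_cnn = build_baseline_cnn(g, spec),
         resnet50 = build_resnet50(g, spec),
         mobilenet_v2 = build_mobilenet_v2(g, spec),
         ghostnet = build_ghostnet(g, spec))
  g
}

#' Build a frame classifier
#'
#' Instantiates the architecture named in `spec` with randomly initialised
#' weights (He initialisation).
#'
#' @param spec an [arch_spec()].
#' @param seed optional integer seed for the weight initialisation.
#' @return object of class `endo_classifier` holding the network graph; train
#'   it with [train_iqm()] or [train_dcm()].
#' @export
build_classifier <- function(spec, seed = NULL) {
  if (!inherits(spec, "arch_spec")) stop("spec must be an arch_spec")
  if (!is.null(seed)) set.seed(seed)
  g <- arch_graph(spec, init_params = TRUE)
  structure(list(spec = spec, graph = g, trained = FALSE,
                 n_params = nn_count_params(g)),
            class = "endo_classifier")
}

#' @export
print.endo_classifier <- function(x, ...) {
  cat(sprintf("<endo_classifier> %s  input %dx%d  %s parameters  %s\n",
              x$spec$name, x$spec$input_size[1], x$spec$input_size[2],
              format(x$n_params, big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Forward a batch of frames through a classifier
#'
#' @param object an `endo_classifier`.
#' @param x array `(H, W, 3, N)` of frames in `[0, 1]`.
#' @param ... unused.
#' @return `(n_classes, N)` matrix of softmax probabilities.
#' @export
predict.endo_classifier <- function(object, x, ...) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[4]
  out <- NULL
  ## chunked so that resizing/normalising never duplicates the full input
  for (start in seq(1, n, by = 256)) {
    take <- start:min(start + 255, n)
    xb <- resize_batch(x[, , , take, drop = FALSE], object$spec$input_size)
    if (isTRUE(object$normalize)) xb <- normalize_frames(xb)
    p <- nn_predict_proba(object$graph, xb)
    out <- if (is.null(out)) p else cbind(out, p)
  }
  out
}
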