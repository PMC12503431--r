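## Compact CPU network engine.
##
## Tensors are plain R arrays in (H, W, C, N) layout; vector features (after
## global pooling) are (F, N) matrices. A network is an ordered list of nodes,
## each holding its operation, input node ids, hyperparameters, parameter
## arrays and inferred output shape. Convolution and max pooling run through
## the compiled im2col kernels in src/; everything else is vectorised R.

#' Start a network graph
#'
#' @param input_shape integer vector `c(H, W, C)` of the expected input.
#' @param init_params if `FALSE`, only shapes are inferred (no parameter
#'   arrays are allocated); used by the FLOP profiler.
#' @return a builder environment; pass to the `ng_*` layer helpers.
#' @keywords internal
ng_new <- function(input_shape, init_params = TRUE) {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g$shapes <- list(input = as.integer(input_shape))
  g$init_params <- isTRUE(init_params)
  g$counter <- 0L
  g
}

ng_uid <- function(g, prefix) {
  g$counter <- g$counter + 1L
  sprintf("%s_%03d", prefix, g$counter)
}

ng_shape <- function(g, id) {
  s <- g$shapes[[id]]
  if (is.null(s)) stop("unknown node id: ", id)
  s
}

ng_put <- function(g, id, op, inputs, hyper = list(), par = NULL, out_shape) {
  if (!is.null(g$nodes[[id]])) stop("duplicate node id: ", id)
  g$nodes[[id]] <- list(id = id, op = op, inputs = inputs, hyper = hyper,
                        par = par)
  g$shapes[[id]] <- as.integer(out_shape)
  id
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

#' @keywords internal
ng_conv <- function(g, input, cout, k, stride = 1L, groups = 1L,
                    bias = FALSE, pad = NULL, id = NULL) {
  s <- ng_shape(g, input)
  if (length(s) != 3) stop("conv expects a (H, W, C) input")
  cin <- s[3]
  if (cin %% groups != 0 || cout %% groups != 0)
    stop("channels not divisible by groups")
  if (is.null(pad)) pad <- k %/% 2L
  ho <- (s[1] + 2L * pad - k) %/% stride + 1L
  wo <- (s[2] + 2L * pad - k) %/% stride + 1L
  if (ho < 1L || wo < 1L) stop("conv output would be empty")
  par <- NULL
  if (g$init_params) {
    par <- list(W = he_init(c(k, k, cin %/% groups, cout),
                            k * k * (cin %/% groups)))
    if (bias) par$b <- numeric(cout)
  }
  if (is.null(id)) id <- ng_uid(g, "conv")
  ng_put(g, id, "conv", input,
         hyper = list(k = as.integer(k), stride = as.integer(stride),
                      pad = as.integer(pad), groups = as.integer(groups),
                      bias = bias, cin = cin, cout = as.integer(cout)),
         par = par, out_shape = c(ho, wo, cout))
}

#' @keywords internal
ng_bn <- function(g, input, id = NULL) {
  s <- ng_shape(g, input)
  cc <- s[length(s)]
  par <- NULL
  if (g$init_params)
    par <- list(gamma = rep(1, cc), beta = numeric(cc),
                rmean = numeric(cc), rvar = rep(1, cc))
  if (is.null(id)) id <- ng_uid(g, "bn")
  ng_put(g, id, "bn", input, hyper = list(channels = cc, eps = 1e-5,
                                          momentum = 0.1),
         par = par, out_shape = s)
}

#' @keywords internal
ng_act <- function(g, input, type = "relu", id = NULL) {
  if (is.null(id)) id <- ng_uid(g, type)
  ng_put(g, id, "act", input, hyper = list(type = type),
         out_shape = ng_shape(g, input))
}

#' @keywords internal
ng_maxpool2 <- function(g, input, id = NULL) {
  s <- ng_shape(g, input)
  if (s[1] %% 2 != 0 || s[2] %% 2 != 0) stop("maxpool needs even H and W")
  if (is.null(id)) id <- ng_uid(g, "pool")
  ng_put(g, id, "maxpool2", input, out_shape = c(s[1] %/% 2, s[2] %/% 2, s[3]))
}

#' @keywords internal
ng_gap <- function(g, input, id = NULL) {
  s <- ng_shape(g, input)
  if (is.null(id)) id <- ng_uid(g, "gap")
  ng_put(g, id, "gap", input, hyper = list(hw = s[1] * s[2]),
         out_shape = s[3])
}

#' @keywords internal
ng_linear <- function(g, input, out, bias = TRUE, id = NULL) {
  s <- ng_shape(g, input)
  if (length(s) != 1) stop("linear expects a vector input (use ng_gap first)")
  par <- NULL
  if (g$init_params) {
    par <- list(W = matrix(stats::rnorm(s * out, sd = sqrt(2 / s)), s, out))
    if (bias) par$b <- numeric(out)
  }
  if (is.null(id)) id <- ng_uid(g, "fc")
  ng_put(g, id, "linear", input,
         hyper = list(fin = s, fout = as.integer(out), bias = bias),
         par = par, out_shape = out)
}

#' @keywords internal
ng_add2 <- function(g, a, b, id = NULL) {
  sa <- ng_shape(g, a); sb <- ng_shape(g, b)
  if (!identical(sa, sb)) stop("add: shape mismatch")
  if (is.null(id)) id <- ng_uid(g, "add")
  ng_put(g, id, "add", c(a, b), out_shape = sa)
}

#' @keywords internal
ng_concat <- function(g, a, b, id = NULL) {
  sa <- ng_shape(g, a); sb <- ng_shape(g, b)
  if (!identical(sa[1:2], sb[1:2])) stop("concat: spatial shape mismatch")
  if (is.null(id)) id <- ng_uid(g, "cat")
  ng_put(g, id, "concat", c(a, b),
         hyper = list(c1 = sa[3], c2 = sb[3]),
         out_shape = c(sa[1], sa[2], sa[3] + sb[3]))
}

#' @keywords internal
ng_upsample2 <- function(g, input, id = NULL) {
  s <- ng_shape(g, input)
  if (is.null(id)) id <- ng_uid(g, "up")
  ng_put(g, id, "upsample2", input, out_shape = c(2L * s[1], 2L * s[2], s[3]))
}

#' @keywords internal
ng_dropout <- function(g, input, rate, id = NULL) {
  if (is.null(id)) id <- ng_uid(g, "drop")
  ng_put(g, id, "dropout", input, hyper = list(rate = rate),
         out_shape = ng_shape(g, input))
}

## Multiply a (H, W, C) map by a per-channel (C) vector node
## (squeeze-and-excite gate).
#' @keywords internal
ng_sescale <- function(g, x, s, id = NULL) {
  sx <- ng_shape(g, x); ss <- ng_shape(g, s)
  if (length(ss) != 1 || ss != sx[3]) stop("sescale: gate must be (C)")
  if (is.null(id)) id <- ng_uid(g, "sescale")
  ng_put(g, id, "sescale", c(x, s), out_shape = sx)
}

channel_stat <- function(x, f = colSums) {
  d <- dim(x)
  hw <- d[1] * d[2]
  m <- x
  dim(m) <- c(hw, d[3] * d[4])
  rowSums(matrix(f(m), d[3], d[4]))
}

act_forward <- function(x, type) {
  switch(type,
         relu = pmax(x, 0),
         relu6 = pmin(pmax(x, 0), 6),
         sigmoid = 1 / (1 + exp(-x)),
         hardsigmoid = pmin(pmax(x / 6 + 0.5, 0), 1),
         hardswish = x * pmin(pmax(x / 6 + 0.5, 0), 1),
         stop("unknown activation: ", type))
}

act_backward <- function(dy, x, y, type) {
  switch(type,
         relu = dy * (x > 0),
         relu6 = dy * (x > 0 & x < 6),
         sigmoid = dy * y * (1 - y),
         hardsigmoid = dy * (x > -3 & x < 3) / 6,
         hardswish = dy * ifelse(x <= -3, 0, ifelse(x >= 3, 1, x / 3 + 0.5)),
         stop("unknown activation: ", type))
}

#' Forward pass through a network graph
#'
#' @param g graph built with the `ng_*` helpers.
#' @param x input array `(H, W, C, N)`.
#' @param train logical; `TRUE` uses batch statistics, applies dropout and
#'   records the caches needed for [nn_backward()].
#' @return list with `out` (the last node's output) and, when `train = TRUE`,
#'   per-node caches.
#' @keywords internal
nn_forward <- function(g, x, train = FALSE) {
  acts <- list(input = x)
  caches <- if (train) list() else NULL
  for (node in g$nodes) {
    xin <- acts[[node$inputs[1]]]
    y <- switch(node$op,
      conv = {
        ## patch-matrix caching pays off in the backward pass but is skipped
        ## for very large layers to bound training memory
        k2 <- node$hyper$k^2 * (node$hyper$cin %/% node$hyper$groups)
        os <- g$shapes[[node$id]]
        cache_ok <- k2 * os[1] * os[2] * dim(xin)[4] <= 8e6
        if (train && node$hyper$groups == 1L && cache_ok) {
          r <- cpp_conv2d_forward_train(
            xin, node$par$W,
            if (isTRUE(node$hyper$bias)) node$par$b else NULL,
            node$hyper$stride, node$hyper$pad)
          caches[[node$id]] <- list(cols = r$cols)
          r$y
        } else {
          cpp_conv2d_forward(xin, node$par$W,
                             if (isTRUE(node$hyper$bias)) node$par$b else NULL,
                             node$hyper$stride, node$hyper$pad,
                             node$hyper$groups)
        }
      },
      bn = {
        d <- dim(xin); hw <- d[1] * d[2]
        if (train) {
          r <- cpp_bn_forward_train(xin, node$par$gamma, node$par$beta,
                                    node$hyper$eps)
          mom <- node$hyper$momentum
          g$nodes[[node$id]]$par$rmean <-
            (1 - mom) * node$par$rmean + mom * r$mu
          g$nodes[[node$id]]$par$rvar <-
            (1 - mom) * node$par$rvar + mom * r$var
          caches[[node$id]] <- list(mu = r$mu, istd = r$istd)
          r$y
        } else {
          istd <- 1 / sqrt(node$par$rvar + node$hyper$eps)
          sc <- node$par$gamma * istd
          sh <- node$par$beta - node$par$rmean * sc
          xin * rep(sc, each = hw) + rep(sh, each = hw)
        }
      },
      act = if (node$hyper$type == "relu") cpp_relu_forward(xin) else
        act_forward(xin, node$hyper$type),
      maxpool2 = {
        r <- cpp_maxpool2_forward(xin)
        if (train) caches[[node$id]] <- list(idx = r$idx, in_dim = dim(xin))
        r$y
      },
      gap = {
        d <- dim(xin); m <- xin; dim(m) <- c(d[1] * d[2], d[3] * d[4])
        matrix(colMeans(m), d[3], d[4])
      },
      linear = {
        m <- if (is.matrix(xin)) xin else matrix(xin, nrow = node$hyper$fin)
        y <- crossprod(node$par$W, m)
        if (isTRUE(node$hyper$bias)) y <- y + node$par$b
        y
      },
      add = xin + acts[[node$inputs[2]]],
      concat = {
        b <- acts[[node$inputs[2]]]
        d1 <- dim(xin); d2 <- dim(b)
        out <- array(0, c(d1[1], d1[2], d1[3] + d2[3], d1[4]))
        out[, , seq_len(d1[3]), ] <- xin
        out[, , d1[3] + seq_len(d2[3]), ] <- b
        out
      },
      upsample2 = {
        d <- dim(xin)
        xin[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
            drop = FALSE]
      },
      dropout = {
        if (train && node$hyper$rate > 0) {
          keep <- (stats::runif(length(xin)) >= node$hyper$rate) /
            (1 - node$hyper$rate)
          caches[[node$id]] <- list(mask = keep)
          xin * keep
        } else xin
      },
      sescale = {
        s <- acts[[node$inputs[2]]]
        d <- dim(xin)
        xin * rep(s, each = d[1] * d[2])
      },
      stop("unknown op: ", node$op))
    acts[[node$id]] <- y
  }
  list(out = acts[[g$nodes[[length(g$nodes)]]$id]],
       acts = if (train) acts else NULL, caches = caches)
}

#' Backward pass; returns parameter gradients keyed by node id
#' @keywords internal
nn_backward <- function(g, fwd, dout) {
  acts <- fwd$acts
  caches <- fwd$caches
  grads_out <- list()
  last <- g$nodes[[length(g$nodes)]]$id
  grads_out[[last]] <- dout
  pgrads <- list()
  for (i in rev(seq_along(g$nodes))) {
    node <- g$nodes[[i]]
    dy <- grads_out[[node$id]]
    if (is.null(dy)) next
    xin_id <- node$inputs[1]
    xin <- acts[[xin_id]]
    need_dx <- xin_id != "input"
    dx <- NULL
    switch(node$op,
      conv = {
        cache <- caches[[node$id]]
        r <- if (!is.null(cache$cols)) {
          cpp_conv2d_backward_cols(cache$cols, dim(xin), node$par$W, dy,
                                   node$hyper$stride, node$hyper$pad,
                                   need_dx, isTRUE(node$hyper$bias))
        } else {
          cpp_conv2d_backward(xin, node$par$W, dy, node$hyper$stride,
                              node$hyper$pad, node$hyper$groups,
                              need_dx, isTRUE(node$hyper$bias))
        }
        pg <- list(W = r$dw)
        if (isTRUE(node$hyper$bias)) pg$b <- r$db
        pgrads[[node$id]] <- pg
        if (need_dx) dx <- r$dx
      },
      bn = {
        cache <- caches[[node$id]]
        r <- cpp_bn_backward(xin, dy, node$par$gamma, cache$mu, cache$istd,
                             need_dx)
        pgrads[[node$id]] <- list(gamma = r$dgamma, beta = r$dbeta)
        if (need_dx) dx <- r$dx
      },
      act = if (need_dx)
        dx <- if (node$hyper$type == "relu") cpp_relu_backward(xin, dy) else
          act_backward(dy, xin, acts[[node$id]], node$hyper$type),
      maxpool2 = if (need_dx) {
        cache <- caches[[node$id]]
        dx <- cpp_maxpool2_backward(dy, cache$idx, cache$in_dim)
      },
      gap = if (need_dx) {
        d <- dim(xin); hw <- d[1] * d[2]
        dx <- array(rep(dy / hw, each = hw), dim = d)
      },
      linear = {
        m <- if (is.matrix(xin)) xin else matrix(xin, nrow = node$hyper$fin)
        pg <- list(W = m %*% t(dy))
        if (isTRUE(node$hyper$bias)) pg$b <- rowSums(dy)
        pgrads[[node$id]] <- pg
        if (need_dx) dx <- node$par$W %*% dy
      },
      add = {
        if (need_dx) dx <- dy
        other <- node$inputs[2]
        if (other != "input")
          grads_out[[other]] <- if (is.null(grads_out[[other]])) dy else
            grads_out[[other]] + dy
      },
      concat = {
        c1 <- node$hyper$c1
        if (need_dx) dx <- dy[, , seq_len(c1), , drop = FALSE]
        other <- node$inputs[2]
        if (other != "input") {
          db <- dy[, , c1 + seq_len(node$hyper$c2), , drop = FALSE]
          grads_out[[other]] <- if (is.null(grads_out[[other]])) db else
            grads_out[[other]] + db
        }
      },
      upsample2 = if (need_dx) {
        d <- dim(xin)
        oi <- seq(1, 2 * d[1], by = 2); oj <- seq(1, 2 * d[2], by = 2)
        dx <- dy[oi, oj, , , drop = FALSE] + dy[oi + 1, oj, , , drop = FALSE] +
          dy[oi, oj + 1, , , drop = FALSE] + dy[oi + 1, oj + 1, , , drop = FALSE]
      },
      dropout = if (need_dx) {
        cache <- caches[[node$id]]
        dx <- if (is.null(cache)) dy else dy * cache$mask
      },
      sescale = {
        s <- acts[[node$inputs[2]]]
        d <- dim(xin); hw <- d[1] * d[2]
        if (need_dx) dx <- dy * rep(s, each = hw)
        other <- node$inputs[2]
        if (other != "input") {
          ds <- matrix(channel_stat_mat(dy * xin), d[3], d[4])
          grads_out[[other]] <- if (is.null(grads_out[[other]])) ds else
            grads_out[[other]] + ds
        }
      },
      stop("unknown op in backward: ", node$op))
    if (need_dx && !is.null(dx)) {
      grads_out[[xin_id]] <- if (is.null(grads_out[[xin_id]])) dx else
        grads_out[[xin_id]] + dx
    }
    grads_out[[node$id]] <- NULL # free memory as we go
  }
  pgrads
}

## per-(channel, image) sums, returned as a (C*N) vector
channel_stat_mat <- function(x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1] * d[2], d[3] * d[4])
  colSums(m)
}

## ---- optimizer -------------------------------------------------------------

#' @keywords internal
adam_init <- function(g) {
  st <- list(t = 0L, m = list(), v = list())
  for (node in g$nodes) {
    if (is.null(node$par)) next
    trainable <- setdiff(names(node$par), c("rmean", "rvar"))
    for (p in trainable) {
      key <- paste0(node$id, ".", p)
      st$m[[key]] <- node$par[[p]] * 0
      st$v[[key]] <- node$par[[p]] * 0
    }
  }
  st
}

#' @keywords internal
adam_step <- function(g, pgrads, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (id in names(pgrads)) {
    for (p in names(pgrads[[id]])) {
      key <- paste0(id, ".", p)
      gr <- pgrads[[id]][[p]]
      st$m[[key]] <- beta1 * st$m[[key]] + (1 - beta1) * gr
      st$v[[key]] <- beta2 * st$v[[key]] + (1 - beta2) * gr * gr
      upd <- lr * (st$m[[key]] / bc1) / (sqrt(st$v[[key]] / bc2) + eps)
      g$nodes[[id]]$par[[p]] <- g$nodes[[id]]$par[[p]] - upd
    }
  }
  st
}

## ---- losses ----------------------------------------------------------------

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

#' Focal cross-entropy on class probabilities
#'
#' Computes `-alpha * (1 - p)^gamma * log(p)` averaged over a batch, where
#' `p` is the predicted probability of each sample's true class.
#' `gamma = 0`, `alpha = 1` recovers plain cross-entropy. Probabilities are
#' clipped to `[1e-7, 1]` before the logarithm.
#'
#' @param p numeric vector of true-class probabilities in `(0, 1]`.
#' @param gamma focusing exponent, `>= 0`; larger values down-weight easy,
#'   well-classified samples.
#' @param alpha positive scale factor in `(0, 1]`.
#' @return mean focal loss (non-negative scalar).
#' @examples
#' focal_loss(0.5, gamma = 0, alpha = 1)   # log(2)
#' focal_loss(0.9, gamma = 2, alpha = 1)   # 0.01 * -log(0.9)
#' @export
focal_loss <- function(p, gamma = 2, alpha = 0.25) {
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (gamma < 0) stop("gamma must be >= 0")
  if (alpha <= 0) stop("alpha must be positive")
  p <- pmax(p, 1e-7)
  mean(-alpha * (1 - p)^gamma * log(p))
}

#' Softmax cross-entropy (optionally focal) loss and logit gradient
#'
#' @param logits `(K, N)` matrix of unnormalised scores.
#' @param labels integer class labels in `1..K`.
#' @param gamma,alpha focal parameters; `gamma = 0`, `alpha = 1` is plain
#'   cross-entropy.
#' @return list with `loss`, `probs` and `dlogits` (gradient of the mean loss).
#' @keywords internal
softmax_focal_loss <- function(logits, labels, gamma = 0, alpha = 1) {
  n <- ncol(logits)
  probs <- softmax_cols(logits)
  idx <- cbind(labels, seq_len(n))
  pt <- pmin(pmax(probs[cbind(labels, seq_len(n))], 1e-7), 1 - 1e-7)
  loss <- mean(-alpha * (1 - pt)^gamma * log(pt))
  if (gamma == 0) {
    dpt_chain <- -alpha / pt
  } else {
    dpt_chain <- alpha * gamma * (1 - pt)^(gamma - 1) * log(pt) -
      alpha * (1 - pt)^gamma / pt
  }
  onehot <- matrix(0, nrow(logits), n)
  onehot[idx] <- 1
  ## dL/dz_j = dL/dp_t * p_t * (1[j = t] - p_j)
  dlogits <- rep(dpt_chain * pt, each = nrow(logits)) * (onehot - probs) / n
  list(loss = loss, probs = probs, dlogits = dlogits)
}

## ---- training loop ---------------------------------------------------------

#' Train a classification graph with Adam
#'
#' @param g network graph ending in a linear logit layer `(K, N)`.
#' @param x input array `(H, W, C, N)`.
#' @param y integer labels `1..K`.
#' @param epochs,batch_size,lr training schedule.
#' @param gamma,alpha focal-loss parameters (`0`, `1` = plain cross-entropy).
#' @param augment apply horizontal flips and brightness jitter (expects raw
#'   frames in `[0, 1]`; applied before any normalisation).
#' @param normalize apply per-frame channel-mean normalisation to each
#'   minibatch (after augmentation).
#' @param shuffle reshuffle minibatches each epoch.
#' @param verbose print per-epoch training loss.
#' @return list with the trained graph and a per-epoch loss history.
#' @keywords internal
nn_train_classifier <- function(g, x, y, epochs = 5, batch_size = 32,
                                lr = 1e-3, gamma = 0, alpha = 1,
                                augment = FALSE, normalize = FALSE,
                                shuffle = TRUE, verbose = FALSE) {
  n <- dim(x)[4]
  st <- adam_init(g)
  history <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- if (shuffle) sample.int(n) else seq_len(n)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1, n, by = batch_size)) {
      take <- ord[start:min(start + batch_size - 1, n)]
      xb <- x[, , , take, drop = FALSE]
      if (augment) xb <- augment_batch(xb)
      if (normalize) xb <- normalize_frames(xb)
      fwd <- nn_forward(g, xb, train = TRUE)
      ls <- softmax_focal_loss(fwd$out, y[take], gamma = gamma, alpha = alpha)
      pg <- nn_backward(g, fwd, ls$dlogits)
      st <- adam_step(g, pg, st, lr = lr)
      ep_loss <- ep_loss + ls$loss
      nb <- nb + 1L
    }
    history <- c(history, ep_loss / nb)
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f", ep, epochs, ep_loss / nb))
  }
  list(graph = g, history = history)
}

## Horizontal flip (p = 0.5) and multiplicative brightness jitter (+-10%).
augment_batch <- function(xb) {
  d <- dim(xb)
  flip <- stats::runif(d[4]) < 0.5
  if (any(flip))
    xb[, , , flip] <- xb[, rev(seq_len(d[2])), , flip, drop = FALSE]
  bright <- stats::runif(d[4], 0.9, 1.1)
  xb <- xb * rep(bright, each = d[1] * d[2] * d[3])
  pmin(pmax(xb, 0), 1)
}

#' Class probabilities for a batch of frames
#'
#' @param g trained graph.
#' @param x `(H, W, C, N)` array.
#' @param batch_size minibatch size used during inference.
#' @return `(K, N)` matrix of softmax probabilities.
#' @keywords internal
nn_predict_proba <- function(g, x, batch_size = 64) {
  n <- dim(x)[4]
  out <- NULL
  for (start in seq(1, n, by = batch_size)) {
    take <- start:min(start + batch_size - 1, n)
    p <- softmax_cols(nn_forward(g, x[, , , take, drop = FALSE])$out)
    out <- if (is.null(out)) p else cbind(out, p)
  }
  out
}

#' Number of trainable parameters in a graph
#' @keywords internal
nn_count_params <- function(g) {
  total <- 0
  for (node in g$nodes) {
    if (is.null(node$par)) next
    for (p in setdiff(names(node$par), c("rmean", "rvar")))
      total <- total + length(node$par[[p]])
  }
  total
}
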