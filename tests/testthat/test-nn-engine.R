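test_that("backpropagation matches numerical gradients", {
  set.seed(1)
  g <- endoscreen:::ng_new(c(8, 8, 3))
  x1 <- endoscreen:::ng_conv(g, "input", 4, 3, bias = TRUE)
  x1 <- endoscreen:::ng_bn(g, x1)
  x1 <- endoscreen:::ng_act(g, x1, "relu")
  x2 <- endoscreen:::ng_conv(g, x1, 4, 3, groups = 4) # depthwise
  x2 <- endoscreen:::ng_add2(g, x2, x1)               # residual
  x3 <- endoscreen:::ng_maxpool2(g, x2)
  x3 <- endoscreen:::ng_upsample2(g, x3)
  x3 <- endoscreen:::ng_concat(g, x3, x1)             # skip connection
  s <- endoscreen:::ng_gap(g, x3)
  s <- endoscreen:::ng_linear(g, s, 8)
  s <- endoscreen:::ng_act(g, s, "sigmoid")
  x4 <- endoscreen:::ng_sescale(g, x3, s)             # SE gate
  v <- endoscreen:::ng_gap(g, x4)
  endoscreen:::ng_linear(g, v, 2)

  x <- array(rnorm(8 * 8 * 3 * 4), c(8, 8, 3, 4))
  y <- c(1, 2, 1, 2)
  for (id in names(g$nodes))
    if (g$nodes[[id]]$op == "bn") g$nodes[[id]]$hyper$momentum <- 0
  lossfun <- function() {
    fwd <- endoscreen:::nn_forward(g, x, train = TRUE)
    endoscreen:::softmax_focal_loss(fwd$out, y, gamma = 2, alpha = 0.5)$loss
  }
  fwd <- endoscreen:::nn_forward(g, x, train = TRUE)
  ls <- endoscreen:::softmax_focal_loss(fwd$out, y, gamma = 2, alpha = 0.5)
  pg <- endoscreen:::nn_backward(g, fwd, ls$dlogits)
  eps <- 1e-6
  set.seed(2)
  for (id in names(pg)) {
    for (p in names(pg[[id]])) {
      par <- g$nodes[[id]]$par[[p]]
      for (k in sample(length(par), min(3, length(par)))) {
        g$nodes[[id]]$par[[p]][k] <- par[k] + eps; lp <- lossfun()
        g$nodes[[id]]$par[[p]][k] <- par[k] - eps; lm <- lossfun()
        g$nodes[[id]]$par[[p]][k] <- par[k]
        num <- (lp - lm) / (2 * eps)
        expect_equal(pg[[id]][[p]][k], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("focal loss matches its closed form and degenerates to CE", {
  expect_equal(focal_loss(0.5, gamma = 0, alpha = 1), log(2),
               tolerance = 1e-9)
  expect_equal(focal_loss(0.9, gamma = 2, alpha = 1),
               0.01 * (-log(0.9)), tolerance = 1e-7)
  expect_equal(focal_loss(0.9, gamma = 2, alpha = 1), 0.0010536,
               tolerance = 1e-4)
  expect_equal(focal_loss(1, gamma = 2, alpha = 0.25), 0, tolerance = 1e-6)
  expect_equal(focal_loss(1, gamma = 0, alpha = 1), 0, tolerance = 1e-6)
  expect_error(focal_loss(1.2), "probabilities")

  # gamma = 0, alpha = 1 reproduces the plain cross-entropy batch loss
  set.seed(3)
  logits <- matrix(rnorm(10), 2, 5)
  labels <- c(1, 2, 2, 1, 2)
  fl <- endoscreen:::softmax_focal_loss(logits, labels, gamma = 0, alpha = 1)
  probs <- apply(logits, 2, function(z) exp(z - max(z)) / sum(exp(z - max(z))))
  ce <- mean(-log(probs[cbind(labels, 1:5)]))
  expect_equal(fl$loss, ce, tolerance = 1e-9)
})

test_that("a few Adam steps reduce the training loss on a separable task", {
  set.seed(4)
  g <- endoscreen:::ng_new(c(8, 8, 1))
  h <- endoscreen:::ng_conv(g, "input", 4, 3)
  h <- endoscreen:::ng_act(g, h, "relu")
  h <- endoscreen:::ng_gap(g, h)
  endoscreen:::ng_linear(g, h, 2)
  n <- 64
  x <- array(rnorm(8 * 8 * n, sd = 0.1), c(8, 8, 1, n))
  y <- rep(1:2, each = n / 2)
  x[, , , y == 2] <- x[, , , y == 2] + 0.8
  fit <- endoscreen:::nn_train_classifier(g, x, y, epochs = 5,
                                          batch_size = 16, lr = 5e-3)
  expect_lt(tail(fit$history, 1), fit$history[1])
  probs <- endoscreen:::nn_predict_proba(fit$graph, x)
  expect_gt(auroc(y - 1, probs[2, ]), 0.95)
  expect_equal(colSums(probs), rep(1, n), tolerance = 1e-12)
})
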