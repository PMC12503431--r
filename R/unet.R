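## Stage 2a of the image quality module: a U-Net glottis segmenter trained on
## image/mask pairs, whose predictions are turned into weak good/poor frame
## quality labels via a visibility rule ("the glottal area is entirely
## visible"): the predicted mask must be large enough and must not touch the
## frame border.

#' U-Net architecture specification
#'
#' A canonical U-Net: `depth` encoder/decoder levels of two 3x3
#' convolution + batch-norm + ReLU layers each, 2x2 max pooling, nearest
#' upsampling and skip concatenation, ending in a 1x1 convolution that emits
#' a per-pixel glottis logit. Channel width doubles per level.
#'
#' @param depth encoder/decoder levels.
#' @param base_channels channels of the first level.
#' @param input_size `c(H, W)`, divisible by `2^depth`. Frames of other sizes
#'   are resized on the way in and predictions upsampled on the way out.
#' @return object of class `unet_spec`.
#' @export
unet_spec <- function(depth = 3, base_channels = 8, input_size = c(64, 64)) {
  input_size <- as.integer(rep(input_size, length.out = 2))
  if (any(input_size %% 2^depth != 0))
    err("input_size must be divisible by 2^depth", "endoscreen_argument_error")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 input_size = input_size),
            class = "unet_spec")
}

conv_block <- function(g, x, ch) {
  for (i in 1:2) {
    x <- ng_conv(g, x, ch, 3)
    x <- ng_bn(g, x)
    x <- ng_act(g, x, "relu")
  }
  x
}

build_unet_graph <- function(spec) {
  g <- ng_new(c(spec$input_size, 3L), init_params = TRUE)
  skips <- character(0)
  x <- "input"
  for (lev in seq_len(spec$depth)) {
    x <- conv_block(g, x, spec$base_channels * 2^(lev - 1))
    if (lev < spec$depth) {
      skips <- c(skips, x)
      x <- ng_maxpool2(g, x)
    }
  }
  for (lev in rev(seq_len(spec$depth - 1))) {
    x <- ng_upsample2(g, x)
    x <- ng_concat(g, x, skips[lev])
    x <- conv_block(g, x, spec$base_channels * 2^(lev - 1))
  }
  ng_conv(g, x, 1L, 1, bias = TRUE)
  g
}

## Compound segmentation loss: pixel BCE + soft Dice, with the gradient
## taken directly w.r.t. the logits.
seg_loss_grad <- function(logits, y, bce_weight = 0.5, smooth = 1) {
  p <- 1 / (1 + exp(-logits))
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  n <- dim(y)[4]
  npix <- prod(dim(y)[1:3])
  bce <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  dbce <- (p - y) / (npix * n)
  sum_d <- function(a) colSums(matrix(a, npix, n))
  inter <- sum_d(p * y)
  sp <- sum_d(p)
  sy <- sum_d(y)
  dice <- (2 * inter + smooth) / (sp + sy + smooth)
  denom <- (sp + sy + smooth)^2
  ## d(1 - dice_i)/dp = -(2 y (sp+sy+s) - (2 inter + s)) / denom
  coef_y <- rep(2 * (sp + sy + smooth) / denom, each = npix)
  coef_c <- rep((2 * inter + smooth) / denom, each = npix)
  ddice <- -(coef_y * y - coef_c) / n
  dlogits <- (bce_weight * dbce + (1 - bce_weight) * ddice) * p * (1 - p)
  list(loss = bce_weight * bce + (1 - bce_weight) * mean(1 - dice),
       dlogits = dlogits, mean_dice = mean(dice))
}

#' Train the U-Net glottis segmenter
#'
#' @param pairs list of `list(frame, mask)` as produced by
#'   [generate_segmentation_set()] or [load_mask_pairs()]; at least 10.
#' @param spec a [unet_spec()].
#' @param epochs,batch_size,lr training schedule (Adam).
#' @param seed seed for initialisation and minibatch order.
#' @param verbose print the per-epoch loss.
#' @return object of class `unet_model`.
#' @export
train_unet <- function(pairs, spec = unet_spec(), epochs = 4, batch_size = 16,
                       lr = 2e-3, seed = 0L, verbose = FALSE) {
  if (length(pairs) == 0)
    err("empty training set", "endoscreen_argument_error")
  if (length(pairs) < 10)
    err("need at least 10 training pairs", "endoscreen_argument_error")
  sz <- spec$input_size
  n <- length(pairs)
  x <- array(0, c(sz[1], sz[2], 3, n))
  y <- array(0, c(sz[1], sz[2], 1, n))
  for (i in seq_len(n)) {
    x[, , , i] <- resize_hw(pairs[[i]]$frame$pixels, sz)
    y[, , 1, i] <- resize_hw(pairs[[i]]$mask$pixels + 0, sz) >= 0.5
  }
  set.seed(seed)
  g <- build_unet_graph(spec)
  st <- adam_init(g)
  history <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1, n, by = batch_size)) {
      take <- ord[start:min(start + batch_size - 1, n)]
      fwd <- nn_forward(g, x[, , , take, drop = FALSE], train = TRUE)
      ls <- seg_loss_grad(fwd$out, y[, , , take, drop = FALSE])
      pg <- nn_backward(g, fwd, ls$dlogits)
      st <- adam_step(g, pg, st, lr = lr)
      ep_loss <- ep_loss + ls$loss; nb <- nb + 1L
    }
    history <- c(history, ep_loss / nb)
    if (verbose)
      message(sprintf("unet epoch %d/%d  loss %.4f", ep, epochs,
                      ep_loss / nb))
  }
  structure(list(spec = spec, graph = g, trained = TRUE, history = history),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> depth %d, base %d, input %dx%d, %s\n",
              x$spec$depth, x$spec$base_channels, x$spec$input_size[1],
              x$spec$input_size[2],
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

## forward a (H, W, 3, N) batch -> glottis probability maps at model size
unet_prob_maps <- function(model, x, batch_size = 32) {
  sz <- model$spec$input_size
  x <- resize_batch(x, sz)
  n <- dim(x)[4]
  out <- array(0, c(sz[1], sz[2], 1, n))
  for (start in seq(1, n, by = batch_size)) {
    take <- start:min(start + batch_size - 1, n)
    z <- nn_forward(model$graph, x[, , , take, drop = FALSE])$out
    out[, , , take] <- 1 / (1 + exp(-z))
  }
  out
}

nearest_upsample_mask <- function(m, target) {
  h <- nrow(m); w <- ncol(m)
  if (h == target[1] && w == target[2]) return(m)
  ri <- pmin(pmax(ceiling(seq_len(target[1]) * h / target[1]), 1L), h)
  ci <- pmin(pmax(ceiling(seq_len(target[2]) * w / target[2]), 1L), w)
  m[ri, ci, drop = FALSE]
}

#' Predict a binary glottis mask for one frame
#'
#' The frame is resized to the model's input size; the thresholded
#' prediction is upsampled (nearest neighbour) back to the frame's original
#' resolution.
#'
#' @param model a trained [train_unet()] model.
#' @param frame a [frame_record()] or `(H, W, 3)` array.
#' @param prob_threshold per-pixel binarisation threshold.
#' @return a [segmentation_mask()] at the frame's resolution.
#' @export
predict_mask <- function(model, frame, prob_threshold = 0.5) {
  if (!inherits(model, "unet_model") || !isTRUE(model$trained))
    err("model is not a trained unet_model", "endoscreen_state_error")
  px <- if (inherits(frame, "frame_record")) frame$pixels else frame
  d <- dim(px)
  x <- array(px, c(d[1], d[2], 3, 1))
  pm <- unet_prob_maps(model, x)[, , 1, 1]
  m <- matrix(as.integer(pm >= prob_threshold), nrow(pm), ncol(pm))
  segmentation_mask(nearest_upsample_mask(m, d[1:2]),
                    if (inherits(frame, "frame_record")) frame$patient_id,
                    if (inherits(frame, "frame_record")) frame$frame_index)
}

#' Visibility criteria turning a predicted mask into a quality label
#'
#' A frame is "good" when the glottis is entirely visible: the predicted
#' mask must cover at least `min_area_fraction` of the frame AND stay clear
#' of a `border_margin`-pixel band at every edge (a mask touching the border
#' indicates a partially visible or cut-off glottis; it also rejects
#' off-target views where the segmenter floods a dark lumen). The default
#' `prob_threshold` is deliberately strict: the segmenter emits large
#' high-confidence masks on sharp frames, while blur erodes the
#' high-confidence area, so thresholding near 1 combined with a minimum
#' area of 2% of the frame (a properly framed glottis occupies several
#' percent) is what makes blurred frames fail the visibility test.
#'
#' @param min_area_fraction minimum predicted mask area / frame area.
#' @param border_margin width in pixels of the exclusion band at each edge.
#' @param prob_threshold per-pixel binarisation threshold used upstream.
#' @return object of class `visibility_criteria`.
#' @export
visibility_criteria <- function(min_area_fraction = 0.02, border_margin = 2,
                                prob_threshold = 0.99) {
  if (min_area_fraction < 0 || min_area_fraction >= 1)
    err("min_area_fraction must lie in [0, 1)", "endoscreen_argument_error")
  if (border_margin < 0)
    err("border_margin must be >= 0", "endoscreen_argument_error")
  structure(list(min_area_fraction = min_area_fraction,
                 border_margin = as.integer(border_margin),
                 prob_threshold = prob_threshold),
            class = "visibility_criteria")
}

#' Assign a weak quality label from a segmentation mask
#'
#' @param mask a [segmentation_mask()].
#' @param criteria a [visibility_criteria()].
#' @return `"good"` or `"poor"`.
#' @export
assign_quality_label <- function(mask, criteria = visibility_criteria()) {
  m <- mask$pixels
  h <- nrow(m); w <- ncol(m)
  if (sum(m) < criteria$min_area_fraction * h * w) return("poor")
  bm <- criteria$border_margin
  if (bm > 0) {
    border <- sum(m[seq_len(bm), ]) + sum(m[(h - bm + 1):h, ]) +
      sum(m[, seq_len(bm)]) + sum(m[, (w - bm + 1):w])
    if (border > 0) return("poor")
  }
  "good"
}

#' Weakly label every frame of a set of videos
#'
#' Runs the segmenter over all frames and applies the visibility criteria,
#' producing the weak quality labels used to train the supervised quality
#' classifier.
#'
#' @param model a trained [train_unet()] model.
#' @param videos list of [video_record()]s.
#' @param criteria a [visibility_criteria()].
#' @return data frame with columns `patient_id`, `frame_index`,
#'   `referral_grade` and `quality_label` (`"good"`/`"poor"`, provenance
#'   "weak"); a `summary` attribute carries the good/poor counts.
#' @export
weak_label_dataset <- function(model, videos,
                               criteria = visibility_criteria()) {
  if (!inherits(model, "unet_model") || !isTRUE(model$trained))
    err("model is not a trained unet_model", "endoscreen_state_error")
  out <- list()
  for (vid in videos) {
    if (length(vid$frames) == 0) next
    x <- frames_to_batch(vid)
    pm <- unet_prob_maps(model, x)
    d <- dim(x)
    labels <- character(dim(pm)[4])
    for (i in seq_along(labels)) {
      m <- matrix(as.integer(pm[, , 1, i] >= criteria$prob_threshold),
                  dim(pm)[1], dim(pm)[2])
      mask <- segmentation_mask(nearest_upsample_mask(m, d[1:2]))
      labels[i] <- assign_quality_label(mask, criteria)
    }
    out[[length(out) + 1]] <- data.frame(
      patient_id = vid$patient_id,
      frame_index = vapply(vid$frames, function(f) f$frame_index, integer(1)),
      referral_grade = vid$referral_grade,
      quality_label = labels, stringsAsFactors = FALSE)
  }
  res <- if (length(out) == 0) {
    data.frame(patient_id = character(0), frame_index = integer(0),
               referral_grade = integer(0), quality_label = character(0),
               stringsAsFactors = FALSE)
  } else do.call(rbind, out)
  attr(res, "summary") <- c(good = sum(res$quality_label == "good"),
                            poor = sum(res$quality_label == "poor"))
  attr(res, "provenance") <- "weak"
  res
}
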