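## Stage 1 of the image quality module: histogram-of-oriented-gradients
## descriptors, cosine similarity against an indexed reference frame, and a
## two-threshold relevance/redundancy filter over a frame sequence. The
## descriptor follows the canonical parameterisation (8-px cells, 2x2-cell
## blocks, 9 unsigned orientation bins, per-block L2 normalisation).

#' Parameters of the HOG descriptor
#'
#' @param cell_size cell edge in pixels.
#' @param block_size block edge in cells (blocks overlap with stride one
#'   cell).
#' @param n_bins unsigned orientation bins over `[0, 180)` degrees.
#' @param resize_to `c(H, W)` applied before extraction; must be divisible by
#'   `cell_size`.
#' @param epsilon normalisation constant guarding empty blocks. Besides
#'   preventing division by zero, a larger value acts as a gradient-energy
#'   floor: blocks whose total gradient magnitude is far below `epsilon`
#'   stay near zero instead of being amplified to unit norm, which keeps
#'   noise-only or flat regions from imitating structured content.
#' @param smooth_sigma optional Gaussian smoothing (pixels, at the resized
#'   scale) applied before differentiation; 0 disables it. Useful on noisy
#'   sensors where per-pixel noise would otherwise dominate the orientation
#'   histograms.
#' @return object of class `hog_params`.
#' @export
hog_params <- function(cell_size = 8, block_size = 2, n_bins = 9,
                       resize_to = c(224, 224), epsilon = 1e-6,
                       smooth_sigma = 0) {
  if (cell_size < 1 || block_size < 1 || n_bins < 1)
    err("cell_size, block_size and n_bins must be positive",
        "endoscreen_argument_error")
  resize_to <- as.integer(rep(resize_to, length.out = 2))
  if (any(resize_to %% cell_size != 0))
    err("resize_to must be divisible by cell_size",
        "endoscreen_argument_error")
  structure(list(cell_size = as.integer(cell_size),
                 block_size = as.integer(block_size),
                 n_bins = as.integer(n_bins),
                 resize_to = resize_to, epsilon = epsilon,
                 smooth_sigma = smooth_sigma),
            class = "hog_params")
}

#' Histogram-of-oriented-gradients descriptor of a frame
#'
#' The frame is converted to luminance, resized, differentiated with centred
#' differences (replicated edges), and gradient magnitudes are accumulated
#' into unsigned orientation histograms per cell with linear interpolation
#' between the two nearest bins. Overlapping `block_size` x `block_size`
#' cell blocks are L2-normalised and concatenated.
#'
#' @param frame a [frame_record()], an RGB array or a grayscale matrix.
#' @param params a [hog_params()].
#' @return numeric descriptor of length
#'   `n_blocks_y * n_blocks_x * block_size^2 * n_bins`.
#' @export
compute_hog <- function(frame, params = hog_params()) {
  px <- if (inherits(frame, "frame_record")) frame$pixels else frame
  g <- if (length(dim(px)) == 3) rgb_to_gray(px) else px
  g <- resize_hw(g, params$resize_to)
  if (!is.null(params$smooth_sigma) && params$smooth_sigma > 0)
    g <- blur_hw(g, params$smooth_sigma)
  h <- nrow(g); w <- ncol(g)
  if (h < params$cell_size || w < params$cell_size)
    err("frame smaller than one cell after resize",
        "endoscreen_argument_error")
  ## centred differences with replicated edges
  gy <- (g[c(2:h, h), ] - g[c(1, 1:(h - 1)), ]) / 2
  gx <- (g[, c(2:w, w)] - g[, c(1, 1:(w - 1))]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- (atan2(gy, gx) * 180 / pi) %% 180
  nb <- params$n_bins
  bw <- 180 / nb
  pos <- ang / bw - 0.5
  lo <- floor(pos)
  w_hi <- pos - lo
  bin_lo <- (as.integer(lo) %% nb)
  bin_hi <- (bin_lo + 1L) %% nb
  cs <- params$cell_size
  ncy <- h %/% cs; ncx <- w %/% cs
  cell_id <- (ceiling(row(g) / cs) - 1L) + ncy * (ceiling(col(g) / cs) - 1L)
  acc_idx_lo <- cell_id * nb + bin_lo
  acc_idx_hi <- cell_id * nb + bin_hi
  n_slots <- ncy * ncx * nb
  hist <- numeric(n_slots)
  add_lo <- tabulate_weighted(acc_idx_lo + 1L, mag * (1 - w_hi), n_slots)
  add_hi <- tabulate_weighted(acc_idx_hi + 1L, mag * w_hi, n_slots)
  hist <- add_lo + add_hi
  cells <- array(hist, c(nb, ncy, ncx))
  bs <- params$block_size
  nby <- ncy - bs + 1L; nbx <- ncx - bs + 1L
  if (nby < 1 || nbx < 1)
    err("frame too small for one block", "endoscreen_argument_error")
  desc <- numeric(nby * nbx * bs * bs * nb)
  k <- 0L
  blen <- bs * bs * nb
  for (bx in seq_len(nbx)) {
    for (by in seq_len(nby)) {
      v <- as.numeric(cells[, by:(by + bs - 1), bx:(bx + bs - 1)])
      v <- v / sqrt(sum(v^2) + params$epsilon^2)
      desc[k + seq_len(blen)] <- v
      k <- k + blen
    }
  }
  desc
}

## weighted tabulate: sums w by integer index 1..n
tabulate_weighted <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(as.numeric(w), group = as.integer(idx))
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Cosine similarity of two descriptors
#'
#' `dot(a, b) / (|a| |b|)`; returns 0 when either norm is 0.
#'
#' @param a,b equal-length numeric vectors.
#' @return real in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b))
    err("descriptors must have equal length", "endoscreen_argument_error")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Relevance/redundancy filter parameters
#'
#' @param index_frame 1-based position of the reference ("indexed") frame;
#'   the first frame of relevance, operator-chosen in practice.
#' @param tau_rel relevance threshold in `[-1, 1]`: a frame must be at least
#'   this similar to the index frame to be retained.
#' @param tau_dup near-duplicate threshold in `[-1, 1]`: a frame at least
#'   this similar to the most recently retained frame is dropped as
#'   redundant. Values `>= 1` disable the redundancy test.
#' @param center compare descriptors by Pearson correlation (cosine after
#'   centring each descriptor; the default) rather than raw cosine. Raw
#'   cosine of two non-negative histogram descriptors has a large positive
#'   baseline even for unrelated content; correlation removes it, so
#'   thresholds discriminate.
#' @return object of class `filter_params`.
#' @export
filter_params <- function(index_frame = 1L, tau_rel = 0.5, tau_dup = 0.98,
                          center = TRUE) {
  if (tau_rel < -1 || tau_rel > 1)
    err("tau_rel must lie in [-1, 1]", "endoscreen_argument_error")
  if (tau_dup < -1)
    err("tau_dup must be >= -1", "endoscreen_argument_error")
  structure(list(index_frame = as.integer(index_frame), tau_rel = tau_rel,
                 tau_dup = tau_dup, center = isTRUE(center)),
            class = "filter_params")
}

#' Similarity filter over a frame sequence
#'
#' The index frame is always retained. Each subsequent frame is retained iff
#' its HOG cosine similarity to the index frame is `>= tau_rel` (relevance)
#' AND its similarity to the most recently retained frame is `< tau_dup`
#' (not a near-duplicate). Frames before the index frame are not considered.
#'
#' @param video a [video_record()], or a list of frames/arrays.
#' @param hog a [hog_params()].
#' @param filt a [filter_params()].
#' @return strictly increasing integer vector of retained 1-based frame
#'   positions, with the per-frame similarity to the index frame attached as
#'   attribute `"similarity"` (NA before the index frame).
#' @export
similarity_filter <- function(video, hog = hog_params(),
                              filt = filter_params()) {
  frames <- if (inherits(video, "video_record")) video$frames else video
  n <- length(frames)
  if (n == 0) err("empty video", "endoscreen_argument_error")
  if (filt$index_frame < 1 || filt$index_frame > n)
    err("index_frame outside the video", "endoscreen_argument_error")
  descs <- lapply(frames, compute_hog, params = hog)
  if (isTRUE(filt$center)) descs <- lapply(descs, function(d) d - mean(d))
  idx <- filt$index_frame
  sims <- rep(NA_real_, n)
  sims[idx] <- 1
  retained <- idx
  last_desc <- descs[[idx]]
  for (i in seq_len(n)) {
    if (i <= idx) next
    s_rel <- cosine_similarity(descs[[i]], descs[[idx]])
    sims[i] <- s_rel
    if (s_rel < filt$tau_rel) next
    if (filt$tau_dup < 1 &&
        cosine_similarity(descs[[i]], last_desc) >= filt$tau_dup) next
    retained <- c(retained, i)
    last_desc <- descs[[i]]
  }
  structure(retained, similarity = sims)
}
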