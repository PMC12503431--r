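## Small image helpers shared across modules. Resizing and Gaussian blur are
## delegated to EBImage; everything operates on arrays in [0, 1] with
## spatial dimensions first.

err <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "endoscreen_error")))
}

#' Read an image file as an RGB array in [0, 1]
#'
#' PNG and JPEG are supported. Grayscale images are channel-replicated and an
#' alpha channel, if present, is dropped, so the result is always `(H, W, 3)`.
#' 8-bit and 16-bit inputs are both scaled to `[0, 1]` by the decoders.
#'
#' @param path file path.
#' @return numeric array `(H, W, 3)`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) err(paste0("image file not found: ", path),
                             "endoscreen_io_error")
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
               png = png::readPNG(path),
               jpg = ,
               jpeg = jpeg::readJPEG(path),
               err(paste0("unsupported image format: ", path),
                   "endoscreen_io_error"))
  to_rgb(px)
}

#' @keywords internal
to_rgb <- function(px) {
  if (is.matrix(px)) px <- array(px, c(dim(px), 1L))
  if (dim(px)[3] == 1L) px <- px[, , c(1, 1, 1), drop = FALSE]
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3] != 3L) err("expected 1, 3 or 4 channels",
                            "endoscreen_validation_error")
  px
}

#' Write an array in [0, 1] to a PNG file
#' @param pixels `(H, W)` or `(H, W, C)` array in `[0, 1]`.
#' @param path output path.
#' @export
write_image <- function(pixels, path) {
  png::writePNG(pmin(pmax(pixels, 0), 1), target = path)
  invisible(path)
}

#' Luminance (grayscale) of an RGB array
#' @keywords internal
rgb_to_gray <- function(px) {
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

## Bilinear resize of the first two dimensions of a (H, W, ...) array.
resize_hw <- function(x, target) {
  d <- dim(x)
  if (d[1] == target[1] && d[2] == target[2]) return(x)
  out <- EBImage::resize(x, w = target[1], h = target[2])
  array(as.numeric(out), c(target[1], target[2], d[-(1:2)]))
}

## Resize a batch (H, W, C, N) to (target, target, C, N).
resize_batch <- function(x, target) {
  d <- dim(x)
  if (d[1] == target[1] && d[2] == target[2]) return(x)
  dim(x) <- c(d[1], d[2], d[3] * d[4])
  x <- resize_hw(x, target)
  dim(x) <- c(target[1], target[2], d[3], d[4])
  x
}

## Gaussian blur of the first two dimensions (per channel).
blur_hw <- function(x, sigma) {
  d <- dim(x)
  nd <- length(d)
  if (is.null(d)) return(as.numeric(EBImage::gblur(x, sigma = sigma)))
  y <- EBImage::gblur(x, sigma = sigma)
  array(as.numeric(y), d)
}

#' Variance of the Laplacian, a standard sharpness statistic
#'
#' High on frames with crisp edges, low on blurred frames; used as an
#' independent check that the synthetic generator's blur corruption is
#' recoverable.
#'
#' @param px `(H, W, 3)` RGB array or `(H, W)` matrix.
#' @return non-negative scalar.
#' @export
laplacian_variance <- function(px) {
  g <- if (length(dim(px)) == 3) rgb_to_gray(px) else px
  h <- nrow(g); w <- ncol(g)
  lap <- 4 * g[2:(h - 1), 2:(w - 1)] -
    g[1:(h - 2), 2:(w - 1)] - g[3:h, 2:(w - 1)] -
    g[2:(h - 1), 1:(w - 2)] - g[2:(h - 1), 3:w]
  stats::var(as.numeric(lap))
}

#' Per-frame channel-mean normalisation
#'
#' Subtracts each frame's per-channel mean and re-centres at 0.5 — a colour
#' constancy step that removes global tone and illumination differences
#' between patients while preserving local contrast (the referral-relevant
#' signal). Applied by the frame classifiers as stored preprocessing.
#'
#' @param x `(H, W, C, N)` array (or `(H, W, C)` for one frame).
#' @return array of the same shape.
#' @export
normalize_frames <- function(x) {
  d <- dim(x)
  if (length(d) == 3) dim(x) <- c(d, 1L)
  d4 <- dim(x)
  m <- x
  dim(m) <- c(d4[1] * d4[2], d4[3] * d4[4])
  m <- sweep(m, 2, colMeans(m))
  dim(m) <- d4
  m <- m + 0.5
  if (length(d) == 3) dim(m) <- d
  m
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Deterministic per-unit seed derived from a master seed (kept below 2^31).
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 7919 + index * 104729) %% 2147483647)
}
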