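## Synthetic endoscopy generator. Emulates flexible nasopharyngoscopy frames
## at desk scale: a dark glottal aperture on pink tissue texture, corrupted in
## "poor" frames by motion blur, secretion-like occlusion, or off-target
## (lumen) content. Ground truth (frame quality, glottis mask, referral
## grade) is known by construction, so every downstream stage can be tested
## without any clinical data. All randomness derives from a single master
## seed.

#' Scene parameters for the synthetic generator
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: 128x128 frames, a glottis covering ~4% of the frame, a subtle
#' lesion (25% peak channel shift) for referral-positive patients, motion
#' blur of 3-8 px, secretion blobs covering ~35% of the frame, and 60% of
#' frames usable. See the methods vignette for the rationale behind each
#' value.
#'
#' @param image_size integer `c(H, W)`.
#' @param glottis_area_fraction target mask area as a fraction of the frame,
#'   in `(0, 0.3]`.
#' @param lesion_strength contrast of the lesion texture painted adjacent to
#'   the glottis on good frames of referral-positive patients (grade 3
#'   patients get 1.5x); 0 removes the disease signal entirely.
#' @param blur_sigma_range `c(lo, hi)` Gaussian blur sigma (pixels) for
#'   blurred poor frames.
#' @param occlusion_fraction fraction of the frame covered by the
#'   secretion-like blob in occluded poor frames, in `[0, 1]`.
#' @param offtarget_probability probability that a poor frame is off-target
#'   (no glottis at all); remaining poor frames split evenly between blur and
#'   occlusion.
#' @param good_frame_fraction fraction of frames rendered sharp and fully
#'   informative, in `(0, 1]`.
#' @param tissue_tone_sd per-patient standard deviation of the tissue colour
#'   (anatomical variation; independent of the referral grade).
#' @param noise_sd per-pixel sensor noise standard deviation.
#' @param seed master integer seed.
#' @return object of class `scene_params`.
#' @export
scene_params <- function(image_size = c(128, 128),
                         glottis_area_fraction = 0.04,
                         lesion_strength = 0.25,
                         blur_sigma_range = c(3, 8),
                         occlusion_fraction = 0.35,
                         offtarget_probability = 0.3,
                         good_frame_fraction = 0.6,
                         tissue_tone_sd = 0.06,
                         noise_sd = 0.05,
                         seed = 1L) {
  stopifnot(length(image_size) == 2, all(image_size >= 32))
  if (glottis_area_fraction <= 0 || glottis_area_fraction > 0.3)
    err("glottis_area_fraction must lie in (0, 0.3]",
        "endoscreen_argument_error")
  if (lesion_strength < 0)
    err("lesion_strength must be >= 0", "endoscreen_argument_error")
  if (length(blur_sigma_range) != 2 || blur_sigma_range[1] > blur_sigma_range[2]
      || blur_sigma_range[1] <= 0)
    err("blur_sigma_range must be an increasing positive pair",
        "endoscreen_argument_error")
  if (occlusion_fraction < 0 || occlusion_fraction > 1)
    err("occlusion_fraction must lie in [0, 1]", "endoscreen_argument_error")
  if (offtarget_probability < 0 || offtarget_probability > 1)
    err("offtarget_probability must lie in [0, 1]",
        "endoscreen_argument_error")
  if (good_frame_fraction <= 0 || good_frame_fraction > 1)
    err("good_frame_fraction must lie in (0, 1]", "endoscreen_argument_error")
  structure(list(image_size = as.integer(image_size),
                 glottis_area_fraction = glottis_area_fraction,
                 lesion_strength = lesion_strength,
                 blur_sigma_range = blur_sigma_range,
                 occlusion_fraction = occlusion_fraction,
                 offtarget_probability = offtarget_probability,
                 good_frame_fraction = good_frame_fraction,
                 tissue_tone_sd = tissue_tone_sd,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_params")
}

## coordinate grids (row = y, col = x), cached per size within a call
coord_grids <- function(H, W) {
  list(y = matrix(seq_len(H), H, W), x = matrix(seq_len(W), H, W, byrow = TRUE))
}

## Low-frequency tissue texture: two octaves of coarse noise, upsampled.
## An optional persistent base (the patient's anatomy) is mixed with fresh
## per-frame variation, giving consecutive frames of one video a shared
## layout the way a steady endoscopic view does.
texture_base <- function() {
  list(g1 = matrix(stats::rnorm(64), 8, 8),
       g2 = matrix(stats::rnorm(256), 16, 16))
}

texture_field <- function(H, W, base = NULL, persistence = 0.75) {
  fresh <- texture_base()
  if (!is.null(base)) {
    fresh$g1 <- persistence * base$g1 + (1 - persistence) * fresh$g1
    fresh$g2 <- persistence * base$g2 + (1 - persistence) * fresh$g2
  }
  0.6 * resize_hw(fresh$g1, c(H, W)) + 0.4 * resize_hw(fresh$g2, c(H, W))
}

render_tissue <- function(H, W, tone, base = NULL) {
  tex <- texture_field(H, W, base)
  grid <- coord_grids(H, W)
  r2 <- ((grid$y - H / 2) / H)^2 + ((grid$x - W / 2) / W)^2
  vig <- 1 - 0.35 * r2 / 0.5
  px <- array(0, c(H, W, 3))
  wts <- c(0.9, 1.0, 0.8) # texture couples mostly to the green channel
  for (c in 1:3) px[, , c] <- (tone[c] + 0.06 * wts[c] * tex) * vig
  px
}

## Glottal aperture: ellipse fused with a tapering triangle (anterior
## commissure), rotated and jittered. Returns the binary mask.
glottis_mask <- function(H, W, area, center, elong, angle) {
  a <- sqrt(area * elong / pi)
  b <- sqrt(area / (pi * elong))
  grid <- coord_grids(H, W)
  dy <- grid$y - center[1]
  dx <- grid$x - center[2]
  u <- cos(angle) * dy + sin(angle) * dx
  v <- -sin(angle) * dy + cos(angle) * dx
  ell <- (u / a)^2 + (v / b)^2 <= 1
  tri_w <- 0.7 * b * (u + 1.4 * a) / (1.4 * a)
  tri <- u >= -1.4 * a & u <= 0 & abs(v) <= tri_w
  m <- ell | tri
  matrix(as.integer(m), H, W)
}

## Smooth irregular blob (for lesions and secretion occlusions).
blob_mask <- function(H, W, center, radius, wobble = 0.2, elong = 1) {
  grid <- coord_grids(H, W)
  dy <- (grid$y - center[1]) * sqrt(elong)
  dx <- (grid$x - center[2]) / sqrt(elong)
  r <- sqrt(dy^2 + dx^2)
  phi <- atan2(dy, dx)
  phase <- stats::runif(1, 0, 2 * pi)
  rad <- radius * (1 + wobble * sin(3 * phi + phase))
  matrix(as.integer(r <= rad), H, W)
}

## Paint a soft-edged overlay: px <- px * (1 - alpha) + colour * alpha
composite <- function(px, alpha, colour) {
  for (c in 1:3) px[, , c] <- px[, , c] * (1 - alpha) + colour[c] * alpha
  px
}

## Draw the per-video anchor geometry: where the glottis sits and how the
## lesion is placed relative to it. Individual frames jitter around this
## anchor (camera and tissue motion), which is what makes frames of one
## video mutually similar.
draw_anchor <- function(params) {
  H <- params$image_size[1]; W <- params$image_size[2]
  area <- params$glottis_area_fraction * H * W * stats::runif(1, 0.8, 1.2)
  elong <- stats::runif(1, 2, 3)
  a <- sqrt(area * elong / pi)
  margin <- 1.6 * a + 4
  list(area = area, elong = elong,
       angle = stats::rnorm(1, 0, 10 * pi / 180),
       center = c(stats::runif(1, margin, H - margin),
                  stats::runif(1, margin, W - margin)),
       margin = margin,
       lesion_side = sample(c(-1, 1), 1),
       texture = texture_base())
}

## One sharp glottis-bearing scene around an anchor. Returns pixels plus the
## ground-truth mask.
render_glottis_scene <- function(params, tone, with_lesion, lesion_mult,
                                 anchor = NULL) {
  H <- params$image_size[1]; W <- params$image_size[2]
  if (is.null(anchor)) anchor <- draw_anchor(params)
  px <- render_tissue(H, W, tone, anchor$texture)
  area <- anchor$area * stats::runif(1, 0.9, 1.1)
  elong <- anchor$elong
  angle <- anchor$angle + stats::rnorm(1, 0, 3 * pi / 180)
  center <- anchor$center + stats::rnorm(2, 0, 3)
  center <- pmin(pmax(center, anchor$margin), c(H, W) - anchor$margin)
  mask <- glottis_mask(H, W, area, center, elong, angle)
  alpha <- pmin(blur_hw(mask + 0, 1) * 1.4, 1)
  ## slightly brightened fold ring around the aperture
  ring <- pmax(blur_hw(mask + 0, 4) - alpha, 0)
  px <- composite(px, 0.5 * ring, c(0.9, 0.62, 0.58))
  depth <- 0.10 + 0.05 * stats::runif(1)
  px <- composite(px, alpha, c(depth, depth * 0.8, depth * 0.85))
  ## lesion randomness is drawn unconditionally so that the RNG stream (and
  ## hence every other pixel) is identical across referral grades; only the
  ## painting is conditional
  a <- sqrt(area * elong / pi)
  b <- sqrt(area / (pi * elong))
  rl <- sqrt(0.5 * area / pi)
  off_u <- -0.3 * a
  off_v <- anchor$lesion_side * (b + 0.9 * rl)
  lc <- c(center[1] + cos(angle) * off_u - sin(angle) * off_v,
          center[2] + sin(angle) * off_u + cos(angle) * off_v)
  lm <- blob_mask(H, W, lc, rl, wobble = 0.25)
  speck <- matrix(stats::rnorm(H * W, 0, 0.3), H, W)
  if (with_lesion) {
    la <- pmin(blur_hw(lm + 0, 1.5) * 1.3, 1)
    strength <- params$lesion_strength * lesion_mult
    shift <- c(0.30, -0.12, -0.10)
    for (c in 1:3)
      px[, , c] <- px[, , c] + strength * la * (shift[c] + 0.2 * speck)
  }
  list(pixels = px, mask = mask, center = center, area = area)
}

## Off-target scene: dark lumen with a specular highlight, no glottis.
render_offtarget_scene <- function(params, tone) {
  H <- params$image_size[1]; W <- params$image_size[2]
  px <- array(0, c(H, W, 3))
  tex <- texture_field(H, W)
  dark <- tone * 0.22
  for (c in 1:3) px[, , c] <- dark[c] + 0.03 * tex
  hc <- c(stats::runif(1, 0.2 * H, 0.8 * H), stats::runif(1, 0.2 * W, 0.8 * W))
  hl <- blob_mask(H, W, hc, sqrt(0.01 * H * W / pi), wobble = 0.3)
  ha <- pmin(blur_hw(hl + 0, 2) * 1.5, 1)
  composite(px, 0.9 * ha, c(1, 0.98, 0.9))
}

add_noise <- function(px, sd) {
  px + array(stats::rnorm(length(px), 0, sd), dim(px))
}

clip01 <- function(px) pmin(pmax(px, 0), 1)

#' Generate one synthetic patient video
#'
#' Good frames contain a sharp, fully-in-frame glottis; poor frames are
#' blurred, occluded by a secretion-like blob, or off-target. The realised
#' number of good frames is exactly `round(good_frame_fraction * n_frames)`.
#' The lesion texture (referral grade >= 2) is painted only on good frames:
#' blur and obscuration destroy its usefulness, so degraded frames carry no
#' disease signal. Output is fully determined by `params$seed` and
#' `patient_id`.
#'
#' @param params a [scene_params()].
#' @param patient_id identifier.
#' @param n_frames number of frames, `>= 1`.
#' @param referral_grade 1, 2 or 3.
#' @param tone optional tissue tone (3-vector); drawn per patient otherwise.
#' @return list with `video` (a [video_record()]), `quality` (logical, TRUE =
#'   good), `masks` (list of [segmentation_mask()], empty mask for off-target
#'   frames) and `degradation` (`"none"`, `"blur"`, `"occlusion"` or
#'   `"offtarget"`).
#' @export
generate_video <- function(params, patient_id, n_frames, referral_grade,
                           tone = NULL) {
  if (n_frames < 1) err("n_frames must be >= 1", "endoscreen_argument_error")
  pid_hash <- sum(utf8ToInt(as.character(patient_id)))
  with_seed(derive_seed(params$seed, pid_hash), {
    H <- params$image_size[1]; W <- params$image_size[2]
    if (is.null(tone))
      tone <- pmin(pmax(c(0.72, 0.45, 0.42) +
                          stats::rnorm(3, 0, params$tissue_tone_sd), 0.1), 0.95)
    n_good <- round(params$good_frame_fraction * n_frames)
    good <- rep(FALSE, n_frames)
    good[sample.int(n_frames, n_good)] <- TRUE
    degradation <- rep("none", n_frames)
    poor_idx <- which(!good)
    if (length(poor_idx) > 0) {
      u <- stats::runif(length(poor_idx))
      degradation[poor_idx] <- ifelse(
        u < params$offtarget_probability, "offtarget",
        ifelse(stats::runif(length(poor_idx)) < 0.5, "blur", "occlusion"))
    }
    lesion_mult <- if (referral_grade == 3) 1.5 else 1
    with_lesion <- referral_grade >= 2 && params$lesion_strength > 0
    anchor <- draw_anchor(params)
    frames <- vector("list", n_frames)
    masks <- vector("list", n_frames)
    empty <- matrix(0L, H, W)
    for (i in seq_len(n_frames)) {
      kind <- degradation[i]
      if (kind == "offtarget") {
        px <- add_noise(render_offtarget_scene(params, tone), params$noise_sd)
        masks[[i]] <- segmentation_mask(empty, patient_id, i - 1L)
      } else {
        sc <- render_glottis_scene(params, tone,
                                   with_lesion && kind == "none", lesion_mult,
                                   anchor)
        px <- sc$pixels
        if (kind == "blur") {
          sigma <- stats::runif(1, params$blur_sigma_range[1],
                                params$blur_sigma_range[2])
          px <- blur_hw(add_noise(px, params$noise_sd), sigma)
        } else if (kind == "occlusion") {
          occ_r <- sqrt(params$occlusion_fraction * H * W / pi)
          oc <- sc$center + stats::rnorm(2, 0, 4)
          om <- blob_mask(H, W, oc, occ_r, wobble = 0.3,
                          elong = stats::runif(1, 1, 1.6))
          oa <- pmin(blur_hw(om + 0, 5) * 1.2, 0.9)
          px <- add_noise(composite(px, oa, c(0.95, 0.92, 0.78)),
                          params$noise_sd)
        } else {
          px <- add_noise(px, params$noise_sd)
        }
        masks[[i]] <- segmentation_mask(sc$mask, patient_id, i - 1L)
      }
      frames[[i]] <- frame_record(patient_id, i - 1L, clip01(px))
    }
    list(video = video_record(patient_id, frames, referral_grade),
         quality = good, masks = masks, degradation = degradation)
  })
}

#' Generate a synthetic cohort
#'
#' `round(positive_fraction * n_patients)` patients receive referral grade 2
#' or 3 (split evenly, remainder to grade 2); the rest are grade 1. Grade
#' order is shuffled deterministically from the master seed and per-patient
#' seeds are derived from it, so the whole cohort is a pure function of
#' `params$seed`.
#'
#' @param params a [scene_params()].
#' @param n_patients number of patients, `>= 2`.
#' @param positive_fraction fraction of referral-positive patients in
#'   `(0, 1)`.
#' @param frames_per_patient frames per video.
#' @return object of class `synthetic_cohort`: lists `videos`, `quality`,
#'   `masks`, `degradation` indexed by patient, plus a `grades` vector.
#' @export
generate_cohort <- function(params, n_patients = 40, positive_fraction = 0.7,
                            frames_per_patient = 100) {
  if (n_patients < 2) err("n_patients must be >= 2",
                          "endoscreen_argument_error")
  if (positive_fraction <= 0 || positive_fraction >= 1)
    err("positive_fraction must lie in (0, 1)", "endoscreen_argument_error")
  n_pos <- round(positive_fraction * n_patients)
  n_g2 <- ceiling(n_pos / 2)
  grades <- c(rep(1L, n_patients - n_pos), rep(2L, n_g2),
              rep(3L, n_pos - n_g2))
  grades <- with_seed(derive_seed(params$seed, 0L),
                      grades[sample.int(n_patients)])
  ids <- sprintf("P%03d", seq_len(n_patients))
  videos <- vector("list", n_patients)
  quality <- vector("list", n_patients)
  masks <- vector("list", n_patients)
  degradation <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    pp <- params
    pp$seed <- derive_seed(params$seed, i)
    g <- generate_video(pp, ids[i], frames_per_patient, grades[i])
    videos[[i]] <- g$video
    quality[[i]] <- g$quality
    masks[[i]] <- g$masks
    degradation[[i]] <- g$degradation
  }
  names(videos) <- names(quality) <- names(masks) <- names(degradation) <- ids
  structure(list(videos = videos, quality = quality, masks = masks,
                 degradation = degradation, grades = stats::setNames(grades, ids),
                 params = params),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n <- length(x$videos)
  npos <- sum(x$grades >= 2)
  nf <- sum(vapply(x$videos, function(v) length(v$frames), integer(1)))
  cat(sprintf(
    "<synthetic_cohort> %d patients (%d referral-positive), %d frames\n",
    n, npos, nf))
  invisible(x)
}

#' Generate an image/mask training set for the glottis segmenter
#'
#' Emits sharp, fully visible glottis scenes with their exact binary masks —
#' the synthetic counterpart of an open glottis-segmentation benchmark. Each
#' pair draws its own tissue tone so the segmenter generalises across
#' patients.
#'
#' @param params a [scene_params()].
#' @param n number of pairs, `>= 1`.
#' @return list of `list(frame = frame_record, mask = segmentation_mask)`.
#' @export
generate_segmentation_set <- function(params, n) {
  if (n < 1) err("n must be >= 1", "endoscreen_argument_error")
  lapply(seq_len(n), function(i) {
    with_seed(derive_seed(params$seed, 500000L + i), {
      tone <- pmin(pmax(c(0.72, 0.45, 0.42) +
                          stats::rnorm(3, 0, params$tissue_tone_sd), 0.1),
                   0.95)
      sc <- render_glottis_scene(params, tone, FALSE, 1)
      px <- clip01(add_noise(sc$pixels, params$noise_sd))
      list(frame = frame_record(sprintf("S%05d", i), 0L, px),
           mask = segmentation_mask(sc$mask, sprintf("S%05d", i), 0L))
    })
  })
}

#' Write a synthetic cohort to disk
#'
#' Writes per-patient frame PNGs, ground-truth mask PNGs, a quality-truth CSV
#' and a dataset manifest (`manifest.csv`) referencing the frames.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param write_masks also write the ground-truth masks.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_masks = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  truth <- list()
  for (pid in names(cohort$videos)) {
    vid <- cohort$videos[[pid]]
    pdir <- file.path(dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    if (write_masks)
      dir.create(file.path(dir, "masks", pid), recursive = TRUE,
                 showWarnings = FALSE)
    for (k in seq_along(vid$frames)) {
      fr <- vid$frames[[k]]
      rel <- file.path(pid, sprintf("frame_%04d.png", fr$frame_index))
      write_image(fr$pixels, file.path(dir, rel))
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = pid, frame_path = rel, frame_index = fr$frame_index,
        referral_grade = vid$referral_grade, stringsAsFactors = FALSE)
      truth[[length(truth) + 1]] <- data.frame(
        patient_id = pid, frame_index = fr$frame_index,
        good = as.integer(cohort$quality[[pid]][k]),
        degradation = cohort$degradation[[pid]][k], stringsAsFactors = FALSE)
      if (write_masks)
        write_image(cohort$masks[[pid]][[k]]$pixels,
                    file.path(dir, "masks", rel))
    }
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  utils::write.csv(do.call(rbind, truth), file.path(dir, "quality_truth.csv"),
                   row.names = FALSE)
  invisible(path)
}

## Flatten a cohort into training arrays: frames (H, W, 3, N) at an optional
## target size, plus per-frame metadata.
cohort_frame_table <- function(cohort, target = NULL) {
  n_total <- sum(vapply(cohort$videos, function(v) length(v$frames),
                        integer(1)))
  d <- dim(cohort$videos[[1]]$frames[[1]]$pixels)
  sz <- if (is.null(target)) d[1:2] else target
  x <- array(0, c(sz[1], sz[2], 3, n_total))
  pid <- character(n_total)
  fidx <- integer(n_total)
  good <- logical(n_total)
  label <- integer(n_total)
  k <- 0L
  for (p in names(cohort$videos)) {
    vid <- cohort$videos[[p]]
    for (j in seq_along(vid$frames)) {
      k <- k + 1L
      px <- vid$frames[[j]]$pixels
      if (!is.null(target)) px <- resize_hw(px, target)
      x[, , , k] <- px
      pid[k] <- p
      fidx[k] <- vid$frames[[j]]$frame_index
      good[k] <- cohort$quality[[p]][j]
      label[k] <- vid$binary_label
    }
  }
  list(x = x, patient_id = pid, frame_index = fidx, good = good,
       label = label)
}
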