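## Domain types and dataset plumbing: single frames, per-patient videos,
## binary glottis masks, and the CSV manifest that ties frame files to
## patients and referral grades.

#' A single video frame
#'
#' @param patient_id opaque identifier (coerced to character).
#' @param frame_index non-negative integer giving the temporal order within
#'   the patient's video.
#' @param pixels `(H, W, 3)` array of intensities in `[0, 1]`; grayscale
#'   matrices are channel-replicated.
#' @return object of class `frame_record`.
#' @export
frame_record <- function(patient_id, frame_index, pixels) {
  pixels <- to_rgb(pixels)
  d <- dim(pixels)
  if (d[1] < 32 || d[2] < 32)
    err("frames must be at least 32x32", "endoscreen_validation_error")
  if (min(pixels) < 0 || max(pixels) > 1)
    err("pixel intensities must lie in [0, 1]", "endoscreen_validation_error")
  if (frame_index < 0 || frame_index != round(frame_index))
    err("frame_index must be a non-negative integer",
        "endoscreen_validation_error")
  structure(list(patient_id = as.character(patient_id),
                 frame_index = as.integer(frame_index),
                 pixels = pixels),
            class = "frame_record")
}

#' An ordered per-patient frame sequence with its referral grade
#'
#' Referral grades follow the three-level triage convention: grade 1 needs no
#' referral, grade 2 a non-urgent referral, grade 3 an urgent referral. The
#' derived `binary_label` is 0 for grade 1 and 1 for grades 2-3.
#'
#' @param patient_id identifier shared by all frames.
#' @param frames list of [frame_record()]s (any order; sorted by
#'   `frame_index`).
#' @param referral_grade integer in `{1, 2, 3}`.
#' @return object of class `video_record`.
#' @export
video_record <- function(patient_id, frames, referral_grade) {
  if (length(frames) == 0)
    err("a video needs at least one frame", "endoscreen_validation_error")
  if (!referral_grade %in% 1:3)
    err("referral_grade must be 1, 2 or 3", "endoscreen_validation_error")
  idx <- vapply(frames, function(f) f$frame_index, integer(1))
  if (anyDuplicated(idx))
    err("duplicate frame_index within a patient",
        "endoscreen_validation_error")
  pid <- as.character(patient_id)
  ok <- vapply(frames, function(f) f$patient_id == pid, logical(1))
  if (!all(ok))
    err("all frames must belong to the same patient",
        "endoscreen_validation_error")
  structure(list(patient_id = pid,
                 frames = frames[order(idx)],
                 referral_grade = as.integer(referral_grade),
                 binary_label = as.integer(referral_grade >= 2)),
            class = "video_record")
}

#' @export
print.video_record <- function(x, ...) {
  cat(sprintf("<video_record> patient %s: %d frames, grade %d (label %d)\n",
              x$patient_id, length(x$frames), x$referral_grade,
              x$binary_label))
  invisible(x)
}

#' A binary glottis segmentation mask aligned to a frame
#'
#' @param pixels `(H, W)` matrix; values are binarised at 0.5.
#' @param patient_id,frame_index optional linkage to a frame.
#' @return object of class `segmentation_mask` with values in `{0, 1}`.
#' @export
segmentation_mask <- function(pixels, patient_id = NULL, frame_index = NULL) {
  if (length(dim(pixels)) == 3) pixels <- pixels[, , 1]
  m <- matrix(as.integer(pixels >= 0.5), nrow(pixels), ncol(pixels))
  structure(list(pixels = m,
                 patient_id = if (is.null(patient_id)) NULL else
                   as.character(patient_id),
                 frame_index = if (is.null(frame_index)) NULL else
                   as.integer(frame_index)),
            class = "segmentation_mask")
}

#' Area fraction of a mask (mask pixels / frame pixels)
#' @param mask a [segmentation_mask()].
#' @return real in `[0, 1]`.
#' @export
mask_area_fraction <- function(mask) {
  mean(mask$pixels)
}

#' Dice overlap of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b [segmentation_mask()]s or binary matrices of equal size.
#' @return real in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  pa <- if (inherits(a, "segmentation_mask")) a$pixels else a
  pb <- if (inherits(b, "segmentation_mask")) b$pixels else b
  if (!identical(dim(pa), dim(pb)))
    err("masks must have equal dimensions", "endoscreen_validation_error")
  sa <- sum(pa); sb <- sum(pb)
  if (sa + sb == 0) return(1)
  2 * sum(pa * pb) / (sa + sb)
}

## ---- manifest --------------------------------------------------------------

MANIFEST_COLS <- c("patient_id", "frame_path", "frame_index", "referral_grade")

validate_manifest <- function(df, base_dir, check_files = TRUE) {
  missing_cols <- setdiff(MANIFEST_COLS, names(df))
  if (length(missing_cols) > 0)
    err(paste0("manifest is missing column(s): ",
               paste(missing_cols, collapse = ", ")),
        "endoscreen_schema_error")
  bad <- which(!df$referral_grade %in% 1:3)
  if (length(bad) > 0)
    err(paste0("referral_grade outside {1,2,3} in manifest row(s) ",
               paste(utils::head(bad, 5), collapse = ", ")),
        "endoscreen_validation_error")
  key <- paste(df$patient_id, df$frame_index)
  if (anyDuplicated(key))
    err("duplicate (patient_id, frame_index) in manifest",
        "endoscreen_validation_error")
  if (check_files) {
    paths <- file.path(base_dir, df$frame_path)
    missing_files <- !file.exists(paths)
    if (any(missing_files))
      err(paste0("manifest references missing file(s), e.g. ",
                 paths[which(missing_files)[1]]),
          "endoscreen_io_error")
  }
  df$patient_id <- as.character(df$patient_id)
  df$frame_index <- as.integer(df$frame_index)
  df$referral_grade <- as.integer(df$referral_grade)
  structure(df, base_dir = base_dir,
            class = c("dataset_manifest", "data.frame"))
}

#' Read a dataset manifest
#'
#' A manifest is a UTF-8 CSV with columns `patient_id`, `frame_path`,
#' `frame_index`, `referral_grade` and optionally `quality_label`; frame
#' paths are interpreted relative to the manifest's directory. Row order is
#' preserved.
#'
#' @param path CSV file path.
#' @param check_files verify that every referenced frame file exists.
#' @return a `dataset_manifest` (a validated data frame with a `base_dir`
#'   attribute).
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path))
    err(paste0("manifest not found: ", path), "endoscreen_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("patient_id" %in% names(df))
    df$patient_id <- as.character(df$patient_id)
  validate_manifest(df, base_dir = dirname(path), check_files = check_files)
}

#' Write a dataset manifest
#' @param manifest a `dataset_manifest` or conforming data frame.
#' @param path output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

#' Build a manifest from an in-memory data frame
#' @param df data frame with the manifest columns.
#' @param base_dir directory that frame paths are relative to.
#' @param check_files verify file existence.
#' @return a `dataset_manifest`.
#' @export
as_manifest <- function(df, base_dir = ".", check_files = FALSE) {
  validate_manifest(as.data.frame(df), base_dir, check_files = check_files)
}

#' Load one patient's video from a manifest
#'
#' Frames are decoded to RGB in `[0, 1]` and returned sorted by
#' `frame_index`, independent of the manifest's row order.
#'
#' @param manifest a `dataset_manifest`.
#' @param patient_id patient to load.
#' @return a [video_record()].
#' @export
load_video <- function(manifest, patient_id) {
  rows <- manifest[manifest$patient_id == as.character(patient_id), ,
                   drop = FALSE]
  if (nrow(rows) == 0)
    err(paste0("unknown patient_id: ", patient_id), "endoscreen_lookup_error")
  grade <- unique(rows$referral_grade)
  if (length(grade) != 1)
    err(paste0("inconsistent referral_grade for patient ", patient_id),
        "endoscreen_validation_error")
  base_dir <- attr(manifest, "base_dir")
  if (is.null(base_dir)) base_dir <- "."
  frames <- lapply(seq_len(nrow(rows)), function(i) {
    frame_record(rows$patient_id[i], rows$frame_index[i],
                 read_image(file.path(base_dir, rows$frame_path[i])))
  })
  video_record(patient_id, frames, grade)
}

#' Load paired images and segmentation masks from a directory
#'
#' The pairing convention mirrors common glottis-segmentation benchmarks:
#' `<name>.png` is the frame, `<name><mask_suffix>.png` its binary mask.
#' Masks are binarised at 0.5 and must match the frame dimensions.
#'
#' @param dir directory containing the pairs.
#' @param mask_suffix filename suffix identifying masks (default `"_seg"`).
#' @return list of `list(frame = frame_record, mask = segmentation_mask)`.
#' @export
load_mask_pairs <- function(dir, mask_suffix = "_seg") {
  files <- list.files(dir, pattern = "\\.png$", full.names = FALSE)
  is_mask <- grepl(paste0(mask_suffix, "\\.png$"), files)
  imgs <- files[!is_mask]
  if (length(imgs) == 0)
    err(paste0("no image files in ", dir), "endoscreen_io_error")
  lapply(imgs, function(f) {
    stem <- sub("\\.png$", "", f)
    mask_file <- file.path(dir, paste0(stem, mask_suffix, ".png"))
    if (!file.exists(mask_file))
      err(paste0("no mask for image ", f), "endoscreen_pairing_error")
    px <- read_image(file.path(dir, f))
    mk <- png::readPNG(mask_file)
    if (length(dim(mk)) == 3) mk <- mk[, , 1]
    if (!identical(dim(mk), dim(px)[1:2]))
      err(paste0("mask dimensions differ from image for ", f),
          "endoscreen_validation_error")
    list(frame = frame_record(stem, 0L, px),
         mask = segmentation_mask(mk))
  })
}

## Stack a list of frame_records (or a video_record) into a (H, W, 3, N)
## array, optionally resized.
frames_to_batch <- function(frames, target = NULL) {
  if (inherits(frames, "video_record")) frames <- frames$frames
  n <- length(frames)
  d <- dim(frames[[1]]$pixels)
  x <- array(0, c(d[1], d[2], 3, n))
  for (i in seq_len(n)) x[, , , i] <- frames[[i]]$pixels
  if (!is.null(target)) x <- resize_batch(x, target)
  x
}
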