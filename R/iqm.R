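## Stage 2b of the image quality module: a supervised frame-quality
## classifier trained on (weak) good/poor labels, plus quality scoring and
## the frame-budget selection rule used by the disease classifier.

#' Train the frame-quality classifier
#'
#' @param x `(H, W, 3, N)` array of frames (resized to `spec$input_size`).
#' @param labels per-frame quality labels: `"good"`/`"poor"`, logical, or
#'   0/1 with 1 = good.
#' @param patient_ids per-frame patient ids; training data must not share
#'   patients with `test_patients`.
#' @param spec an [arch_spec()]; the quality task trains well at reduced
#'   input sizes and widths.
#' @param test_patients optional ids reserved for evaluation; overlap raises
#'   a leakage error.
#' @param epochs,batch_size,lr,seed,augment training schedule.
#' @param normalize apply per-frame channel-mean normalisation
#'   ([normalize_frames()]); stored on the model and re-applied at
#'   prediction time.
#' @return a trained `endo_classifier` whose positive class is "good".
#' @export
train_iqm <- function(x, labels, patient_ids = NULL,
                      spec = arch_spec("baseline_cnn", input_size = c(64, 64),
                                       width_multiplier = 0.25),
                      test_patients = NULL, epochs = 3, batch_size = 32,
                      lr = 1e-3, seed = 0L, augment = FALSE,
                      normalize = TRUE) {
  y <- quality_to_binary(labels)
  if (length(unique(y)) < 2)
    err("both quality classes must be present", "endoscreen_training_error")
  if (!is.null(patient_ids) && !is.null(test_patients) &&
      length(intersect(unique(patient_ids), test_patients)) > 0)
    err("training frames share patients with the test set",
        "endoscreen_leakage_error")
  x <- resize_batch(x, spec$input_size)
  set.seed(seed)
  model <- build_classifier(spec)
  fit <- nn_train_classifier(model$graph, x, y + 1L, epochs = epochs,
                             batch_size = batch_size, lr = lr,
                             augment = augment, normalize = normalize)
  model$graph <- fit$graph
  model$history <- fit$history
  model$trained <- TRUE
  model$normalize <- normalize
  model$classes <- c("poor", "good")
  model
}

quality_to_binary <- function(labels) {
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("good", "poor"))
    if (length(bad) > 0) err("quality labels must be 'good' or 'poor'",
                             "endoscreen_argument_error")
    as.integer(labels == "good")
  } else as.integer(as.logical(labels))
}

#' Quality score (probability of "good") for frames
#'
#' @param model a trained [train_iqm()] classifier.
#' @param frames a [frame_record()], an `(H, W, 3)` array, or an
#'   `(H, W, 3, N)` batch.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
score_quality <- function(model, frames) {
  if (!inherits(model, "endo_classifier") || !isTRUE(model$trained))
    err("model is not a trained classifier", "endoscreen_state_error")
  px <- if (inherits(frames, "frame_record")) frames$pixels else frames
  probs <- predict(model, px)
  probs[2, ]
}

#' Select frames by quality score
#'
#' Frames scoring at least `threshold` are ranked by descending score (ties
#' broken by ascending frame index) and truncated to `max_n`. A video whose
#' selection falls below `min_frames` is flagged excluded — the analogue of
#' dropping videos with insufficient good-quality frames.
#'
#' @param scores per-frame quality scores.
#' @param threshold minimum score.
#' @param max_n frame budget (`Inf` = all frames above threshold).
#' @param min_frames exclusion minimum.
#' @param frame_index optional frame indices used for the tie-break and in
#'   the returned selection (defaults to positions).
#' @return object of class `frame_selection`: `indices` (positions into
#'   `scores`, in rank order), `frame_index`, `excluded`, `scores`.
#' @export
select_frames <- function(scores, threshold = 0.5, max_n = Inf,
                          min_frames = 10,
                          frame_index = seq_along(scores)) {
  keep <- which(scores >= threshold)
  ord <- keep[order(-scores[keep], frame_index[keep])]
  if (is.finite(max_n)) ord <- utils::head(ord, max_n)
  structure(list(indices = ord,
                 frame_index = frame_index[ord],
                 excluded = length(ord) < min_frames,
                 scores = scores),
            class = "frame_selection")
}

#' @export
print.frame_selection <- function(x, ...) {
  cat(sprintf("<frame_selection> %d frames retained%s\n", length(x$indices),
              if (x$excluded) " (video EXCLUDED: below minimum)" else ""))
  invisible(x)
}
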