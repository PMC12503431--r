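## Disease classification module: a frame-level binary referral classifier
## whose per-frame probabilities are averaged ("bagged") into a patient-level
## referral probability, plus the frame-budget ablation harness.

#' Focal-loss parameters
#'
#' Binary focal cross-entropy `-alpha * (1 - p_t)^gamma * log(p_t)` on the
#' true-class probability; `gamma = 0`, `alpha = 1` (or `enabled = FALSE`)
#' recovers plain cross-entropy.
#'
#' @param gamma focusing exponent `>= 0`.
#' @param alpha scale in `(0, 1]`.
#' @param enabled use the focal form during training.
#' @return object of class `focal_loss_params`.
#' @export
focal_loss_params <- function(gamma = 2, alpha = 0.25, enabled = TRUE) {
  if (gamma < 0) err("gamma must be >= 0", "endoscreen_argument_error")
  if (alpha <= 0 || alpha > 1)
    err("alpha must lie in (0, 1]", "endoscreen_argument_error")
  structure(list(gamma = gamma, alpha = alpha, enabled = isTRUE(enabled)),
            class = "focal_loss_params")
}

#' Train the frame-level referral classifier
#'
#' Frames inherit their patient's binary referral label (grade 1 = 0, grades
#' 2-3 = 1). Training refuses data that would leak patients into a declared
#' test set.
#'
#' @param x `(H, W, 3, N)` frame array.
#' @param labels per-frame binary labels (0/1).
#' @param patient_ids per-frame patient ids.
#' @param spec an [arch_spec()].
#' @param loss a [focal_loss_params()].
#' @param augment horizontal flips + brightness jitter during training.
#' @param test_patients optional ids reserved for evaluation; overlap raises
#'   a leakage error.
#' @param epochs,batch_size,lr,seed training schedule.
#' @param normalize apply per-frame channel-mean normalisation
#'   ([normalize_frames()]), removing the patient-specific tissue tone so the
#'   classifier must rely on local lesion contrast; stored on the model and
#'   re-applied at prediction time.
#' @return a trained `endo_classifier` whose positive class is "referral".
#' @export
train_dcm <- function(x, labels, patient_ids,
                      spec = arch_spec("baseline_cnn", input_size = c(32, 32),
                                       width_multiplier = 0.25),
                      loss = focal_loss_params(), augment = FALSE,
                      test_patients = NULL, epochs = 3, batch_size = 32,
                      lr = 1e-3, seed = 0L, normalize = TRUE) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2)
    err("both referral classes must be present in training data",
        "endoscreen_training_error")
  tab <- table(unique(data.frame(p = patient_ids, y = y))$y)
  if (length(tab) < 2 || any(tab < 2))
    err("need at least 2 patients per class", "endoscreen_training_error")
  if (!is.null(test_patients) &&
      length(intersect(unique(patient_ids), test_patients)) > 0)
    err("training frames share patients with the test set",
        "endoscreen_leakage_error")
  x <- resize_batch(x, spec$input_size)
  gamma <- if (loss$enabled) loss$gamma else 0
  alpha <- if (loss$enabled) loss$alpha else 1
  set.seed(seed)
  model <- build_classifier(spec)
  fit <- nn_train_classifier(model$graph, x, y + 1L, epochs = epochs,
                             batch_size = batch_size, lr = lr, gamma = gamma,
                             alpha = alpha, augment = augment,
                             normalize = normalize)
  model$graph <- fit$graph
  model$history <- fit$history
  model$trained <- TRUE
  model$normalize <- normalize
  model$classes <- c("non-referral", "referral")
  model
}

#' Patient-level referral prediction by probability averaging
#'
#' Scores the selected frames of one patient's video and aggregates by the
#' arithmetic mean of the frame probabilities; the patient is predicted
#' "referral" when the aggregate reaches `threshold`. An empty selection
#' yields an excluded (not failed) result.
#'
#' @param model a trained [train_dcm()] classifier.
#' @param video a [video_record()] or an `(H, W, 3, N)` frame array.
#' @param selection a [select_frames()] result, a vector of frame positions,
#'   or `NULL` for all frames.
#' @param threshold decision threshold on the aggregate probability.
#' @return object of class `patient_prediction` with `frame_probabilities`,
#'   `aggregate_probability`, `predicted_label` and `excluded`.
#' @export
predict_patient <- function(model, video, selection = NULL, threshold = 0.5) {
  if (!inherits(model, "endo_classifier") || !isTRUE(model$trained))
    err("model is not a trained classifier", "endoscreen_state_error")
  pid <- if (inherits(video, "video_record")) video$patient_id else NA_character_
  x <- if (inherits(video, "video_record")) frames_to_batch(video) else video
  take <- if (is.null(selection)) seq_len(dim(x)[4]) else
    if (inherits(selection, "frame_selection")) selection$indices else
      as.integer(selection)
  if (length(take) == 0) {
    return(structure(list(patient_id = pid,
                          frame_probabilities = numeric(0),
                          aggregate_probability = NA_real_,
                          predicted_label = NA_integer_, excluded = TRUE),
                     class = "patient_prediction"))
  }
  probs <- predict(model, x[, , , take, drop = FALSE])[2, ]
  agg <- mean(probs)
  structure(list(patient_id = pid, frame_probabilities = probs,
                 aggregate_probability = agg,
                 predicted_label = as.integer(agg >= threshold),
                 excluded = FALSE),
            class = "patient_prediction")
}

#' @export
print.patient_prediction <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf("<patient_prediction> %s: EXCLUDED (no usable frames)\n",
                x$patient_id))
  } else {
    cat(sprintf(
      "<patient_prediction> %s: aggregate %.3f over %d frames -> label %d\n",
      x$patient_id, x$aggregate_probability, length(x$frame_probabilities),
      x$predicted_label))
  }
  invisible(x)
}

## ---- ablation harness ------------------------------------------------------

#' Frame-budget ablation experiment
#'
#' Trains and evaluates the disease classifier under a list of conditions:
#' without quality filtering (`NA`), and with the quality module selecting at
#' most n frames per patient (`Inf` = all frames scored good). For every
#' seed the cohort is split at the patient level, a quality classifier is
#' fitted on the training patients, frames are selected per condition, the
#' referral classifier is trained on the selected training frames, and
#' patient-level metrics are computed on the held-out patients.
#'
#' @param cohort a [generate_cohort()] result.
#' @param conditions numeric vector; `NA` = no quality filtering, otherwise
#'   the per-patient frame budget (`Inf` = unlimited).
#' @param seeds integer vector; one full split/train/eval cycle per seed.
#' @param iqm_spec,dcm_spec [arch_spec()]s for the two classifiers.
#' @param iqm_labels `"truth"` trains the quality classifier on the
#'   generator's quality ground truth (isolates the ablation from labeling
#'   noise); `"weak"` first fits a U-Net on `n_seg_pairs` synthetic pairs and
#'   uses its weak labels, i.e. the full pipeline.
#' @param loss,augment forwarded to [train_dcm()].
#' @param test_fraction held-out patient fraction.
#' @param iqm_frames_per_patient training-frame cap per patient for the
#'   quality classifier.
#' @param epochs_iqm,epochs_dcm,lr training schedule; `epochs_dcm` is the
#'   minimum epoch count — small frame budgets train for more epochs so that
#'   every condition receives a comparable number of optimisation steps
#'   (`passes_target` image-passes, capped at `max_epochs_dcm` epochs).
#' @param passes_target,max_epochs_dcm optimisation budget per condition.
#' @param min_frames exclusion minimum for [select_frames()].
#' @param n_seg_pairs U-Net training pairs when `iqm_labels = "weak"`.
#' @param threshold quality-score threshold.
#' @param frame_tables optional precomputed frame tables
#'   `list(iqm = , dcm = )` (as built by the internal cohort flattener at the
#'   two input sizes); avoids re-flattening a large cohort.
#' @param verbose print progress.
#' @return data frame of class `ablation_result`: one row per (condition,
#'   seed) with patient-level accuracy, weighted F1, AUROC, AUPRC; the
#'   condition means are attached as attribute `"summary"`.
#' @export
run_experiment <- function(cohort, conditions = c(NA, 10, 30, 50, Inf),
                           seeds = 1:5,
                           iqm_spec = arch_spec("baseline_cnn",
                                                input_size = c(64, 64),
                                                width_multiplier = 0.25),
                           dcm_spec = arch_spec("baseline_cnn",
                                                input_size = c(32, 32),
                                                width_multiplier = 0.25),
                           iqm_labels = c("truth", "weak"),
                           loss = focal_loss_params(gamma = 2, alpha = 1),
                           augment = TRUE,
                           test_fraction = 0.2,
                           iqm_frames_per_patient = 25,
                           epochs_iqm = 3, epochs_dcm = 2, lr = 2e-3,
                           passes_target = 6000, max_epochs_dcm = 12,
                           min_frames = 10, n_seg_pairs = 300,
                           threshold = 0.5, frame_tables = NULL,
                           verbose = FALSE) {
  iqm_labels <- match.arg(iqm_labels)
  if (length(cohort$videos) < 20)
    err("need at least 20 patients for stable splits",
        "endoscreen_argument_error")
  ids <- names(cohort$videos)
  plabels <- vapply(cohort$videos, function(v) v$binary_label, integer(1))
  ft_iqm <- if (is.null(frame_tables)) {
    cohort_frame_table(cohort, target = iqm_spec$input_size)
  } else frame_tables$iqm
  ft_dcm <- if (is.null(frame_tables)) {
    cohort_frame_table(cohort, target = dcm_spec$input_size)
  } else frame_tables$dcm
  qlab <- ft_iqm$good
  if (iqm_labels == "weak") {
    segs <- generate_segmentation_set(cohort$params, n_seg_pairs)
    un <- train_unet(segs, seed = cohort$params$seed)
    wl <- weak_label_dataset(un, cohort$videos)
    key <- paste(wl$patient_id, wl$frame_index)
    ours <- paste(ft_iqm$patient_id, ft_iqm$frame_index)
    qlab <- wl$quality_label[match(ours, key)] == "good"
  }
  rows <- list()
  for (s in seq_along(seeds)) {
    seed <- seeds[s]
    split <- patient_split(ids, plabels, test_fraction = test_fraction,
                           seed = derive_seed(seed, 17L))
    in_train <- ft_iqm$patient_id %in% split$train
    ## cap quality-training frames per patient
    take_iqm <- with_seed(derive_seed(seed, 29L), {
      unlist(lapply(split$train, function(p) {
        w <- which(ft_iqm$patient_id == p)
        if (length(w) > iqm_frames_per_patient)
          sort(sample(w, iqm_frames_per_patient)) else w
      }))
    })
    ep_iqm <- min(max(epochs_iqm, ceiling(2000 / length(take_iqm))), 10)
    iqm <- train_iqm(ft_iqm$x[, , , take_iqm, drop = FALSE],
                     qlab[take_iqm], ft_iqm$patient_id[take_iqm],
                     spec = iqm_spec, test_patients = split$test,
                     epochs = ep_iqm, lr = lr,
                     seed = derive_seed(seed, 31L))
    scores <- score_quality(iqm, ft_iqm$x)
    for (cond in conditions) {
      cond_name <- if (is.na(cond)) "none" else
        if (is.infinite(cond)) "unlimited" else as.character(cond)
      sel_idx <- function(pids) {
        unlist(lapply(pids, function(p) {
          w <- which(ft_dcm$patient_id == p)
          if (is.na(cond)) return(w)
          sel <- select_frames(scores[w], threshold = threshold,
                               max_n = cond, min_frames = min_frames,
                               frame_index = ft_dcm$frame_index[w])
          if (sel$excluded) integer(0) else w[sel$indices]
        }))
      }
      tr <- sel_idx(split$train)
      ep <- min(max(epochs_dcm, ceiling(passes_target / length(tr))),
                max_epochs_dcm)
      dcm <- train_dcm(ft_dcm$x[, , , tr, drop = FALSE], ft_dcm$label[tr],
                       ft_dcm$patient_id[tr], spec = dcm_spec, loss = loss,
                       augment = augment, test_patients = split$test,
                       epochs = ep, lr = lr,
                       seed = derive_seed(seed, 37L))
      agg <- vapply(split$test, function(p) {
        w <- which(ft_dcm$patient_id == p)
        take <- if (is.na(cond)) w else {
          sel <- select_frames(scores[w], threshold = threshold,
                               max_n = cond, min_frames = min_frames,
                               frame_index = ft_dcm$frame_index[w])
          if (sel$excluded) integer(0) else w[sel$indices]
        }
        if (length(take) == 0) return(NA_real_)
        mean(predict(dcm, ft_dcm$x[, , , take, drop = FALSE])[2, ])
      }, numeric(1))
      keep <- !is.na(agg)
      mr <- metrics_report(plabels[split$test][keep], agg[keep],
                           level = "patient")
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond_name, seed = seed, accuracy = mr$accuracy,
        weighted_f1 = mr$weighted_f1, auroc = mr$auroc, auprc = mr$auprc,
        n_test_patients = sum(keep), n_excluded = sum(!keep),
        n_train_frames = length(tr), stringsAsFactors = FALSE)
      if (verbose)
        message(sprintf("seed %d  %-9s  AUROC %.3f  AUPRC %.3f", seed,
                        cond_name, mr$auroc, mr$auprc))
    }
  }
  res <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "weighted_f1", "auroc", "auprc")
  summ <- stats::aggregate(res[metric_cols], by = list(condition = res$condition),
                           FUN = mean)
  cond_names <- vapply(conditions, function(cond)
    if (is.na(cond)) "none" else if (is.infinite(cond)) "unlimited" else
      as.character(cond), character(1))
  ord <- match(cond_names, summ$condition)
  attr(res, "summary") <- summ[ord[!is.na(ord)], ]
  class(res) <- c("ablation_result", "data.frame")
  res
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("Frame-budget ablation (patient-level metrics, mean over seeds):\n")
  print.data.frame(attr(x, "summary"), row.names = FALSE, digits = 3)
  invisible(x)
}
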