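# Shared fixtures, built in code. Small scene sizes keep module tests fast;
# the acceptance suite uses the full default study conditions.

small_params <- function(seed = 1L, ...) {
  scene_params(image_size = c(64, 64), seed = seed, ...)
}

# memoised tiny cohort shared by several tests
.fixture_env <- new.env()

tiny_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(small_params(seed = 42L),
                                           n_patients = 8,
                                           positive_fraction = 0.5,
                                           frames_per_patient = 12)
  }
  .fixture_env$cohort
}

# a flat mid-gray frame
flat_frame <- function(h = 64, w = 64, value = 0.5) {
  array(value, c(h, w, 3))
}

# frame whose intensity steps at a horizontal boundary (gradients at 90 deg)
hstep_frame <- function(h = 64, w = 64) {
  g <- matrix(0.2, h, w)
  g[(h %/% 2):h, ] <- 0.8
  array(rep(g, 3), c(h, w, 3))
}

# brute-force AUROC: pairwise concordance with half credit for ties
bf_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# brute-force average precision via an explicit threshold sweep
bf_auprc <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  np <- sum(labels == 1)
  ap <- 0
  rec_prev <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / np
    ap <- ap + (rec - rec_prev) * prec
    rec_prev <- rec
  }
  ap
}

# brute-force weighted F1 from the confusion counts
bf_weighted_f1 <- function(labels, predictions) {
  out <- 0
  for (cl in unique(labels)) {
    tp <- sum(labels == cl & predictions == cl)
    fp <- sum(labels != cl & predictions == cl)
    fn <- sum(labels == cl & predictions != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    out <- out + f1 * mean(labels == cl)
  }
  out
}
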