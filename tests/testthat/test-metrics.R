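test_that("worked examples of all four metrics are exact", {
  expect_equal(accuracy(c(0, 0, 1, 1), c(0, 1, 1, 1)), 0.75)
  expect_equal(accuracy(c(0, 1), c(0, 1)), 1)
  expect_equal(accuracy(c(0, 1), c(1, 0)), 0)

  expect_equal(weighted_f1(c(1, 1, 0, 0), c(1, 1, 1, 1)), 1 / 3)
  expect_equal(weighted_f1(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)

  # positives scored (0.9, 0.4), negatives (0.5, 0.1)
  lab <- c(1, 1, 0, 0); sc <- c(0.9, 0.4, 0.5, 0.1)
  expect_equal(auroc(lab, sc), 0.75)
  expect_equal(auprc(lab, sc), 1 * 0.5 + 2 / 3 * 0.5)
  expect_equal(auroc(c(1, 1, 0), c(3, 2, 1)), 1)
  expect_equal(auroc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_equal(auprc(c(1, 1, 1, 0, 0, 0), c(9, 8, 7, 3, 2, 1)), 1)
  # all scores tied: average precision equals prevalence
  expect_equal(auprc(c(1, 0, 0, 1), rep(1, 4)), 0.5)
})

test_that("metrics match brute-force oracles on random instances", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    # mix of tied and continuous scores
    scores <- if (i %% 3 == 0) sample(seq(0, 1, 0.25), n, replace = TRUE)
              else runif(n)
    preds <- as.integer(scores >= 0.5)
    expect_equal(auroc(labels, scores), bf_auroc(labels, scores),
                 tolerance = 1e-9)
    expect_equal(auprc(labels, scores), bf_auprc(labels, scores),
                 tolerance = 1e-9)
    expect_equal(weighted_f1(labels, preds), bf_weighted_f1(labels, preds),
                 tolerance = 1e-9)
    expect_equal(accuracy(labels, preds), mean(labels == preds),
                 tolerance = 1e-9)
  }
})

test_that("AUROC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (i in 1:20) {
    labels <- c(rbinom(15, 1, 0.5), 0, 1)
    scores <- round(runif(17), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auroc(labels, scores), ref, tolerance = 1e-9)
  }
})

test_that("ranking metrics are invariant under monotone score transforms", {
  set.seed(31)
  labels <- c(rbinom(30, 1, 0.4), 0, 1)
  scores <- runif(32)
  for (f in list(function(s) 3 * s + 2, function(s) exp(s),
                 function(s) atan(s))) {
    expect_equal(auroc(labels, f(scores)), auroc(labels, scores))
    expect_equal(auprc(labels, f(scores)), auprc(labels, scores))
  }
  # complement identity for tie-free scores
  expect_equal(auroc(labels, scores) + auroc(labels, -scores), 1)
})

test_that("weighted F1 is invariant to consistent class relabeling", {
  set.seed(41)
  labels <- rbinom(20, 1, 0.5); labels[1:2] <- c(0, 1)
  preds <- rbinom(20, 1, 0.5)
  expect_equal(weighted_f1(labels, preds),
               weighted_f1(1 - labels, 1 - preds))
})

test_that("degenerate-metric inputs raise instead of returning a value", {
  expect_error(auroc(c(1, 1), c(0.2, 0.3)), class = "endoscreen_metric_error")
  expect_error(auprc(c(0, 0), c(0.2, 0.3)), class = "endoscreen_metric_error")
  expect_error(accuracy(1:3, 1:2), class = "endoscreen_argument_error")
})

test_that("patient split is disjoint, exhaustive, deterministic and sized", {
  ids <- sprintf("P%03d", 1:10)
  labs <- rep(c(0, 1), 5)
  s1 <- patient_split(ids, labs, 0.2, seed = 5)
  s2 <- patient_split(ids, labs, 0.2, seed = 5)
  expect_identical(s1, s2)
  expect_length(s1$test, 2)
  expect_length(s1$train, 8)
  expect_length(intersect(s1$train, s1$test), 0)
  expect_setequal(c(s1$train, s1$test), ids)
  # the cohort size of the clinical study: 116 patients at 20% -> 23 held out
  ids2 <- sprintf("Q%03d", 1:116)
  labs2 <- c(rep(0, 34), rep(1, 82))
  s3 <- patient_split(ids2, labs2, 0.2, seed = 1)
  expect_length(s3$test, 23)
  expect_length(s3$train, 93)
  # stratification keeps at least one test patient per class
  expect_true(all(table(labs2[ids2 %in% s3$test]) >= 1))
})

test_that("metrics_report bundles all four metrics consistently", {
  lab <- c(1, 1, 0, 0); sc <- c(0.9, 0.4, 0.5, 0.1)
  mr <- metrics_report(lab, sc, level = "patient")
  expect_s3_class(mr, "metrics_report")
  expect_equal(mr$auroc, 0.75)
  expect_equal(mr$accuracy, accuracy(lab, as.integer(sc >= 0.5)))
  expect_equal(mr$n_samples, 4)
  expect_equal(mr$level, "patient")
})
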