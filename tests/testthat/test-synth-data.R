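test_that("generation is a pure function of the seed", {
  p <- small_params(seed = 9)
  a <- generate_video(p, "D1", 10, 2)
  b <- generate_video(p, "D1", 10, 2)
  expect_identical(a$quality, b$quality)
  for (i in c(1, 5, 10))
    expect_identical(a$video$frames[[i]]$pixels, b$video$frames[[i]]$pixels)
  # a different seed changes the pixels
  c <- generate_video(small_params(seed = 10), "D1", 10, 2)
  expect_false(identical(a$video$frames[[1]]$pixels,
                         c$video$frames[[1]]$pixels))
})

test_that("good-frame counting follows the rounding rule exactly", {
  p <- small_params(seed = 2, good_frame_fraction = 0.4)
  g <- generate_video(p, "D2", 100, 1)
  expect_equal(sum(g$quality), 40)
  # degenerate settings: everything good, all masks non-empty
  p1 <- small_params(seed = 3, good_frame_fraction = 1,
                     offtarget_probability = 0)
  g1 <- generate_video(p1, "D3", 8, 1)
  expect_true(all(g1$quality))
  expect_true(all(vapply(g1$masks, function(m) sum(m$pixels) > 0,
                         logical(1))))
  expect_error(generate_video(p1, "D4", 0, 1),
               class = "endoscreen_argument_error")
})

test_that("good frames carry a fully-in-frame glottis; off-target ones none", {
  g <- generate_video(small_params(seed = 4), "D5", 30, 1)
  for (i in seq_along(g$quality)) {
    m <- g$masks[[i]]$pixels
    if (g$quality[i]) {
      expect_gt(sum(m), 0)
      border <- sum(m[1:2, ]) + sum(m[63:64, ]) + sum(m[, 1:2]) +
        sum(m[, 63:64])
      expect_equal(border, 0) # entirely visible: clear of the frame edge
    }
    if (g$degradation[i] == "offtarget") expect_equal(sum(m), 0)
  }
})

test_that("cohort grade assignment follows the rounding/split rules", {
  co <- generate_cohort(small_params(seed = 6), n_patients = 10,
                        positive_fraction = 0.7, frames_per_patient = 4)
  expect_equal(sum(co$grades >= 2), 7)
  expect_equal(sum(co$grades == 2), 4) # remainder goes to grade 2
  expect_equal(sum(co$grades == 3), 3)
  expect_equal(sum(co$grades == 1), 3)
  co2 <- generate_cohort(small_params(seed = 6), n_patients = 10,
                         positive_fraction = 0.7, frames_per_patient = 4)
  expect_identical(co$grades, co2$grades)
  expect_identical(co$videos[["P004"]]$frames[[2]]$pixels,
                   co2$videos[["P004"]]$frames[[2]]$pixels)
  expect_error(generate_cohort(small_params(), 10, 1.2, 4),
               class = "endoscreen_argument_error")
  expect_error(generate_cohort(small_params(), 1, 0.5, 4),
               class = "endoscreen_argument_error")
})

test_that("segmentation pairs honour the target mask area within +-50%", {
  p <- small_params(seed = 12)
  pairs <- generate_segmentation_set(p, 30)
  expect_length(pairs, 30)
  af <- vapply(pairs, function(pr) mask_area_fraction(pr$mask), numeric(1))
  expect_true(all(af > 0))
  expect_true(all(af >= 0.5 * p$glottis_area_fraction))
  expect_true(all(af <= 1.5 * p$glottis_area_fraction))
  pairs2 <- generate_segmentation_set(p, 30)
  expect_identical(pairs[[7]]$frame$pixels, pairs2[[7]]$frame$pixels)
})

test_that("sharpness statistic recovers the generator's blur truth", {
  # generator fidelity: variance of the Laplacian must separate sharp from
  # blurred frames cleanly under default parameters
  lv_good <- c(); lv_blur <- c()
  for (seed in 1:3) {
    g <- generate_video(scene_params(seed = seed), sprintf("L%d", seed),
                        40, 1)
    lv <- vapply(g$video$frames, function(f) laplacian_variance(f$pixels),
                 numeric(1))
    lv_good <- c(lv_good, lv[g$quality])
    lv_blur <- c(lv_blur, lv[g$degradation == "blur"])
  }
  lab <- c(rep(1, length(lv_good)), rep(0, length(lv_blur)))
  expect_gte(auroc(lab, c(lv_good, lv_blur)), 0.95)
})

test_that("the lesion marks exactly the good frames of positive patients", {
  # same patient id and seed, differing only in grade: the frame-by-frame
  # difference isolates the lesion texture
  p <- small_params(seed = 20, lesion_strength = 0.4)
  pos <- generate_video(p, "E1", 20, 2)
  neg <- generate_video(p, "E1", 20, 1)
  expect_identical(pos$quality, neg$quality)
  for (i in seq_along(pos$quality)) {
    dred <- sum(abs(pos$video$frames[[i]]$pixels[, , 1] -
                      neg$video$frames[[i]]$pixels[, , 1]))
    if (pos$quality[i]) {
      expect_gt(dred, 1) # lesion present on every good frame
    } else {
      expect_equal(dred, 0) # degraded frames carry no disease signal
    }
  }
  # grade 3 paints a stronger lesion than grade 2 (1.5x contrast)
  g3 <- generate_video(p, "E1", 20, 3)
  i <- which(pos$quality)[1]
  d2 <- sum(abs(pos$video$frames[[i]]$pixels - neg$video$frames[[i]]$pixels))
  d3 <- sum(abs(g3$video$frames[[i]]$pixels - neg$video$frames[[i]]$pixels))
  expect_gt(d3, d2)
  # zero lesion strength removes the signal entirely
  p0 <- small_params(seed = 20, lesion_strength = 0)
  z2 <- generate_video(p0, "E1", 10, 2)
  z1 <- generate_video(p0, "E1", 10, 1)
  expect_identical(z2$video$frames[[1]]$pixels, z1$video$frames[[1]]$pixels)
})

test_that("a cohort written to disk round-trips through the manifest", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(small_params(seed = 15), n_patients = 3,
                        positive_fraction = 0.5, frames_per_patient = 4)
  path <- write_cohort(co, dir)
  m <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(m), 12)
  v <- load_video(m, "P002")
  expect_equal(length(v$frames), 4)
  expect_equal(v$referral_grade, unname(co$grades["P002"]))
  # pixels survive the 8-bit PNG round trip to within quantisation
  expect_equal(v$frames[[1]]$pixels, co$videos[["P002"]]$frames[[1]]$pixels,
               tolerance = 1 / 255)
  expect_true(file.exists(file.path(dir, "quality_truth.csv")))
})
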