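test_that("HOG descriptor has the expected length and zero/edge behaviour", {
  # defaults: 224x224, 8-px cells, 2x2 blocks, 9 bins -> 27*27*4*9
  d <- compute_hog(flat_frame(224, 224))
  expect_length(d, 27 * 27 * 2 * 2 * 9)
  expect_true(all(d == 0)) # constant frame: no gradients anywhere

  # gradients of a horizontal intensity step point at 90 degrees
  hp <- hog_params(resize_to = c(64, 64))
  d2 <- compute_hog(hstep_frame(64, 64), hp)
  cells <- matrix(d2, nrow = 9)
  bin_energy <- rowSums(cells^2)
  # 90 deg falls in the bin centred at 90 (bin 5 of 9, 20-deg bins)
  expect_gt(bin_energy[5] / sum(bin_energy), 0.9)
})

test_that("HOG is invariant to adding a constant and bounded per block", {
  set.seed(7)
  px <- array(runif(64 * 64 * 3, 0.2, 0.7), c(64, 64, 3))
  hp <- hog_params(resize_to = c(64, 64))
  expect_equal(compute_hog(px, hp), compute_hog(px + 0.2, hp),
               tolerance = 1e-10)
  d <- compute_hog(px, hp)
  blocks <- matrix(d, nrow = 2 * 2 * 9)
  expect_true(all(sqrt(colSums(blocks^2)) <= 1 + 1e-8))
  expect_true(all(d >= 0))
})

test_that("cosine similarity matches hand computations and its properties", {
  expect_equal(cosine_similarity(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(cosine_similarity(c(1, 0, 1), c(0, 1, 0)), 0)
  expect_equal(cosine_similarity(c(1, 0, 1), c(1, 1, 0)), 0.5)
  expect_equal(cosine_similarity(c(0, 0), c(1, 1)), 0) # zero-norm convention
  expect_error(cosine_similarity(1:3, 1:4), class = "endoscreen_argument_error")
  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(10); b <- rnorm(10); c <- runif(1, 0.1, 5)
    expect_equal(cosine_similarity(a, b), cosine_similarity(b, a))
    expect_equal(cosine_similarity(a, c * b), cosine_similarity(a, b))
    expect_lte(abs(cosine_similarity(a, b)), 1 + 1e-12)
  }
})

test_that("similarity filter retains the index frame and drops duplicates", {
  px <- array(runif(64 * 64 * 3), c(64, 64, 3))
  frames <- replicate(10, px, simplify = FALSE)
  hp <- hog_params(resize_to = c(64, 64))
  # identical frames: everything after the index is a near-duplicate
  r <- similarity_filter(frames, hp, filter_params(tau_dup = 0.98))
  expect_equal(as.integer(r), 1L)
  # permissive thresholds retain everything
  r2 <- similarity_filter(frames, hp,
                          filter_params(tau_rel = -1, tau_dup = 1))
  expect_equal(as.integer(r2), 1:10)
  expect_error(similarity_filter(list(), hp, filter_params()),
               class = "endoscreen_argument_error")
  expect_error(similarity_filter(frames, hp, filter_params(index_frame = 11)),
               class = "endoscreen_argument_error")
})

test_that("retained set is a deterministic subsequence, monotone in tau_rel", {
  g <- generate_video(small_params(seed = 5), "H1", 16, 1)
  hp <- hog_params(resize_to = c(64, 64), epsilon = 0.1, smooth_sigma = 1)
  taus <- c(-1, 0.2, 0.5, 0.8)
  sizes <- integer(0)
  for (tau in taus) {
    fp <- filter_params(tau_rel = tau, tau_dup = 1)
    r1 <- similarity_filter(g$video, hp, fp)
    r2 <- similarity_filter(g$video, hp, fp)
    expect_identical(as.integer(r1), as.integer(r2)) # deterministic
    expect_true(all(diff(r1) > 0))                    # strictly increasing
    expect_true(all(r1 %in% seq_along(g$video$frames)))
    sizes <- c(sizes, length(r1))
  }
  expect_true(all(diff(sizes) <= 0)) # non-increasing in tau_rel
})

test_that("relevance filtering separates glottis frames from pure noise", {
  # videos of 20 anchored glottis frames + 20 pure-noise frames; at
  # tau_rel = 0.5 the retained set should be glottis-only and nearly complete
  hp <- hog_params(resize_to = c(64, 64), epsilon = 0.1, smooth_sigma = 1)
  fp <- filter_params(tau_rel = 0.5, tau_dup = 1)
  for (seed in 1:5) {
    g <- generate_video(scene_params(seed = seed,
                                     good_frame_fraction = 1), "N1", 20, 1)
    noise <- lapply(1:20, function(i) {
      set.seed(1000 * seed + i)
      array(runif(128 * 128 * 3), c(128, 128, 3))
    })
    frames <- c(lapply(g$video$frames, function(f) f$pixels), noise)
    r <- as.integer(similarity_filter(frames, hp, fp))
    expect_true(all(r <= 20))      # nothing off-target survives
    expect_gte(length(r), 0.8 * 20) # most glottis frames retained
  }
})
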