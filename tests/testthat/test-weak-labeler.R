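test_that("visibility criteria implement the area and border rules", {
  crit <- visibility_criteria(min_area_fraction = 0.002, border_margin = 2)
  h <- 100; w <- 100
  empty <- segmentation_mask(matrix(0, h, w))
  expect_equal(assign_quality_label(empty, crit), "poor")
  # centred disc covering ~5% of the frame, clear of the margin
  grid <- expand.grid(r = 1:h, c = 1:w)
  disc <- matrix(as.integer((grid$r - 50)^2 + (grid$c - 50)^2 <= 12.6^2),
                 h, w)
  expect_equal(assign_quality_label(segmentation_mask(disc), crit), "good")
  # same disc translated to touch the left edge: no longer entirely visible
  shifted <- matrix(0L, h, w)
  shifted[, 1:(w - 48)] <- disc[, 49:w]
  expect_equal(assign_quality_label(segmentation_mask(shifted), crit),
               "poor")
  # monotone in the area criterion: removing pixels never flips poor -> good
  small <- disc
  small[disc == 1][1:(sum(disc) - 10)] <- 0L
  expect_equal(assign_quality_label(segmentation_mask(small), crit), "poor")
})

test_that("untrained models are rejected and shapes are preserved", {
  fake <- structure(list(trained = FALSE), class = "unet_model")
  fr <- frame_record("p", 0, flat_frame(96, 96))
  expect_error(predict_mask(fake, fr), class = "endoscreen_state_error")
  expect_error(weak_label_dataset(fake, list()),
               class = "endoscreen_state_error")
  expect_error(train_unet(list()), class = "endoscreen_argument_error")
})

test_that("a briefly trained U-Net segments sharp synthetic glottis frames", {
  p <- small_params(seed = 30)
  pairs <- generate_segmentation_set(p, 110)
  un <- train_unet(pairs[1:100], unet_spec(depth = 3, base_channels = 8,
                                           input_size = c(64, 64)),
                   epochs = 6, seed = 0)
  expect_true(un$trained)
  expect_lt(tail(un$history, 1), un$history[1]) # loss decreased
  # prediction contract: binary mask at the frame's own resolution
  pm <- predict_mask(un, pairs[[105]]$frame)
  expect_equal(dim(pm$pixels), dim(pairs[[105]]$frame$pixels)[1:2])
  expect_true(all(pm$pixels %in% c(0L, 1L)))
  # training is reproducible under a fixed seed
  una <- train_unet(pairs[1:15], unet_spec(depth = 2, base_channels = 4,
                                           input_size = c(32, 32)),
                    epochs = 1, seed = 5)
  unb <- train_unet(pairs[1:15], unet_spec(depth = 2, base_channels = 4,
                                           input_size = c(32, 32)),
                    epochs = 1, seed = 5)
  expect_equal(una$history, unb$history, tolerance = 1e-12)
  # held-out overlap is already well above chance after six short epochs
  dc <- vapply(101:110, function(i)
    dice_coefficient(predict_mask(un, pairs[[i]]$frame), pairs[[i]]$mask),
    numeric(1))
  expect_gt(mean(dc), 0.5)
})

test_that("weak labelling covers every frame and reports counts", {
  p <- small_params(seed = 31)
  pairs <- generate_segmentation_set(p, 50)
  un <- train_unet(pairs, unet_spec(depth = 3, base_channels = 8,
                                    input_size = c(64, 64)),
                   epochs = 2, seed = 0)
  g <- generate_video(p, "W1", 12, 1)
  wl <- weak_label_dataset(un, list(g$video))
  expect_equal(nrow(wl), 12)
  expect_true(all(wl$quality_label %in% c("good", "poor")))
  expect_equal(sum(attr(wl, "summary")), 12)
  expect_equal(attr(wl, "provenance"), "weak")
  # vacuous case
  wl0 <- weak_label_dataset(un, list())
  expect_equal(nrow(wl0), 0)
})

test_that("dice is a proper overlap score for training masks", {
  m <- matrix(0L, 64, 64); m[20:40, 25:35] <- 1L
  expect_equal(dice_coefficient(m, m), 1)
  expect_equal(dice_coefficient(m, matrix(0L, 64, 64)), 0)
})
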