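make_disk_video <- function(dir, pid = "P001", n = 3, grade = 2,
                            shuffle = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(n) - 1L, function(i) {
    rel <- sprintf("%s_f%02d.png", pid, i)
    write_image(array(runif(32 * 32 * 3), c(32, 32, 3)), file.path(dir, rel))
    data.frame(patient_id = pid, frame_path = rel, frame_index = i,
               referral_grade = grade, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (shuffle) df <- df[rev(seq_len(nrow(df))), ]
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

test_that("manifest round-trip is the identity on all fields", {
  dir <- withr::local_tempdir()
  path <- make_disk_video(dir, n = 3)
  m <- read_manifest(path)
  expect_equal(nrow(m), 3)
  out <- file.path(dir, "copy.csv")
  write_manifest(m, out)
  m2 <- read_manifest(out)
  expect_equal(as.data.frame(m), as.data.frame(m2))
})

test_that("manifest validation errors are specific", {
  dir <- withr::local_tempdir()
  path <- make_disk_video(dir)
  df <- utils::read.csv(path)
  # missing column
  utils::write.csv(df[, -1], file.path(dir, "bad1.csv"), row.names = FALSE)
  expect_error(read_manifest(file.path(dir, "bad1.csv")),
               class = "endoscreen_schema_error")
  # grade outside {1,2,3}
  df2 <- df; df2$referral_grade[2] <- 4
  utils::write.csv(df2, file.path(dir, "bad2.csv"), row.names = FALSE)
  expect_error(read_manifest(file.path(dir, "bad2.csv")),
               class = "endoscreen_validation_error")
  # missing frame file
  df3 <- df; df3$frame_path[1] <- "nope.png"
  utils::write.csv(df3, file.path(dir, "bad3.csv"), row.names = FALSE)
  expect_error(read_manifest(file.path(dir, "bad3.csv")),
               class = "endoscreen_io_error")
  # duplicate (patient, frame) key
  utils::write.csv(rbind(df, df[1, ]), file.path(dir, "bad4.csv"),
                   row.names = FALSE)
  expect_error(read_manifest(file.path(dir, "bad4.csv")),
               class = "endoscreen_validation_error")
})

test_that("load_video derives the binary label and sorts frames", {
  dir <- withr::local_tempdir()
  m1 <- read_manifest(make_disk_video(file.path(dir, "a"), "A", grade = 1))
  v1 <- load_video(m1, "A")
  expect_equal(v1$binary_label, 0L)
  # grades 2 and 3 are both "referral"
  m3 <- read_manifest(make_disk_video(file.path(dir, "b"), "B", grade = 3,
                                      shuffle = TRUE))
  v3 <- load_video(m3, "B")
  expect_equal(v3$binary_label, 1L)
  idx <- vapply(v3$frames, function(f) f$frame_index, integer(1))
  expect_equal(idx, sort(idx))
  expect_error(load_video(m1, "ZZZ"), class = "endoscreen_lookup_error")
  # decoded intensities stay in [0, 1]
  px <- v1$frames[[1]]$pixels
  expect_true(min(px) >= 0 && max(px) <= 1)
})

test_that("frame and video invariants are enforced", {
  expect_error(frame_record("p", 0, array(2, c(32, 32, 3))),
               class = "endoscreen_validation_error")
  expect_error(frame_record("p", 0, array(0.5, c(16, 16, 3))),
               class = "endoscreen_validation_error")
  f0 <- frame_record("p", 0, flat_frame())
  f0b <- frame_record("p", 0, flat_frame())
  expect_error(video_record("p", list(f0, f0b), 2),
               class = "endoscreen_validation_error") # duplicate index
  expect_error(video_record("p", list(), 1),
               class = "endoscreen_validation_error")
  expect_error(video_record("p", list(f0), 5),
               class = "endoscreen_validation_error")
  # grayscale input is channel-replicated
  fg <- frame_record("p", 1, matrix(0.3, 40, 40))
  expect_equal(dim(fg$pixels), c(40, 40, 3))
})

test_that("mask pairs load, binarise and validate dimensions", {
  dir <- withr::local_tempdir()
  for (i in 1:5) {
    write_image(array(runif(32 * 32 * 3), c(32, 32, 3)),
                file.path(dir, sprintf("img%d.png", i)))
    m <- matrix(0, 32, 32); m[10:20, 10:20] <- 1
    write_image(m, file.path(dir, sprintf("img%d_seg.png", i)))
  }
  pairs <- load_mask_pairs(dir)
  expect_length(pairs, 5)
  expect_true(all(vapply(pairs, function(p)
    all(p$mask$pixels %in% c(0L, 1L)), logical(1))))
  expect_gt(sum(pairs[[1]]$mask$pixels), 0)
  # unmatched pair
  write_image(array(0.5, c(32, 32, 3)), file.path(dir, "orphan.png"))
  expect_error(load_mask_pairs(dir), class = "endoscreen_pairing_error")
  file.remove(file.path(dir, "orphan.png"))
  # dimension mismatch
  write_image(array(0.5, c(64, 64, 3)), file.path(dir, "big.png"))
  write_image(matrix(1, 32, 32), file.path(dir, "big_seg.png"))
  expect_error(load_mask_pairs(dir), class = "endoscreen_validation_error")
})

test_that("dice coefficient behaves like an overlap measure", {
  m <- matrix(0L, 20, 20); m[5:10, 5:10] <- 1L
  e <- matrix(0L, 20, 20)
  expect_equal(dice_coefficient(m, m), 1)
  expect_equal(dice_coefficient(m, e), 0)
  expect_equal(dice_coefficient(e, e), 1)
  half <- m; half[5:7, ] <- 0L
  expect_lt(dice_coefficient(m, half), 1)
  expect_gt(dice_coefficient(m, half), 0)
})
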