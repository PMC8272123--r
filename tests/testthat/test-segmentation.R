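test_that("row separator lands in a clean horizontal gap at angle 0", {
  bin <- fixture_two_rows(gap = 28:32)
  sep <- find_row_separator(bin, angle_range = 5, step = 1)
  expect_equal(sep$angle, 0)
  expect_true(sep$index >= 28 && sep$index <= 32)
  expect_equal(sep$score, 0)
})

test_that("row separator matches the brute-force (angle, row) search", {
  for (s in 1:3) {
    bin <- withr::with_seed(s, {
      b <- matrix(0, 64, 64)
      b[4:sample(22:30, 1), 6:58] <- 255
      b[sample(34:42, 1):60, 6:58] <- 255
      # speckle noise to break trivial ties
      flip <- sample(64 * 64, 60)
      b[flip] <- 255 - b[flip]
      b
    })
    got <- find_row_separator(bin, angle_range = 5, step = 1)
    want <- oracle_row_separator(bin, 5, 1)
    expect_equal(got$angle, want$angle)
    expect_equal(got$index, want$index)
    expect_equal(got$score, want$score)
  }
})

test_that("solid image ties resolve to the center-nearest row at full mass", {
  bin <- matrix(255, 21, 30)
  sep <- find_row_separator(bin, angle_range = 2, step = 1)
  expect_equal(sep$angle, 0)
  expect_equal(sep$index, 11)
  expect_equal(sep$score, 30 * 255)
})

test_that("split_rows cuts at the separator and conserves mass", {
  bin <- fixture_two_rows(h = 200, w = 60, gap = 99:103)
  src <- bin / 255 * 180
  sep <- find_row_separator(bin, angle_range = 2, step = 1)
  parts <- split_rows(src, bin, sep)
  expect_equal(nrow(parts$upper) + nrow(parts$lower), 200)
  expect_equal(sum(parts$upper_bin) + sum(parts$lower_bin), sum(bin))
  sep101 <- separator_line(0, 101, 0, "row", c(100.5, 30.5))
  p2 <- split_rows(src, bin, sep101)
  expect_equal(nrow(p2$upper), 100)
  expect_equal(nrow(p2$lower), 100)
  expect_error(split_rows(src, bin, separator_line(0, 1, 0, "row",
                                                   c(100.5, 30.5))),
               "degenerate")
})

test_that("tooth separators find every gap of a multi-tooth row", {
  fx <- fixture_tooth_row(n = 4)
  seps <- find_tooth_separators(fx$bin, angle_range = 3, step = 1,
                                min_tooth_width = 10)
  expect_length(seps, 3)
  idx <- vapply(seps, `[[`, integer(1), "index")
  expect_true(all(idx == sort(idx)))
  for (k in 1:3)
    expect_true(any(idx >= fx$gaps[k, 1] & idx <= fx$gaps[k, 2]))
  expect_true(all(vapply(seps, `[[`, numeric(1), "angle") == 0))
})

test_that("a single-tooth row yields no separators", {
  fx <- fixture_tooth_row(n = 1)
  expect_length(find_tooth_separators(fx$bin, 3, 1, min_tooth_width = 10), 0)
})

test_that("tooth separators still split a rotated row cleanly", {
  # a 5-px gap over ~46 rows admits exact-zero lines across several
  # degrees, so the angle is identifiable only up to atan(gap/height);
  # what must hold is that every cut is a zero-score line through a gap
  fx <- fixture_tooth_row(n = 4, h = 60, w = 140, gap_w = 5)
  rot <- rotate_image(fx$bin, 2, "nearest")
  seps <- find_tooth_separators(rot, angle_range = 5, step = 1,
                                min_tooth_width = 10)
  expect_length(seps, 3)
  feas <- atan(7 / 46) * 180 / pi  # gap width + raster slop over height
  for (s in seps) {
    expect_equal(s$score, 0)
    expect_lte(abs(s$angle + 2), feas + 1)
  }
})

test_that("vertical separating lines make masking a plain crop", {
  img <- matrix(runif(50 * 80, 0, 255), 50, 80)
  left <- separator_line(0, 20, 0, "column", c(25.5, 40.5))
  right <- separator_line(0, 61, 0, "column", c(25.5, 40.5))
  crop <- crop_and_mask(img, left, right)
  expect_equal(crop$bbox[["left"]], 20)
  expect_equal(crop$bbox[["right"]], 61)
  expect_equal(crop$image, img[, 20:61])
  expect_equal(crop$mask_fraction, 0)
})

test_that("oblique masking matches a pointwise half-plane oracle", {
  img <- matrix(100, 20, 10)
  left <- separator_line(10, 4, 0, "column", c(10.5, 5.5))
  crop <- crop_and_mask(img, left, NULL)
  a <- 10 * pi / 180
  for (i in seq_len(nrow(crop$image))) for (j in seq_len(ncol(crop$image))) {
    jj <- j + crop$bbox[["left"]] - 1
    rc <- 5.5 + sin(a) * (i - 10.5) + cos(a) * (jj - 5.5)
    expect_equal(crop$image[i, j], if (rc < 4) 0 else 100)
  }
  expect_gt(crop$mask_fraction, 0)
})

test_that("masking is idempotent and never raises a pixel", {
  img <- matrix(runif(40 * 60, 0, 255), 40, 60)
  left <- separator_line(-6, 12, 0, "column", c(20.5, 30.5))
  right <- separator_line(8, 49, 0, "column", c(20.5, 30.5))
  crop <- crop_and_mask(img, left, right)
  sub <- img[, crop$bbox[["left"]]:crop$bbox[["right"]]]
  expect_true(all(crop$image <= sub))                 # monotone
  kept <- crop$image == sub
  expect_true(all(crop$image[!kept] == 0))            # zeroed outside
  again <- crop_and_mask(crop$image, left = NULL, right = NULL)
  expect_equal(again$image, crop$image)               # no-op without lines
})

test_that("half split follows the odd-width convention and keeps content sided", {
  img <- matrix(0, 30, 101)
  img[5, 90] <- 255  # content in the right half
  crop <- structure(list(image = img, bbox = c(top = 1, left = 1,
                                               bottom = 30, right = 101),
                         left_line = NULL, right_line = NULL, row = "upper",
                         mask_fraction = 0), class = "tooth_crop")
  halves <- split_halves(crop, "bw", 3)
  expect_equal(ncol(halves[[1]]$image), 51)
  expect_equal(ncol(halves[[2]]$image), 50)
  expect_equal(sum(halves[[1]]$image), 0)
  expect_equal(sum(halves[[2]]$image), 255)
  expect_equal(halves[[1]]$side, "left")
  even <- crop; even$image <- img[, 1:100]
  he <- split_halves(structure(even, class = "tooth_crop"))
  expect_equal(ncol(he[[1]]$image), 50)
  expect_equal(ncol(he[[2]]$image), 50)
})

test_that("end-to-end segmentation emits two halves per tooth", {
  gb <- generate_bitewing(scene_spec(teeth_per_row = 8, global_rotation = 0,
                                     seed = 7))
  seg <- segment_bitewing(gb$image, bitewing_id = "bw7")
  expect_equal(length(seg$halves),
               2 * (seg$report$rows$upper$n_teeth +
                      seg$report$rows$lower$n_teeth))
  expect_equal(length(seg$halves), 32)  # 8 upper + 8 lower teeth
  expect_s3_class(seg$halves[[1]], "half_tooth")
  expect_error(segment_bitewing(matrix(0, 50, 50)), "no content")
})

test_that("segmentation is deterministic", {
  gb <- generate_bitewing(scene_spec(teeth_per_row = 5, global_rotation = 4,
                                     seed = 12))
  s1 <- segment_bitewing(gb$image)
  s2 <- segment_bitewing(gb$image)
  expect_identical(s1$report, s2$report)
  expect_identical(lapply(s1$halves, `[[`, "image"),
                   lapply(s2$halves, `[[`, "image"))
})
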