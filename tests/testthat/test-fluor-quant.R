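# Calcium dF/F0, response magnitudes, punctal intensities, normalization.

test_that("dF/F0 is zero for constant traces and cancels background", {
  flat <- dff_trace(rep(110, 20), rep(10, 20))
  expect_true(all(flat$dff == 0))
  # +50 step on F = 100 baseline reads 50%
  roi <- c(rep(110, 10), rep(160, 10))
  stepped <- dff_trace(roi, rep(10, 20))
  expect_equal(stepped$dff, c(rep(0, 10), rep(50, 10)))
  # common offset on roi and bg changes nothing
  shifted <- dff_trace(roi + 500, rep(10, 20) + 500)
  expect_equal(shifted$dff, stepped$dff)
  expect_error(dff_trace(rep(5, 10), rep(10, 10)), "F0")
  expect_error(dff_trace(rep(10, 3), rep(1, 3)), "longer")
})

test_that("response magnitude uses inclusive windows and is symmetric", {
  # 2 fps, step exactly at the 30.5 s frame boundary
  dff <- c(rep(0, 61), rep(50, 39))
  tr <- tibble::tibble(time_s = (0:99) / 2, dff = dff)
  m <- response_magnitude(tr)
  expect_equal(m$pre_mean, 0)
  expect_equal(m$post_mean, 50)
  expect_equal(m$magnitude, 50)
  expect_equal(m$n_pre, 21L)    # frames 40..60 inclusive
  expect_equal(m$n_post, 21L)   # frames 61..81 inclusive
  # swapping windows leaves the magnitude unchanged
  sw <- response_magnitude(tr, pre_window = c(30.5, 40.5),
                           post_window = c(20, 30))
  expect_equal(sw$magnitude, m$magnitude)
  # flat trace: zero
  expect_equal(response_magnitude(rep(3, 100))$magnitude, 0)
  # NA inside a window: mean over available frames, flagged
  tr$dff[45] <- NA
  m2 <- response_magnitude(tr)
  expect_false(m2$complete)
  expect_equal(m2$n_pre, 20L)
  expect_error(response_magnitude(rep(0, 10), pre_window = c(50, 60)),
               "no frame")
})

test_that("cluster intensity sums masks and subtracts the surround minimum", {
  img <- matrix(c(10, 20, 5, 7, 3, 9), nrow = 2)
  expect_equal(cluster_intensity(img, c(1, 2), "raw_sum"), 30)
  # uniform image: k * v raw, 0 after subtracting an equal surround
  uni <- matrix(4, 5, 5)
  expect_equal(cluster_intensity(uni, 1:7, "raw_sum"), 28)
  expect_equal(cluster_intensity(uni, 1:7, "local_min_subtracted",
                                 surround = 8:12), 0)
  # mask {10, 20}, surround minimum 5 -> 5 + 15
  expect_equal(cluster_intensity(img, c(1, 2), "local_min_subtracted",
                                 surround = c(3, 4)), 20)
  # raw sums are additive over disjoint masks; subtraction never exceeds raw
  set.seed(51)
  for (i in 1:50) {
    im <- matrix(runif(100, 0, 50), 10)
    idx <- sample(100, 30)
    m1 <- idx[1:10]; m2 <- idx[11:20]; sur <- idx[21:30]
    expect_equal(cluster_intensity(im, c(m1, m2), "raw_sum"),
                 cluster_intensity(im, m1, "raw_sum") +
                   cluster_intensity(im, m2, "raw_sum"))
    expect_lte(cluster_intensity(im, m1, "local_min_subtracted",
                                 surround = sur),
               cluster_intensity(im, m1, "raw_sum"))
  }
  # mask matrices work too
  mm <- matrix(FALSE, 2, 3); mm[1, 1] <- TRUE; mm[2, 1] <- TRUE
  expect_equal(cluster_intensity(img, mm, "raw_sum"), 30)
  expect_error(cluster_intensity(img, integer(0)), "empty")
  expect_error(cluster_intensity(img, c(1, 2), "local_min_subtracted"),
               "surround")
  expect_error(cluster_intensity(img, c(1, 2), "local_min_subtracted",
                                 surround = c(2, 3)), "disjoint")
})

test_that("TIFF image + label mask pairs round-trip into cluster_intensity", {
  skip_if_not_installed("tiff")
  img <- matrix(seq(0, 1, length.out = 24), 4, 6)
  mask <- matrix(0L, 4, 6)
  mask[2:3, 2:3] <- 1L
  img_path <- tempfile(fileext = ".tif")
  mask_path <- tempfile(fileext = ".tif")
  tiff::writeTIFF(img, img_path, bits.per.sample = 32)
  tiff::writeTIFF(mask / 255, mask_path, bits.per.sample = 8)
  pair <- read_intensity_tiff(img_path, mask_path)
  expect_equal(dim(pair$image), dim(img))
  got <- cluster_intensity(pair$image, pair$mask == 1, "raw_sum")
  expect_equal(got, sum(pair$image[mask == 1]))
})

test_that("same-day reference normalization is a day-scale-free percent", {
  rec <- tibble::tibble(
    worm_id = sprintf("w%d", 1:8),
    condition = c(rep("buffer", 3), rep("butanone", 1),
                  rep("buffer", 3), rep("butanone", 1)),
    sleep_status = "slept",
    timepoint_h = 16,
    assay_day = rep(c("d1", "d2"), each = 4),
    raw_intensity = c(10, 20, 30, 15, 100, 200, 300, 150)
  )
  out <- normalize_intensity(rec)
  expect_equal(out$normalized_pct[1:4], c(50, 100, 150, 75))
  # day 2 is day 1 scaled by 10: identical percentages
  expect_equal(out$normalized_pct[5:8], out$normalized_pct[1:4])
  # reference median itself normalizes to 100
  expect_equal(median(out$normalized_pct[out$condition == "buffer" &
                                           out$assay_day == "d1"]), 100)
  # rank preservation within a day
  expect_equal(order(out$normalized_pct[1:4]), order(rec$raw_intensity[1:4]))
  # a day with no reference animals errors, naming the day
  bad <- dplyr::mutate(rec, condition = replace(condition, 5:7, "butanone"))
  expect_error(normalize_intensity(bad), "d2")
})

test_that("single-worm change calls >= 50% reductions inclusively", {
  expect_false(single_worm_change(100, 100)$reduced)
  expect_equal(single_worm_change(100, 100)$pct, 100)
  half <- single_worm_change(200, 100)
  expect_true(half$reduced)           # boundary inclusive
  expect_equal(half$pct, 50)
  gone <- single_worm_change(80, 0)
  expect_true(gone$reduced)
  expect_equal(gone$pct, 0)
  expect_false(single_worm_change(100, 51)$reduced)
  expect_error(single_worm_change(0, 10), "> 0")
})
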