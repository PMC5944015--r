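px_rgb <- function(h, s, v, nr = 4, nc = 4) {
  tr <- shootgraph:::hsv_to_rgb_triple(h, s, v)
  array(rep(tr, each = nr * nc), dim = c(nr, nc, 3))
}

test_that("hsv_binarize applies the default plant color band", {
  expect_true(all(hsv_binarize(px_rgb(0.33, 0.50, 0.50)) == 1))
  expect_true(all(hsv_binarize(px_rgb(0.33, 1.00, 0.50)) == 0))  # saturation above band
  expect_true(all(hsv_binarize(array(0, dim = c(4, 4, 3))) == 0))  # black never set
})

test_that("hsv_binarize is idempotent on its own masked output and monotone in the ranges", {
  spec <- sample_plant_spec(9, n_leaves = 4)
  fr <- render_frame(spec, 12)
  m1 <- hsv_binarize(fr$rgb)
  masked <- fr$rgb
  for (ch in 1:3) { pl <- masked[, , ch]; pl[m1 == 0] <- 0; masked[, , ch] <- pl }
  expect_identical(hsv_binarize(masked), m1)
  wider <- hsv_ranges(hue = c(0, 1), saturation = c(0, 1), value = c(0, 1))
  expect_true(all(hsv_binarize(fr$rgb, wider) >= m1))
})

test_that("frame differencing thresholds the max channel difference", {
  spec <- sample_plant_spec(10, n_leaves = 4)
  fr <- render_frame(spec, 10)
  bg <- render_background(spec)
  expect_true(all(frame_difference(bg, bg) == 0))
  expect_true(all(frame_difference(fr$rgb, bg, threshold = 1) == 0))
  rough <- frame_difference(fr$rgb, bg)
  expect_true(all(rough[fr$mask > 0] == 1))  # foreground superset of plant
  expect_error(frame_difference(fr$rgb, bg[1:10, 1:10, ]), "dimension")
})

test_that("green superimposition keeps green plant pixels and zeroes clutter", {
  spec <- sample_plant_spec(12, n_leaves = 3)
  fr <- render_frame(spec, 10)
  rough <- frame_difference(fr$rgb, render_background(spec))
  out <- green_superimpose(fr$rgb, matrix(0, nrow(fr$mask), ncol(fr$mask)))
  expect_true(all(out == 0))  # empty rough mask
  out <- green_superimpose(fr$rgb, rough)
  expect_identical(out[, , 1][fr$mask > 0], fr$rgb[, , 1][fr$mask > 0])
  # brown soil blob inside the rough mask is removed (hue outside green band)
  soiled <- fr$rgb
  soil <- shootgraph:::hsv_to_rgb_triple(0.08, 0.6, 0.4)
  for (ch in 1:3) soiled[300:310, 100:140, ch] <- soil[ch]
  rough2 <- frame_difference(soiled, render_background(spec))
  out2 <- green_superimpose(soiled, rough2)
  expect_true(all(out2[300:310, 100:140, ] == 0))
})

test_that("morphological cleanup removes specks, fills holes, keeps one component", {
  spec <- sample_plant_spec(14, n_leaves = 4)
  fr <- render_frame(spec, 12)
  noisy <- fr$mask
  set.seed(1)
  for (k in 1:10) {  # isolated 1 px specks
    repeat {
      r <- sample(5:50, 1); c <- sample(5:50, 1)
      if (noisy[r, c] == 0) { noisy[r, c] <- 1; break }
    }
  }
  cleaned <- morphological_clean(noisy)
  expect_equal(shootgraph:::count_components(cleaned), 1)
  expect_true(all(cleaned[1:55, 1:55] == 0))
  # a small interior hole is filled back
  holed <- fr$mask
  solid <- which(EBImage::erode(fr$mask, shootgraph:::disc_brush(2)) > 0, arr.ind = TRUE)
  holed[solid[1, 1], solid[1, 2]] <- 0
  expect_identical(morphological_clean(holed), morphological_clean(fr$mask))
  expect_equal(morphological_clean(holed)[solid[1, 1], solid[1, 2]], 1)
  # empty input passes through
  expect_true(all(morphological_clean(matrix(0, 10, 10)) == 0))
})

test_that("full segmentation recovers the renderer truth mask", {
  for (seed in c(5, 17)) {
    spec <- sample_plant_spec(seed, n_leaves = 5)
    fr <- render_frame(spec, 15)
    bg <- render_background(spec)
    m <- segment_plant(fr$rgb, bg)
    expect_gte(mask_iou(m, fr$mask), 0.98)
    # never contains pixels absent from the HSV binarization of the frame
    expect_true(all(m <= hsv_binarize(fr$rgb)))
  }
  spec <- sample_plant_spec(5, n_leaves = 5)
  bg <- render_background(spec)
  expect_true(all(segment_plant(bg, bg) == 0))  # background-only frame
})

test_that("segmentation is robust to illumination gain on the background", {
  spec <- sample_plant_spec(19, n_leaves = 5)
  fr <- render_frame(spec, 15)
  bg <- render_background(spec)
  lit <- fr$rgb
  for (ch in 1:3) {
    pl <- lit[, , ch]
    pl[fr$mask == 0] <- pmin(1, pl[fr$mask == 0] * 1.2)
    lit[, , ch] <- pl
  }
  expect_gte(mask_iou(segment_plant(lit, bg), fr$mask), 0.98)
})

test_that("registration recovers identity and known similarity transforms", {
  set.seed(42)
  bg <- array(0.2, dim = c(160, 160, 3))
  for (k in 1:25) {  # textured background with corners
    r <- sample(10:140, 1); c <- sample(10:140, 1)
    h <- sample(4:14, 1); w <- sample(4:14, 1)
    val <- runif(3, 0.3, 1)
    for (ch in 1:3) bg[r:(r + h), c:(c + w), ch] <- val[ch]
  }
  reg <- register_to_background(bg, bg)
  expect_equal(attr(reg, "scale"), 1, tolerance = 0.01)
  expect_equal(attr(reg, "rotation"), 0, tolerance = 0.01)
  scaled <- shootgraph:::warp_similarity(bg, dim(bg)[1:2], 1.2 + 0i, 4 + 6i,
                                         fill = c(0.2, 0.2, 0.2))
  reg2 <- register_to_background(scaled, bg)
  expect_equal(attr(reg2, "scale"), 1 / 1.2, tolerance = 0.01)
  expect_error(
    register_to_background(array(0.5, dim = c(80, 80, 3)),
                           array(0.5, dim = c(80, 80, 3))),
    class = "registration_failure"
  )
})

test_that("segmentation config round-trips through a key-value file", {
  f <- withr::local_tempfile(fileext = ".yml")
  writeLines(c(
    "# custom thresholds", "difference_threshold: 0.1",
    "hue: [0.1, 0.4]", "register: false", "min_component_area: 20"
  ), f)
  cfg <- read_segmentation_config(f)
  expect_equal(cfg$difference_threshold, 0.1)
  expect_equal(cfg$hsv$hue, c(0.1, 0.4))
  expect_false(cfg$register)
  expect_equal(cfg$min_component_area, 20)
  expect_equal(cfg$hsv$saturation, c(0.102, 0.804))  # untouched default
})
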