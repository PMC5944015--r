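test_that("plant sampling is deterministic under a fixed seed and seed-sensitive", {
  a <- sample_plant_spec(1, n_leaves = 3)
  b <- sample_plant_spec(1, n_leaves = 3)
  c <- sample_plant_spec(2, n_leaves = 3)
  expect_identical(a, b)
  expect_false(identical(a$leaf_specs, c$leaf_specs))
  days <- vapply(a$leaf_specs, `[[`, integer(1), "emergence_day")
  expect_true(all(diff(days) > 0))
  sides <- vapply(a$leaf_specs, `[[`, character(1), "side")
  expect_true(all(sides[-1] != sides[-length(sides)]))  # alternating
})

test_that("degenerate and invalid sampler inputs behave", {
  s0 <- sample_plant_spec(5, n_leaves = 0)
  expect_length(s0$leaf_specs, 0)
  expect_error(sample_plant_spec(1, n_leaves = -1))
  expect_error(leaf_spec(0, "left", 20, 8, 90), "emergence_day")
  expect_error(render_frame(sample_plant_spec(1, 2), day = 0), "day")
  expect_error(render_sequence(sample_plant_spec(1, 2), integer(0)))
})

test_that("rendering respects emergence days and mask invariants", {
  spec <- plant_spec("t", list(
    leaf_spec(1, "left", 25, 9, 90),
    leaf_spec(5, "right", 52, 9, 90)
  ))
  fr3 <- render_frame(spec, 3)
  expect_equal(nrow(fr3$truth_leaves), 1)  # pre-emergence leaf absent
  expect_length(fr3$truth$leaves, 1)
  fr8 <- render_frame(spec, 8)
  expect_equal(nrow(fr8$truth_leaves), 2)
  expect_true(all(vapply(fr8$truth$leaves, `[[`, character(1), "status") == "alive"))
  # mask is one 8-connected component
  expect_equal(shootgraph:::count_components(fr8$mask), 1)
  # truth tips/collars lie within stroke width of mask pixels
  for (l in fr8$truth$leaves) {
    for (pt in list(l$tip, l$collar)) {
      r <- pt[2]; c <- pt[1]; w <- spec$stroke_width
      patch <- fr8$mask[max(1, r - w):min(nrow(fr8$mask), r + w),
                        max(1, c - w):min(ncol(fr8$mask), c + w)]
      expect_true(any(patch > 0))
    }
  }
})

test_that("a stem-only plant renders as a near-vertical bar", {
  spec <- plant_spec("s", list(), stem_growth_rate = 12)
  fr <- render_frame(spec, 10)
  expect_equal(nrow(fr$truth_leaves), 0)
  idx <- which(fr$mask > 0, arr.ind = TRUE)
  expect_lt(diff(range(idx[, 2])), 10)       # narrow
  expect_gt(diff(range(idx[, 1])), 100)      # tall
})

test_that("per-day truth leaf counts are a non-decreasing step function", {
  spec <- sample_plant_spec(11, n_leaves = 5)
  frames <- render_sequence(spec, 1:22)
  counts <- vapply(frames, function(f) nrow(f$truth_leaves), integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(max(counts), 5)
})

test_that("rendering is deterministic and consistent between frame and sequence", {
  spec <- sample_plant_spec(3, n_leaves = 4)
  s1 <- render_sequence(spec, c(4, 9))
  s2 <- render_sequence(spec, c(4, 9))
  expect_identical(s1[[1]]$rgb, s2[[1]]$rgb)
  expect_identical(s1[[2]]$mask, s2[[2]]$mask)
  single <- render_frame(spec, 9)
  expect_identical(single$mask, s1[[2]]$mask)
  expect_identical(single$truth_leaves, s1[[2]]$truth_leaves)
})

test_that("ground truth is geometrically consistent: chord <= arc", {
  for (seed in c(2, 8, 21)) {
    spec <- sample_plant_spec(seed, n_leaves = 6)
    fr <- render_frame(spec, 17)
    expect_true(all(fr$truth_leaves$chord <= fr$truth_leaves$length + 1e-9))
  }
})

test_that("bezier primitives match independent oracles", {
  # straight segment: arc length equals the chord
  expect_equal(bezier_arc_length(c(0, 0), c(1.5, 2), c(3, 4)), 5, tolerance = 1e-9)
  # canonical parabola: area between curve and chord = 1/3 (closed form),
  # and matches the 2/3-control-triangle rule
  p0 <- c(0, 0); p1 <- c(0.5, 1); p2 <- c(1, 0)
  expect_equal(bezier_chord_area(p0, p1, p2), 1 / 3, tolerance = 1e-12)
  # curvature vs numerical differentiation
  num_curv <- function(t, h = 1e-5) {
    pts <- bezier_point(p0, p1, p2, c(t - h, t, t + h))
    d1 <- (pts[3, ] - pts[1, ]) / (2 * h)
    d2 <- (pts[3, ] - 2 * pts[2, ] + pts[1, ]) / h^2
    abs(d1[1] * d2[2] - d1[2] * d2[1]) / sum(d1^2)^1.5
  }
  for (t in c(0.2, 0.5, 0.8)) {
    expect_equal(bezier_curvature(p0, p1, p2, t), num_curv(t), tolerance = 1e-4)
  }
  # truth leaf lengths follow min(max_length, rate * age)
  spec <- plant_spec("t", list(leaf_spec(2, "right", 30, 7, 40)))
  expect_equal(render_frame(spec, 3)$truth_leaves$length, 14, tolerance = 1e-9)
  expect_equal(render_frame(spec, 30)$truth_leaves$length, 40, tolerance = 1e-9)
})

test_that("leaf center-lines do not cross off the stem (no-crossover default)", {
  checked <- 0L
  for (seed in c(4, 13)) {
    spec <- sample_plant_spec(seed, n_leaves = 6)
    beziers <- purrr::compact(purrr::map(
      spec$leaf_specs, shootgraph:::leaf_bezier, spec = spec, day = 20
    ))
    ts <- seq(0, 1, length.out = 300)
    curves <- purrr::map(beziers, ~ bezier_point(.x$p0, .x$p1, .x$p2, ts))
    for (i in seq_along(curves)) {
      for (j in seq_len(i - 1)) {
        d <- sqrt(outer(curves[[i]][, 1], curves[[j]][, 1], `-`)^2 +
                    outer(curves[[i]][, 2], curves[[j]][, 2], `-`)^2)
        # approaches closer than 2 px happen only near the stem (both
        # curve parameters near 0); elsewhere curves stay apart
        ij <- arrayInd(which.min(d), dim(d))
        ok <- min(d) >= 2 || (ts[ij[1]] < 0.15 && ts[ij[2]] < 0.15)
        expect_true(ok)
        checked <- checked + 1L
      }
    }
  }
  expect_gte(checked, 2 * choose(6, 2) - 20)  # all pairs examined
})

test_that("the crossover flag produces intersecting center-lines", {
  spec <- sample_plant_spec(6, n_leaves = 4)
  spec$crossover <- TRUE
  fr <- render_frame(spec, 14)
  expect_error(analyze_mask(fr$mask), class = "unsupported_topology")
})
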