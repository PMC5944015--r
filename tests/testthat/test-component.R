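test_that("polynomial leaf fitting handles lines, parabolas and orientation", {
  # collinear points: residual ~ 0 and the fit reproduces the line
  # (y rises twice as fast as x, so the fit is x(y))
  path <- cbind(x = 0:10, y = 2 * (0:10) + 1)
  g <- fit_leaf_curve(path)
  expect_lt(g$rms, 1e-8)
  expect_equal(g$orient, "x_of_y")
  expect_equal(shootgraph:::poly_eval(g$coefs, shootgraph:::geom_u(g, 16)),
               7.5, tolerance = 1e-6)

  # samples of y = x^2 are reproduced exactly (order 4 >= 2)
  xs <- seq(0, 1, by = 0.05)
  gq <- fit_leaf_curve(cbind(x = xs, y = xs^2))
  expect_lt(gq$rms, 1e-10)
  expect_equal(shootgraph:::geom_slope(gq, 0.3), 0.6, tolerance = 1e-6)

  # near-vertical path flips orientation and fits better than forced y(x)
  vpath <- cbind(x = 20 + 0.02 * (0:40)^2 / 40, y = 100 + (0:40))
  gv <- fit_leaf_curve(vpath)
  expect_equal(gv$orient, "x_of_y")
  expect_lt(gv$rms, 0.5)

  expect_error(fit_leaf_curve(cbind(1:2, 1:2)), class = "insufficient_points")
})

test_that("leaf length matches closed forms and scales homogeneously", {
  # straight leaf: arc equals chord
  p <- cbind(x = seq(0, 3, length.out = 21), y = seq(0, 4, length.out = 21))
  gs <- fit_leaf_curve(p)
  expect_equal(leaf_length(gs), 5, tolerance = 1e-6)

  # p(x) = x^2 on [0, 1]: sqrt(5)/2 + asinh(2)/4
  xs <- seq(0, 1, by = 0.02)
  gq <- fit_leaf_curve(cbind(x = xs, y = xs^2))
  expect_equal(leaf_length(gq), sqrt(5) / 2 + asinh(2) / 4, tolerance = 1e-6)

  gd <- fit_leaf_curve(cbind(x = 2 * xs, y = 2 * xs^2))
  # doubling coordinates doubles the arc length (note 2x^2 is not x^2 scaled;
  # use the straight leaf for strict homogeneity)
  gs2 <- fit_leaf_curve(2 * p)
  expect_equal(leaf_length(gs2), 10, tolerance = 1e-6)
  expect_true(is.finite(leaf_length(gd)))
})

test_that("junction-tip distance is the Euclidean chord", {
  expect_equal(junction_tip_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(junction_tip_distance(c(2, 2), c(2, 2)), 0)
  expect_equal(junction_tip_distance(c(1, 1), c(4, 5)), 5)
})

test_that("curvature follows K = |y''| / (1 + y'^2)^(3/2)", {
  line <- poly_curve(c(3, 2))           # y = 3 + 2x
  for (x in c(-5, 0, 7)) expect_equal(curvature_at(line, x), 0)
  par <- poly_curve(c(0, 0, 1))         # y = x^2
  expect_identical(curvature_at(par, 0), 2)
  # polynomial fit to an upper semicircle of radius 50: K ~ 1/50 at apex
  th <- seq(pi / 4, 3 * pi / 4, length.out = 80)
  circ <- cbind(x = 50 * cos(th), y = 50 * sin(th))
  gc <- fit_leaf_curve(circ)
  expect_equal(curvature_at(gc, 0), 0.02, tolerance = 0.1)
})

test_that("leaf apex is the farthest point from the chord (possibly several)", {
  xs <- seq(0, 1, by = 0.01)
  arch <- fit_leaf_curve(cbind(x = xs, y = xs * (1 - xs)))
  ap <- leaf_apex(arch)
  expect_false(ap$degenerate)
  expect_equal(unname(ap$points[1, 1]), 0.5, tolerance = 0.02)  # symmetric arch

  straight <- fit_leaf_curve(cbind(x = xs, y = 2 * xs))
  aps <- leaf_apex(straight)
  expect_true(aps$degenerate)
  expect_equal(nrow(aps$points), length(xs))            # all points, flagged

  # two equal humps -> two apices
  humps <- fit_leaf_curve(cbind(x = xs, y = sin(2 * pi * xs)))
  aph <- leaf_apex(humps, tol = 1e-3)
  expect_equal(nrow(aph$points), 2)
  deg <- fit_leaf_curve(cbind(x = c(0, 1, 0), y = c(0, 1, 0)))
  deg$tip <- deg$junction
  expect_error(leaf_apex(deg), class = "undefined_chord")
})

test_that("mid-leaf picks floor(n/2) clamped to 1", {
  path10 <- cbind(x = seq(0, 9), y = rep(0, 10))
  expect_equal(mid_leaf(fit_leaf_curve(path10))$index, 5)
  path7 <- cbind(x = seq(0, 6), y = rep(0, 7))
  expect_equal(mid_leaf(fit_leaf_curve(path7))$index, 3)
  g1 <- poly_curve(c(0, 1))
  g1$path <- cbind(x = 2, y = 2)
  expect_equal(mid_leaf(g1)$index, 1)
})

test_that("leaf-junction angle follows the two-slope formula", {
  expect_equal(angle_between_slopes(1, 0), pi / 4)
  expect_equal(angle_between_slopes(2, 2), 0)
  expect_equal(angle_between_slopes(1, -1), pi / 2)
  # geometric version agrees on a fitted leaf
  xs <- seq(0, 1, by = 0.01)
  g <- fit_leaf_curve(cbind(x = xs, y = xs * (1 - xs)))
  m1 <- shootgraph:::geom_slope(g, 0)   # tangent at junction
  m2 <- 0                               # chord (0,0) -> (1,0)
  expect_equal(leaf_junction_angle(g), angle_between_slopes(m1, m2),
               tolerance = 1e-6)
  expect_true(leaf_junction_angle(g) >= 0 && leaf_junction_angle(g) <= pi / 2)
})

test_that("integral leaf-skeleton area matches closed forms and scales as s^2", {
  xs <- seq(0, 1, by = 0.01)
  straight <- fit_leaf_curve(cbind(x = xs, y = 2 * xs))
  expect_equal(integral_leaf_skeleton_area(straight), 0, tolerance = 1e-8)
  arch <- fit_leaf_curve(cbind(x = xs, y = xs * (1 - xs)))
  expect_equal(integral_leaf_skeleton_area(arch), 1 / 6, tolerance = 1e-6)
  arch3 <- fit_leaf_curve(cbind(x = 3 * xs, y = 3 * xs * (1 - xs)))
  expect_equal(integral_leaf_skeleton_area(arch3), 9 / 6, tolerance = 1e-6)
})

test_that("stem angle regresses x on y so vertical stems score zero", {
  expect_equal(stem_angle(data.frame(x = rep(5, 4), y = c(10, 20, 30, 40))), 0)
  expect_equal(stem_angle(data.frame(x = c(0, 10), y = c(0, 10))), pi / 4,
               tolerance = 1e-9)
  expect_error(stem_angle(data.frame(x = 1, y = 1)),
               class = "insufficient_junctions")
  # tilted stem with +-1 px junction noise recovers within 0.02 rad
  set.seed(3)
  for (rep in 1:10) {
    y <- seq(300, 120, by = -30)
    x <- 120 + tan(0.1) * (300 - y) + runif(length(y), -1, 1)
    expect_lt(abs(stem_angle(data.frame(x = x, y = y)) - 0.1), 0.02)
  }
})

test_that("arc >= chord for every fitted leaf and rotation barely changes length", {
  spec <- sample_plant_spec(61, 6)
  fr <- render_frame(spec, 19)
  tg <- analyze_mask(fr$mask)
  geoms <- leaf_geometries(tg)
  expect_gt(length(geoms), 3)
  for (g in geoms) {
    expect_lt(g$rms, 2)  # fitted-curve residual bound
    ll <- leaf_length(g)
    expect_gte(ll + 1e-6, junction_tip_distance(g$junction, g$tip))
    # rotate the path by 90 degrees: orientation flips, length within 1%
    rot <- cbind(x = -g$path[, 2], y = g$path[, 1])
    gr <- fit_leaf_curve(rot)
    expect_equal(leaf_length(gr), ll, tolerance = 0.01)
  }
})

test_that("fitted geometry recovers the generator's analytic leaf values", {
  # fit the exact center-lines (no rasterization): length within 5%,
  # integral area within 10% of the closed forms
  for (seed in c(18, 55)) {
    spec <- sample_plant_spec(seed, 6)
    beziers <- purrr::compact(purrr::map(
      spec$leaf_specs, shootgraph:::leaf_bezier, spec = spec, day = 20
    ))
    for (bz in beziers) {
      ts <- seq(0, 1, length.out = 120)
      path <- bezier_point(bz$p0, bz$p1, bz$p2, ts)
      colnames(path) <- c("x", "y")
      g <- fit_leaf_curve(path)
      expect_equal(leaf_length(g), bz$length, tolerance = 0.05)
      expect_equal(integral_leaf_skeleton_area(g),
                   bezier_chord_area(bz$p0, bz$p1, bz$p2), tolerance = 0.1)
      kmid <- unname(curvature_at(g, shootgraph:::geom_ind(g, mid_leaf(g)$point)))
      expect_equal(kmid, bezier_curvature(bz$p0, bz$p1, bz$p2, 0.5),
                   tolerance = 0.35)
    }
  }
})

test_that("per-frame component records carry all six phenotypes", {
  fr <- render_frame(sample_plant_spec(71, 5), 16)
  tg <- analyze_mask(fr$mask)
  cp <- component_phenotypes(tg, "plant", 16)
  expect_equal(nrow(cp), count_leaves(tg))
  expect_true(all(c("leaf_length", "junction_tip_distance", "apex_curvature",
                    "mid_leaf_curvature", "leaf_junction_angle",
                    "integral_area") %in% names(cp)))
  expect_true(all(cp$leaf_length + 1e-6 >= cp$junction_tip_distance, na.rm = TRUE))
  expect_true(all(cp$apex_curvature >= 0, na.rm = TRUE))
  expect_true(all(cp$leaf_junction_angle >= 0 & cp$leaf_junction_angle <= pi / 2,
                  na.rm = TRUE))
  st <- stem_phenotypes(tg, "plant", 16)
  expect_equal(nrow(st), 1)
  expect_true(st$stem_angle >= 0 && st$stem_angle < pi / 2)
})
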