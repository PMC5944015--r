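#' Synthetic maize-like plants with exact ground truth
#'
#' The generator renders stick-figure maize plants: a near-vertical stem
#' growing from the bottom of the frame, with leaves emerging at junctions
#' on alternating sides on known days.  Each leaf center-line is a
#' quadratic Bezier curve, so its arc length, curvature and the area
#' enclosed with the junction-tip chord all have closed forms, giving every
#' downstream measurement an independent analytic oracle.  Strokes are
#' rendered by dilating the one-pixel center-line with a disc, on a
#' non-green background, inside the HSV band that the segmentation
#' defaults accept.
#'
#' @name synthetic_plants
NULL

# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Leaf and plant specifications
#'
#' `leaf_spec()` describes one leaf: the day it emerges, the side of the
#' stem it grows from, the height of its junction (collar) along the stem,
#' its daily elongation rate and final length, and two shape parameters:
#' `arch`, a curvature scale (1/px) controlling how much the tangent
#' rotates per pixel of growth, and `droop`, a unitless multiplier on that
#' rotation.  `init_angle` is the emergence angle above the horizontal in
#' radians.
#'
#' @param emergence_day integer day (>= 1) the leaf first appears.
#' @param side `"left"` or `"right"`.
#' @param junction_height height of the collar above the base, px along the stem.
#' @param elongation_rate growth in px per day.
#' @param max_length final leaf length, px.
#' @param arch curvature parameter, 1/px, >= 0.
#' @param droop unitless shape parameter, >= 0.
#' @param init_angle emergence angle above horizontal, radians.
#' @param view90_factor projected length factor used for the 90-degree view.
#' @return a `leaf_spec` list.
#' @export
leaf_spec <- function(emergence_day, side, junction_height, elongation_rate,
                      max_length, arch = 0.006, droop = 0.4,
                      init_angle = 0.6, view90_factor = 1) {
  if (emergence_day < 1) abort("emergence_day must be >= 1")
  if (max_length <= 0) abort("max_length must be positive")
  side <- match.arg(side, c("left", "right"))
  structure(
    list(
      emergence_day = as.integer(emergence_day), side = side,
      junction_height = junction_height, elongation_rate = elongation_rate,
      max_length = max_length, arch = arch, droop = droop,
      init_angle = init_angle, view90_factor = view90_factor
    ),
    class = "leaf_spec"
  )
}

#' @rdname leaf_spec
#' @param plant_id identifier string.
#' @param leaf_specs list of [leaf_spec()] sorted by emergence day.
#' @param stem_growth_rate px/day, governs stem height before the first leaf.
#' @param image_size `(rows, cols)` of the rendered frame.
#' @param base_position `(row, col)` of the plant base; must lie in the
#'   bottom third of the image.
#' @param stroke_width stroke diameter in px (>= 3, odd).
#' @param plant_hsv,background_hsv HSV triples in `[0, 1]`.
#' @param stem_tilt stem lean from vertical, radians (positive leans right).
#' @param crossover if `TRUE` an extra rogue leaf crossing an existing one
#'   is rendered, to exercise cycle detection downstream.
#' @param seed integer recorded with the spec.
#' @export
plant_spec <- function(plant_id, leaf_specs, stem_growth_rate = 10,
                       image_size = c(320, 240), base_position = c(300, 120),
                       stroke_width = 5,
                       plant_hsv = c(0.33, 0.45, 0.55),
                       background_hsv = c(0.60, 0.15, 0.92),
                       stem_tilt = 0, crossover = FALSE, seed = NA_integer_) {
  if (stroke_width < 3) abort("stroke_width must be >= 3")
  if (base_position[1] < 2 * image_size[1] / 3)
    abort("base_position must lie in the bottom third of the image")
  ed <- vapply(leaf_specs, `[[`, integer(1), "emergence_day")
  if (is.unsorted(ed)) abort("leaf_specs must be sorted by emergence_day")
  structure(
    list(
      plant_id = plant_id, leaf_specs = leaf_specs,
      stem_growth_rate = stem_growth_rate,
      image_size = as.integer(image_size),
      base_position = base_position, stroke_width = stroke_width,
      plant_hsv = plant_hsv, background_hsv = background_hsv,
      stem_tilt = stem_tilt, crossover = crossover, seed = seed
    ),
    class = "plant_spec"
  )
}

#' Default parameter ranges for the plant sampler
#'
#' Ranges mimic vegetative-stage maize imaged daily: the first leaf on day
#' 1-2, a new leaf every 2-4 days, collars 24-30 px apart, leaves
#' elongating 6-12 px/day up to 70-110 px, and a stem within 0.06 rad of
#' vertical.
#'
#' @return named list of `(lo, hi)` ranges.
#' @export
default_plant_ranges <- function() {
  list(
    first_emergence = c(1, 2),
    emergence_gap = c(2, 4),
    junction_start = c(18, 26),
    junction_gap = c(24, 30),
    elongation_rate = c(6, 12),
    max_length = c(70, 110),
    arch = c(0.004, 0.010),
    droop = c(0.2, 0.6),
    init_angle = c(0.45, 0.85),
    stem_tilt = c(-0.06, 0.06),
    view90_factor = c(0.65, 1)
  )
}

runif1 <- function(r) runif(1, r[1], r[2])
rint1 <- function(r) sample(seq(r[1], r[2]), 1)

#' Sample a reproducible plant specification
#'
#' @param seed integer seed; the same seed always yields the same spec.
#' @param n_leaves number of leaves (>= 0).
#' @param ranges parameter ranges, see [default_plant_ranges()].
#' @param ... further arguments passed to [plant_spec()].
#' @return a [plant_spec()].
#' @export
sample_plant_spec <- function(seed, n_leaves, ranges = default_plant_ranges(), ...) {
  if (n_leaves < 0) abort("n_leaves must be >= 0")
  for (nm in names(default_plant_ranges()))
    if (is.null(ranges[[nm]])) abort(paste0("ranges is missing '", nm, "'"))
  with_seed(seed, {
    side0 <- sample(c("left", "right"), 1)
    day <- 0; height <- 0
    leaves <- vector("list", n_leaves)
    for (i in seq_len(n_leaves)) {
      day <- if (i == 1) rint1(ranges$first_emergence) else day + rint1(ranges$emergence_gap)
      height <- if (i == 1) runif1(ranges$junction_start) else height + runif1(ranges$junction_gap)
      side <- if ((i %% 2) == 1) side0 else setdiff(c("left", "right"), side0)
      leaves[[i]] <- leaf_spec(
        emergence_day = day, side = side, junction_height = height,
        elongation_rate = runif1(ranges$elongation_rate),
        max_length = runif1(ranges$max_length),
        arch = runif1(ranges$arch), droop = runif1(ranges$droop),
        init_angle = runif1(ranges$init_angle),
        view90_factor = runif1(ranges$view90_factor)
      )
    }
    plant_spec(
      plant_id = sprintf("synth_%06d", seed %% 1000000L),
      leaf_specs = leaves, stem_tilt = runif1(ranges$stem_tilt),
      seed = as.integer(seed), ...
    )
  })
}

# ---- quadratic Bezier primitives --------------------------------------------

#' Quadratic Bezier geometry
#'
#' Closed-form helpers for the leaf center-line model.  `bezier_point()`
#' evaluates the curve, `bezier_arc_length()` integrates the speed to
#' relative tolerance 1e-10, `bezier_curvature()` is the analytic curvature
#' |B' x B''| / |B'|^3 and `bezier_chord_area()` the area enclosed between
#' the curve and its chord (two thirds of the control-triangle area).
#'
#' @param p0,p1,p2 control points, numeric length-2 `(x, y)`.
#' @param t curve parameter(s) in `[0, 1]`.
#' @return point matrix, or scalar length/curvature/area.
#' @export
bezier_point <- function(p0, p1, p2, t) {
  cbind(
    (1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1],
    (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2]
  )
}

#' @rdname bezier_point
#' @export
bezier_arc_length <- function(p0, p1, p2) {
  d1 <- 2 * (p1 - p0); d2 <- 2 * (p2 - p1)
  speed <- function(t) {
    dx <- (1 - t) * d1[1] + t * d2[1]
    dy <- (1 - t) * d1[2] + t * d2[2]
    sqrt(dx^2 + dy^2)
  }
  integrate(speed, 0, 1, rel.tol = 1e-10, subdivisions = 200L)$value
}

#' @rdname bezier_point
#' @export
bezier_curvature <- function(p0, p1, p2, t) {
  d1 <- 2 * (p1 - p0); d2 <- 2 * (p2 - p1)
  dx <- (1 - t) * d1[1] + t * d2[1]
  dy <- (1 - t) * d1[2] + t * d2[2]
  ax <- d2[1] - d1[1]; ay <- d2[2] - d1[2]
  abs(dx * ay - dy * ax) / (dx^2 + dy^2)^1.5
}

#' @rdname bezier_point
#' @export
bezier_chord_area <- function(p0, p1, p2) {
  v1 <- p1 - p0; v2 <- p2 - p0
  (2 / 3) * abs(v1[1] * v2[2] - v1[2] * v2[1]) / 2
}

# ---- geometry of one frame --------------------------------------------------

leaf_length_on_day <- function(leaf, day, view = 0) {
  if (day < leaf$emergence_day) return(0)
  len <- min(leaf$max_length, leaf$elongation_rate * (day - leaf$emergence_day + 1))
  if (view == 90) len <- len * leaf$view90_factor
  len
}

stem_unit <- function(tilt) c(sin(tilt), -cos(tilt))  # (dx, dy), y grows down

# control points of a leaf on a given day, in (x, y) pixel coordinates
leaf_bezier <- function(spec, leaf, day, view = 0) {
  len <- leaf_length_on_day(leaf, day, view)
  if (len <= 0) return(NULL)
  base <- c(spec$base_position[2], spec$base_position[1])  # (x, y)
  junction <- base + stem_unit(spec$stem_tilt) * leaf$junction_height
  s <- if (leaf$side == "left") -1 else 1
  b0 <- leaf$init_angle
  delta <- min(1.3, leaf$arch * len * (1 + leaf$droop))
  bt <- b0 - delta
  u <- c(s * cos(b0), -sin(b0))
  v <- c(s * cos(bt), -sin(bt))
  unit_len <- bezier_arc_length(c(0, 0), u, u + v)
  a <- len / unit_len
  p0 <- junction; p1 <- junction + a * u; p2 <- junction + a * (u + v)
  list(p0 = p0, p1 = p1, p2 = p2, length = len, side = s,
       junction = junction, tip = p2)
}

# stamp a polyline (continuous (x, y) points) onto a mask matrix
stamp_points <- function(mask, pts) {
  r <- round(pts[, 2]); c <- round(pts[, 1])
  ok <- r >= 1 & r <= nrow(mask) & c >= 1 & c <= ncol(mask)
  mask[cbind(r[ok], c[ok])] <- 1
  mask
}

#' Render one day of a synthetic plant
#'
#' @param spec a [plant_spec()].
#' @param day imaging day (>= 1).
#' @param view side-view angle, 0 or 90 degrees.
#' @return a `rendered_frame` list with elements `day`, `view`, `rgb`
#'   (array), `mask` (binary matrix), `truth` (a [gt_plant()]) and
#'   `truth_leaves`, a tibble of per-leaf analytic geometry: emergence
#'   rank, junction and tip coordinates, exact arc length, the enclosed
#'   curve-chord area, curvature at mid-curve, and the junction-tip
#'   distance.
#' @export
render_frame <- function(spec, day, view = 0) {
  if (day < 1) abort("day must be >= 1")
  if (!view %in% c(0, 90)) abort("view must be 0 or 90")
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  center <- matrix(0, nr, nc)
  base <- c(spec$base_position[2], spec$base_position[1])
  emerged <- purrr::keep(spec$leaf_specs, ~ .x$emergence_day <= day)
  stem_top_h <- if (length(emerged) > 0) {
    max(vapply(emerged, `[[`, numeric(1), "junction_height"))
  } else {
    spec$stem_growth_rate * day
  }
  # stem center-line
  tt <- seq(0, stem_top_h, by = 0.25)
  stem_pts <- cbind(base[1] + stem_unit(spec$stem_tilt)[1] * tt,
                    base[2] + stem_unit(spec$stem_tilt)[2] * tt)
  center <- stamp_points(center, stem_pts)

  beziers <- purrr::compact(purrr::map(spec$leaf_specs, leaf_bezier,
                                       spec = spec, day = day, view = view))
  for (bz in beziers) {
    ts <- seq(0, 1, length.out = max(16L, ceiling(4 * bz$length)))
    center <- stamp_points(center, bezier_point(bz$p0, bz$p1, bz$p2, ts))
  }
  if (isTRUE(spec$crossover) && length(beziers) >= 2) {
    a <- beziers[[2]]$junction
    m <- bezier_point(beziers[[1]]$p0, beziers[[1]]$p1, beziers[[1]]$p2, 0.5)[1, ]
    dirv <- (m - a); dirv <- dirv / sqrt(sum(dirv^2))
    tt <- seq(0, sqrt(sum((m - a)^2)) + 40, by = 0.25)
    center <- stamp_points(center, cbind(a[1] + dirv[1] * tt, a[2] + dirv[2] * tt))
  }
  mask <- EBImage::dilate(center, disc_brush(floor(spec$stroke_width / 2)))

  pc <- hsv_to_rgb_triple(spec$plant_hsv[1], spec$plant_hsv[2], spec$plant_hsv[3])
  bc <- hsv_to_rgb_triple(spec$background_hsv[1], spec$background_hsv[2], spec$background_hsv[3])
  rgb <- array(rep(bc, each = nr * nc), dim = c(nr, nc, 3))
  for (ch in 1:3) {
    pl <- rgb[, , ch]; pl[mask > 0] <- pc[ch]; rgb[, , ch] <- pl
  }

  ranks <- which(vapply(spec$leaf_specs, `[[`, integer(1), "emergence_day") <= day)
  truth_leaves <- purrr::map2_dfr(beziers, ranks, function(bz, rk) {
    tibble::tibble(
      leaf_rank = rk,
      emergence_day = spec$leaf_specs[[rk]]$emergence_day,
      side = spec$leaf_specs[[rk]]$side,
      junction_x = bz$junction[1], junction_y = bz$junction[2],
      tip_x = bz$tip[1], tip_y = bz$tip[2],
      length = bz$length,
      chord = sqrt(sum((bz$tip - bz$junction)^2)),
      integral_area = bezier_chord_area(bz$p0, bz$p1, bz$p2),
      mid_curvature = bezier_curvature(bz$p0, bz$p1, bz$p2, 0.5)
    )
  })
  truth <- gt_plant(
    plant_image_id = sprintf("%s_day%02d_view%d", spec$plant_id, day, view),
    base = c(round(base[1]), round(base[2])),
    leaves = purrr::map(seq_len(nrow(truth_leaves)), function(i) {
      gt_leaf(
        leaf_id = truth_leaves$leaf_rank[i], status = "alive",
        tip = c(round(truth_leaves$tip_x[i]), round(truth_leaves$tip_y[i])),
        collar = c(round(truth_leaves$junction_x[i]), round(truth_leaves$junction_y[i]))
      )
    })
  )
  structure(
    list(day = as.integer(day), view = view, rgb = rgb, mask = mask,
         truth = truth, truth_leaves = truth_leaves,
         stem_tilt = spec$stem_tilt, plant_id = spec$plant_id),
    class = "rendered_frame"
  )
}

#' @rdname render_frame
#' @param days strictly increasing vector of imaging days.
#' @export
render_sequence <- function(spec, days, view = 0) {
  if (length(days) == 0) abort("days must be nonempty")
  if (is.unsorted(days, strictly = TRUE)) abort("days must be strictly increasing")
  purrr::map(days, render_frame, spec = spec, view = view)
}

#' Render the plant-free background frame for a spec
#'
#' @inheritParams render_frame
#' @export
render_background <- function(spec) {
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  bc <- hsv_to_rgb_triple(spec$background_hsv[1], spec$background_hsv[2], spec$background_hsv[3])
  array(rep(bc, each = nr * nc), dim = c(nr, nc, 3))
}

#' Trivial top view: a disc spanning the plant's horizontal reach
#'
#' Used to exercise the plant-aspect-ratio denominator; returns the mask
#' and the exact disc diameter.
#'
#' @inheritParams render_frame
#' @export
render_top_view <- function(spec, day) {
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  beziers <- purrr::compact(purrr::map(spec$leaf_specs, leaf_bezier,
                                       spec = spec, day = day, view = 0))
  base_x <- spec$base_position[2]
  reach <- if (length(beziers) == 0) spec$stroke_width else {
    max(vapply(beziers, function(b) abs(b$tip[1] - base_x), numeric(1)))
  }
  r <- max(spec$stroke_width, reach)
  cx <- nc / 2; cy <- nr / 2
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr), nc), nr, nc)
  mask <- matrix(as.numeric((xs - cx)^2 + (ys - cy)^2 <= r^2), nr, nc)
  list(mask = mask, diameter = 2 * r)
}
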