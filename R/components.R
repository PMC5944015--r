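#' Per-leaf and stem geometry
#'
#' Each detected leaf is reduced to a `leaf_geometry`: its ordered
#' skeleton path from junction (collar) to tip, and a least-squares
#' polynomial fitted to that path.  The independent axis is whichever
#' image axis has the greater extent along the path, so near-vertical
#' leaves are fitted as x(y); internally the independent coordinate is
#' rescaled to `[0, 1]` for numerical conditioning and all derivatives are
#' mapped back through the chain rule.  From the fitted curve come the six
#' component phenotypes: leaf length (arc length of the fit between the
#' junction and tip abscissae), junction-tip distance (the chord),
#' curvature at the leaf apex and at mid-leaf, the leaf-junction angle,
#' and the integral leaf-skeleton area enclosed between curve and chord.
#'
#' @name component_phenotypes
NULL

poly_eval <- function(coefs, u) {
  acc <- 0
  for (k in rev(seq_along(coefs))) acc <- acc * u + coefs[k]
  acc
}

poly_deriv_coefs <- function(coefs) {
  if (length(coefs) <= 1) return(0)
  coefs[-1] * seq_len(length(coefs) - 1)
}

poly_integral_coefs <- function(coefs) {
  c(0, coefs / seq_along(coefs))
}

#' Construct a leaf geometry from a skeleton path
#'
#' @param path ordered matrix/data frame of `(x, y)` skeleton points from
#'   junction to tip.
#' @param junction,tip `(x, y)`; default to the path endpoints.
#' @param max_order maximum polynomial order (default 4); the actual order
#'   is `min(max_order, n_points - 1)`.
#' @return a `leaf_geometry` object.
#' @export
fit_leaf_curve <- function(path, junction = NULL, tip = NULL, max_order = 4) {
  path <- as.matrix(path)
  if (nrow(path) < 3) abort("at least 3 path points required", class = "insufficient_points")
  if (is.null(junction)) junction <- path[1, ]
  if (is.null(tip)) tip <- path[nrow(path), ]
  ext_x <- diff(range(path[, 1])); ext_y <- diff(range(path[, 2]))
  orient <- if (ext_y > ext_x) "x_of_y" else "y_of_x"
  ind <- if (orient == "y_of_x") path[, 1] else path[, 2]
  dep <- if (orient == "y_of_x") path[, 2] else path[, 1]
  a <- min(ind); s <- max(ind) - min(ind)
  if (s <= 0) abort("degenerate path: zero extent on both axes", class = "degenerate_leaf")
  u <- (ind - a) / s
  ord <- min(max_order, nrow(path) - 1)
  X <- outer(u, 0:ord, `^`)
  fit <- stats::lm.fit(X, dep)
  coefs <- unname(coef(fit))
  coefs[is.na(coefs)] <- 0
  rms <- sqrt(mean(fit$residuals^2))
  structure(
    list(path = path, junction = as.numeric(junction), tip = as.numeric(tip),
         orient = orient, coefs = coefs, a = a, s = s, order = ord, rms = rms),
    class = "leaf_geometry"
  )
}

#' @export
print.leaf_geometry <- function(x, ...) {
  cat("<leaf_geometry> order-", x$order, " fit (", x$orient, "), ",
      nrow(x$path), " points, rms ", signif(x$rms, 3), " px\n", sep = "")
  invisible(x)
}

#' A bare polynomial curve y = p(x)
#'
#' Wraps raw polynomial coefficients (ascending powers: `c0, c1, ...`)
#' into the same representation as a fitted leaf, for analytic checks and
#' direct curvature evaluation.
#'
#' @param coefs ascending-power coefficients.
#' @export
poly_curve <- function(coefs) {
  structure(
    list(path = NULL, junction = NULL, tip = NULL, orient = "y_of_x",
         coefs = as.numeric(coefs), a = 0, s = 1,
         order = length(coefs) - 1, rms = 0),
    class = "leaf_geometry"
  )
}

geom_u <- function(geom, at) (at - geom$a) / geom$s

geom_ind <- function(geom, point) {
  unname(if (geom$orient == "y_of_x") point[1] else point[2])
}

# first and second derivative of the dependent w.r.t. the independent axis
geom_slope <- function(geom, at) {
  poly_eval(poly_deriv_coefs(geom$coefs), geom_u(geom, at)) / geom$s
}

geom_second <- function(geom, at) {
  poly_eval(poly_deriv_coefs(poly_deriv_coefs(geom$coefs)), geom_u(geom, at)) / geom$s^2
}

#' Leaf length: arc length of the fitted curve
#'
#' Numerically integrates sqrt(1 + (dy/dx)^2) between the junction and tip
#' abscissae of the fitted polynomial.
#'
#' @param geom a [fit_leaf_curve()] result.
#' @param rel_tol quadrature relative tolerance.
#' @return length in px.
#' @export
leaf_length <- function(geom, rel_tol = 1e-6) {
  x1 <- geom_ind(geom, geom$junction); x2 <- geom_ind(geom, geom$tip)
  if (isTRUE(all.equal(x1, x2)))
    abort("junction and tip share an abscissa; orientation should have flipped",
          class = "degenerate_leaf")
  u1 <- geom_u(geom, x1); u2 <- geom_u(geom, x2)
  d1 <- poly_deriv_coefs(geom$coefs)
  f <- function(u) sqrt(1 + (poly_eval(d1, u) / geom$s)^2)
  abs(integrate(f, u1, u2, rel.tol = rel_tol, subdivisions = 400L)$value * geom$s)
}

#' Junction-tip distance (the chord)
#'
#' @param junction,tip `(x, y)` points.
#' @return Euclidean distance in px.
#' @export
junction_tip_distance <- function(junction, tip) {
  sqrt(sum((as.numeric(tip) - as.numeric(junction))^2))
}

#' Curvature of the fitted curve at an abscissa
#'
#' K = |y''| / (1 + y'^2)^(3/2); the radius of curvature is 1/K (an
#' infinite radius is reported as K = 0).
#'
#' @param geom a [fit_leaf_curve()] or [poly_curve()].
#' @param at abscissa on the independent axis, px.
#' @return curvature in 1/px.
#' @export
curvature_at <- function(geom, at) {
  d1 <- geom_slope(geom, at); d2 <- geom_second(geom, at)
  abs(d2) / (1 + d1^2)^1.5
}

#' Leaf apex: path points farthest from the junction-tip chord
#'
#' The signed perpendicular distance of every path point from the
#' junction-tip line is computed and the points attaining the maximal
#' absolute distance are returned (a leaf may have several apices).
#'
#' @param geom a [fit_leaf_curve()].
#' @param tol ties within `tol` of the maximum all count as apices.
#' @return list with `points` (matrix of apex `(x, y)`), `indices` into the
#'   path, `distance` (the maximal |perpendicular distance|) and
#'   `degenerate` (`TRUE` for a straight leaf, where every point is at
#'   distance 0).
#' @export
leaf_apex <- function(geom, tol = 1e-6) {
  if (nrow(geom$path) < 3) abort("at least 3 path points required", class = "insufficient_points")
  j <- geom$junction; t <- geom$tip
  den <- sqrt(sum((t - j)^2))
  if (den == 0) abort("junction equals tip: chord undefined", class = "undefined_chord")
  x0 <- geom$path[, 1]; y0 <- geom$path[, 2]
  dist <- ((t[2] - j[2]) * x0 - (t[1] - j[1]) * y0 + t[1] * j[2] - t[2] * j[1]) / den
  mx <- max(abs(dist))
  degenerate <- mx <= tol
  idx <- if (degenerate) seq_along(dist) else which(abs(dist) >= mx - tol)
  list(points = geom$path[idx, , drop = FALSE], indices = idx,
       distance = mx, degenerate = degenerate)
}

#' Mid-leaf point
#'
#' The b-th path point with b = floor(n/2) (1-based, clamped to 1),
#' evaluated on the fitted curve at that point's abscissa.
#'
#' @param geom a [fit_leaf_curve()].
#' @return list with `index`, `point` (`(x, y)` on the fitted curve) and
#'   `abscissa` on the independent axis.
#' @export
mid_leaf <- function(geom) {
  n <- nrow(geom$path)
  b <- max(1L, as.integer(floor(n / 2)))
  at <- geom_ind(geom, geom$path[b, ])
  dep <- poly_eval(geom$coefs, geom_u(geom, at))
  pt <- if (geom$orient == "y_of_x") c(at, dep) else c(dep, at)
  list(index = b, point = pt, abscissa = at)
}

#' Angle between two slopes
#'
#' theta = |atan((m2 - m1) / (1 + m1 m2))|, with theta = pi/2 when the
#' lines are perpendicular (1 + m1 m2 = 0).
#'
#' @param m1,m2 line slopes.
#' @return angle in radians, in `[0, pi/2]`.
#' @export
angle_between_slopes <- function(m1, m2) {
  den <- 1 + m1 * m2
  if (abs(den) < 1e-12) return(pi / 2)
  abs(atan((m2 - m1) / den))
}

#' Leaf-junction angle
#'
#' Angle between the tangent of the fitted leaf at the junction and the
#' junction-tip chord, reported in `[0, pi/2]` radians.  Computed from
#' direction vectors so that x(y)-oriented fits are handled identically.
#'
#' @param geom a [fit_leaf_curve()].
#' @return radians.
#' @export
leaf_junction_angle <- function(geom) {
  j <- geom$junction; t <- geom$tip
  if (all(j == t)) abort("junction equals tip: chord undefined", class = "undefined_chord")
  sl <- geom_slope(geom, geom_ind(geom, j))
  tangent <- if (geom$orient == "y_of_x") c(1, sl) else c(sl, 1)
  chord <- t - j
  cr <- tangent[1] * chord[2] - tangent[2] * chord[1]
  dt <- sum(tangent * chord)
  atan2(abs(cr), abs(dt))
}

#' Integral leaf-skeleton area
#'
#' Area enclosed between the fitted leaf curve and the junction-tip chord:
#' |integral of (p(x) - f(x)) dx| between the tip and junction abscissae,
#' with f the chord line.  Large values relative to the chord indicate
#' drooping.
#'
#' @param geom a [fit_leaf_curve()].
#' @return area in px^2.
#' @export
integral_leaf_skeleton_area <- function(geom) {
  x1 <- geom_ind(geom, geom$junction); x2 <- geom_ind(geom, geom$tip)
  if (isTRUE(all.equal(x1, x2))) abort("degenerate leaf: equal abscissae", class = "degenerate_leaf")
  yj <- poly_eval(geom$coefs, geom_u(geom, x1))
  yt <- poly_eval(geom$coefs, geom_u(geom, x2))
  u1 <- geom_u(geom, x1); u2 <- geom_u(geom, x2)
  # chord in the scaled variable: linear from (u1, yj) to (u2, yt)
  m <- (yt - yj) / (u2 - u1)
  chord_coefs <- c(yj - m * u1, m)
  diff_coefs <- geom$coefs
  diff_coefs[1:2] <- diff_coefs[1:2] - chord_coefs
  anti <- poly_integral_coefs(diff_coefs)
  abs((poly_eval(anti, u2) - poly_eval(anti, u1)) * geom$s)
}

#' Stem angle from junction coordinates
#'
#' The stem axis is the least-squares line through all junctions, with the
#' horizontal coordinate regressed on the vertical one so that a perfectly
#' vertical stem has slope zero; the stem angle is |atan(slope)|, the
#' deviation of the stem axis from the vertical.
#'
#' @param junctions matrix or data frame with columns `x`, `y` (>= 2 rows).
#' @return angle in radians, in `[0, pi/2)`.
#' @export
stem_angle <- function(junctions) {
  junctions <- as.data.frame(junctions)
  if (nrow(junctions) < 2)
    abort("at least 2 junctions required for the stem angle", class = "insufficient_junctions")
  y <- junctions$y - mean(junctions$y)
  if (all(abs(y) < 1e-12)) return(pi / 2)  # all junctions at one height
  m <- sum(y * (junctions$x - mean(junctions$x))) / sum(y^2)
  abs(atan(m))
}

# ---- per-frame phenotype records -------------------------------------------

#' Leaf geometries of a typed plant graph
#'
#' @param g typed [plant_graph].
#' @param max_order polynomial order cap for [fit_leaf_curve()].
#' @return list of `leaf_geometry` objects, one per leaf edge (leaves
#'   whose paths are too short to fit are skipped).
#' @export
leaf_geometries <- function(g, max_order = 4) {
  ed <- g$edges[g$edges$kind == "LEAF", , drop = FALSE]
  kind_of <- setNames(g$nodes$kind, g$nodes$node_id)
  out <- list()
  for (i in seq_len(nrow(ed))) {
    e <- ed[i, ]
    tip_id <- if (kind_of[as.character(e$to)] == "TIP") e$to else e$from
    jn_id <- if (tip_id == e$to) e$from else e$to
    jn <- g$nodes[g$nodes$node_id == jn_id, ]
    p <- orient_path(e$path[[1]], jn$row, jn$col)  # junction -> tip
    path_xy <- cbind(x = p[, 2], y = p[, 1])
    if (nrow(path_xy) < 3) next
    geom <- tryCatch(fit_leaf_curve(path_xy), error = function(e) NULL)
    if (is.null(geom)) next
    geom$edge_id <- e$edge_id
    out[[length(out) + 1L]] <- geom
  }
  out
}

#' Component phenotypes of one frame
#'
#' @param g typed [plant_graph].
#' @param plant_id,day identifiers copied into the output.
#' @return tibble with one row per detected leaf: fitted leaf length,
#'   junction-tip distance, apex and mid-leaf curvature, leaf-junction
#'   angle, integral leaf-skeleton area, and the apex coordinates.
#' @export
component_phenotypes <- function(g, plant_id = NA_character_, day = NA_integer_) {
  geoms <- leaf_geometries(g)
  purrr::map_dfr(geoms, function(geom) {
    safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
    apex <- tryCatch(leaf_apex(geom), error = function(e) NULL)
    apex_curv <- if (!is.null(apex) && !apex$degenerate) {
      safe(curvature_at(geom, geom_ind(geom, apex$points[1, ])))
    } else if (!is.null(apex)) 0 else NA_real_
    ml <- mid_leaf(geom)
    tibble::tibble(
      plant_id = plant_id, day = day, edge_id = geom$edge_id,
      leaf_length = safe(leaf_length(geom)),
      junction_tip_distance = junction_tip_distance(geom$junction, geom$tip),
      apex_curvature = apex_curv,
      mid_leaf_curvature = safe(curvature_at(geom, ml$abscissa)),
      leaf_junction_angle = safe(leaf_junction_angle(geom)),
      integral_area = safe(integral_leaf_skeleton_area(geom)),
      apex_x = if (!is.null(apex)) apex$points[1, 1] else NA_real_,
      apex_y = if (!is.null(apex)) apex$points[1, 2] else NA_real_,
      n_apex = if (!is.null(apex)) nrow(apex$points) else NA_integer_,
      tip_x = geom$tip[1], tip_y = geom$tip[2],
      junction_x = geom$junction[1], junction_y = geom$junction[2],
      fit_rms = geom$rms
    )
  })
}

#' Stem phenotypes of one frame
#'
#' @inheritParams component_phenotypes
#' @return one-row tibble: number of junctions, stem angle (radians, NA
#'   with fewer than 2 junctions), stem height (px path length from the
#'   base to the top junction) and the mean inter-junction distance.
#' @export
stem_phenotypes <- function(g, plant_id = NA_character_, day = NA_integer_) {
  st <- extract_stem(g)
  nj <- nrow(st$junctions)
  ang <- if (nj >= 2) stem_angle(st$junctions) else NA_real_
  height <- if (nj >= 1) max(st$junctions$dist) else path_length_px(st$path)
  ijd <- if (nj >= 2) mean(diff(st$junctions$dist)) else NA_real_
  tibble::tibble(
    plant_id = plant_id, day = day, n_junctions = nj,
    stem_angle = ang, stem_height = height, mean_inter_junction = ijd
  )
}
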