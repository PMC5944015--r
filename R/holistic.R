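#' Holistic (whole-silhouette) phenotypes
#'
#' Holistic traits treat the segmented plant as a single object.  From the
#' binary silhouette the package measures the convex-hull area (shoelace
#' formula on the hull of pixel centers), the bounding-rectangle height,
#' the minimum-enclosing-circle diameter and the total plant pixel count,
#' and combines them into three scale-invariant ratios: the bi-angular
#' convex-hull area ratio (hull area at the 0-degree view over the
#' 90-degree view, informative about plant rotation and phyllotaxy), the
#' plant aspect ratio (side-view bounding-rectangle height over top-view
#' minimum-enclosing-circle diameter) and the plant aerial density (plant
#' pixels over hull area, a compactness/biomass proxy).
#'
#' @name holistic_phenotypes
NULL

shoelace_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# ---- minimum enclosing circle (Welzl, deterministic order) ------------------

circle2 <- function(a, b) {
  list(center = (a + b) / 2, radius = sqrt(sum((a - b)^2)) / 2)
}

circle3 <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) return(NULL)  # collinear
  ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) + sum(c^2) * (a[2] - b[2])) / d
  uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) + sum(c^2) * (b[1] - a[1])) / d
  ctr <- c(ux, uy)
  list(center = ctr, radius = sqrt(sum((a - ctr)^2)))
}

in_circle <- function(circ, p, eps = 1e-9) {
  sqrt(sum((p - circ$center)^2)) <= circ$radius + eps
}

mec_trivial <- function(R) {
  n <- length(R)
  if (n == 0) return(list(center = c(0, 0), radius = 0))
  if (n == 1) return(list(center = R[[1]], radius = 0))
  if (n == 2) return(circle2(R[[1]], R[[2]]))
  for (i in 1:2) for (j in (i + 1):3) {
    c2 <- circle2(R[[i]], R[[j]])
    k <- setdiff(1:3, c(i, j))
    if (in_circle(c2, R[[k]])) return(c2)
  }
  c3 <- circle3(R[[1]], R[[2]], R[[3]])
  if (is.null(c3)) {
    # collinear: span of the farthest pair
    d12 <- sum((R[[1]] - R[[2]])^2); d13 <- sum((R[[1]] - R[[3]])^2)
    d23 <- sum((R[[2]] - R[[3]])^2)
    mx <- which.max(c(d12, d13, d23))
    pr <- list(c(1, 2), c(1, 3), c(2, 3))[[mx]]
    return(circle2(R[[pr[1]]], R[[pr[2]]]))
  }
  c3
}

welzl <- function(pts, idx, R) {
  if (length(idx) == 0 || length(R) == 3) return(mec_trivial(R))
  p <- pts[idx[1], ]
  D <- welzl(pts, idx[-1], R)
  if (in_circle(D, p)) return(D)
  welzl(pts, idx[-1], c(R, list(p)))
}

#' Minimum enclosing circle of a point set
#'
#' @param pts matrix with columns `(x, y)`.
#' @return list with `center` and `radius`.
#' @export
min_enclosing_circle <- function(pts) {
  pts <- unique(as.matrix(pts))
  if (nrow(pts) == 0) abort("no points", class = "empty_input")
  if (nrow(pts) > 3) {
    hull <- grDevices::chull(pts[, 1], pts[, 2])
    pts <- pts[hull, , drop = FALSE]
  }
  old <- options(expressions = max(5e4, getOption("expressions")))
  on.exit(options(old))
  welzl(pts, seq_len(nrow(pts)), list())
}

#' Silhouette shape metrics
#'
#' The convex hull is taken over pixel *corners* (each foreground pixel
#' contributes its four cell corners), so the hull of a filled convex
#' region equals the covered area exactly and the aerial density of a
#' filled shape is 1; hulls over pixel centers under-cover by about half
#' the perimeter.
#'
#' @param mask nonempty binary matrix.
#' @return one-row tibble: `hull_area` (px^2), `br_height`
#'   (bounding-rectangle row extent, px), `mec_diameter` (px) and
#'   `plant_pixels` (count).
#' @export
shape_metrics <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) abort("empty mask", class = "empty_input")
  x <- c(idx[, 2] - 0.5, idx[, 2] + 0.5, idx[, 2] - 0.5, idx[, 2] + 0.5)
  y <- c(idx[, 1] - 0.5, idx[, 1] - 0.5, idx[, 1] + 0.5, idx[, 1] + 0.5)
  hull <- grDevices::chull(x, y)
  tibble::tibble(
    hull_area = shoelace_area(x[hull], y[hull]),
    br_height = diff(range(y)),
    mec_diameter = 2 * min_enclosing_circle(cbind(x[hull], y[hull]))$radius,
    plant_pixels = nrow(idx)
  )
}

#' Select the side view with the larger convex hull
#'
#' @param area0,area90 convex-hull areas (px^2) at side views 0 and 90.
#' @return 0 or 90 (degrees); ties resolve to 0.
#' @export
select_view <- function(area0, area90) {
  if (area0 < 0 || area90 < 0) abort("areas must be >= 0")
  if (area0 == 0 && area90 == 0) abort("both views empty", class = "empty_input")
  if (area90 > area0) 90 else 0
}

#' Bi-angular convex-hull area ratio
#'
#' @inheritParams select_view
#' @return `area0 / area90`.
#' @export
bi_angular_chr <- function(area0, area90) {
  if (area90 == 0) abort("division by zero: empty 90-degree hull")
  area0 / area90
}

#' Plant aspect ratio
#'
#' @param br_height_side bounding-rectangle height at the side view, px.
#' @param mec_diameter_top minimum-enclosing-circle diameter at the top
#'   view, px.
#' @return the quotient.
#' @export
plant_aspect_ratio <- function(br_height_side, mec_diameter_top) {
  if (mec_diameter_top == 0) abort("division by zero: empty top view")
  br_height_side / mec_diameter_top
}

#' Plant aerial density
#'
#' @param plant_pixels total plant pixel count.
#' @param hull_area convex-hull area at the same view, px^2.
#' @return `plant_pixels / hull_area`.
#' @export
plant_aerial_density <- function(plant_pixels, hull_area) {
  if (hull_area == 0) abort("division by zero: empty hull")
  plant_pixels / hull_area
}

#' Holistic phenotype record for one imaging day
#'
#' @param mask0,mask90 binary side-view masks (either may be `NULL`).
#' @param top_mask optional binary top-view mask for the plant aspect
#'   ratio denominator.
#' @param plant_id,day identifiers copied into the output.
#' @return one-row tibble: hull areas of both views, the selected view,
#'   and the three holistic ratios (`NA` where an input view is missing).
#' @export
holistic_record <- function(mask0, mask90 = NULL, top_mask = NULL,
                            plant_id = NA_character_, day = NA_integer_) {
  m0 <- if (!is.null(mask0) && any(mask0 != 0)) shape_metrics(mask0) else NULL
  m90 <- if (!is.null(mask90) && any(mask90 != 0)) shape_metrics(mask90) else NULL
  area0 <- if (is.null(m0)) 0 else m0$hull_area
  area90 <- if (is.null(m90)) 0 else m90$hull_area
  sel <- if (area0 == 0 && area90 == 0) NA_real_ else select_view(area0, area90)
  selm <- if (identical(sel, 90)) m90 else m0
  ba <- if (!is.null(m0) && !is.null(m90) && area90 > 0) bi_angular_chr(area0, area90) else NA_real_
  par <- if (!is.null(selm) && !is.null(top_mask) && any(top_mask != 0)) {
    plant_aspect_ratio(selm$br_height, shape_metrics(top_mask)$mec_diameter)
  } else NA_real_
  pad <- if (!is.null(selm)) plant_aerial_density(selm$plant_pixels, selm$hull_area) else NA_real_
  tibble::tibble(
    plant_id = plant_id, day = day,
    cv_area0 = area0, cv_area90 = area90, selected_view = sel,
    ba_chr = ba, par = par, pad = pad
  )
}
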