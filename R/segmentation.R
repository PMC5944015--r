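#' Segmentation of a plant from a fixed background
#'
#' The segmentation pipeline mirrors a fixed-background greenhouse imaging
#' cabinet: the frame is first registered to a plant-free background shot,
#' frame differencing yields a rough foreground, green pixels of the
#' original image are superimposed on it (non-green clutter such as soil
#' or pot film is zeroed), HSV thresholding binarizes the result, and a
#' morphological clean-up keeps a single connected plant region.
#'
#' @name segmentation
NULL

#' HSV threshold ranges
#'
#' Defaults are the plant color band used for greenhouse maize imagery:
#' hue 0.051-0.503, saturation 0.102-0.804, value 0.000-0.786 (all on a
#' 0-1 scale).
#'
#' @param hue,saturation,value `(lo, hi)` ranges in `[0, 1]`.
#' @return an `hsv_ranges` list.
#' @export
hsv_ranges <- function(hue = c(0.051, 0.503),
                       saturation = c(0.102, 0.804),
                       value = c(0.000, 0.786)) {
  for (r in list(hue, saturation, value))
    if (length(r) != 2 || r[1] > r[2]) abort("each range must be (lo, hi) with lo <= hi")
  structure(list(hue = hue, saturation = saturation, value = value),
            class = "hsv_ranges")
}

#' Segmentation configuration
#'
#' @param hsv an [hsv_ranges()].
#' @param register should the frame be registered to the background first?
#'   Off by default; geometry is already aligned for synthetic and
#'   fixed-camera data.
#' @param difference_threshold frame-difference threshold on the max
#'   channel, intensity units in `[0, 1]`.
#' @param green_hue hue sub-interval treated as "green" when
#'   superimposing green pixels.
#' @param erosion_radius,dilation_radius disc radii (px) of the
#'   erosion-then-dilation clean-up.  Equal radii form a morphological
#'   opening, which removes speckle without biasing the stroke width.
#' @param min_component_area smallest surviving component, px^2.
#' @param fill_holes fill small enclosed background holes before component
#'   selection.
#' @param max_hole_area largest hole (px^2) that is filled; larger
#'   enclosed background regions (e.g. a pocket closed off by a drooping
#'   leaf touching the stem) are genuine background and stay open.
#' @return a `segmentation_config` list.
#' @export
segmentation_config <- function(hsv = hsv_ranges(), register = FALSE,
                                difference_threshold = 15 / 255,
                                green_hue = c(0.17, 0.45),
                                erosion_radius = 1, dilation_radius = 1,
                                min_component_area = 50,
                                fill_holes = TRUE, max_hole_area = 100) {
  if (difference_threshold < 0) abort("difference_threshold must be >= 0")
  if (erosion_radius < 0 || dilation_radius < 0) abort("radii must be >= 0")
  structure(
    list(hsv = hsv, register = register,
         difference_threshold = difference_threshold, green_hue = green_hue,
         erosion_radius = erosion_radius, dilation_radius = dilation_radius,
         min_component_area = min_component_area, fill_holes = fill_holes,
         max_hole_area = max_hole_area),
    class = "segmentation_config"
  )
}

#' Read a segmentation configuration from a key-value file
#'
#' Accepts a flat YAML document; every [segmentation_config()] default can
#' be overridden (`hue`, `saturation`, `value` as two-element lists).
#'
#' @param path YAML file path.
#' @export
read_segmentation_config <- function(path) {
  kv <- yaml_load_flat(path)
  hsv <- hsv_ranges(
    hue = kv$hue %||% c(0.051, 0.503),
    saturation = kv$saturation %||% c(0.102, 0.804),
    value = kv$value %||% c(0.000, 0.786)
  )
  segmentation_config(
    hsv = hsv,
    register = kv$register %||% FALSE,
    difference_threshold = kv$difference_threshold %||% (15 / 255),
    green_hue = kv$green_hue %||% c(0.17, 0.45),
    erosion_radius = kv$erosion_radius %||% 1,
    dilation_radius = kv$dilation_radius %||% 1,
    min_component_area = kv$min_component_area %||% 50,
    fill_holes = kv$fill_holes %||% TRUE,
    max_hole_area = kv$max_hole_area %||% 100
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal flat YAML reader (scalars and [a, b] lists), no extra dependency
yaml_load_flat <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) < 3) next
    val <- trimws(m[3])
    if (grepl("^\\[", val)) {
      val <- as.numeric(strsplit(gsub("\\[|\\]", "", val), ",")[[1]])
    } else if (val %in% c("true", "TRUE", "yes")) val <- TRUE
    else if (val %in% c("false", "FALSE", "no")) val <- FALSE
    else if (!is.na(suppressWarnings(as.numeric(val)))) val <- as.numeric(val)
    out[[m[2]]] <- val
  }
  out
}

# ---- registration -----------------------------------------------------------

rgb_to_gray <- function(rgb) {
  0.2989 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

# Harris corner response, vectorized over the whole frame
harris_corners <- function(gray, n_max = 80, window = 2) {
  gx <- (shift_mat(gray, 0, -1) - shift_mat(gray, 0, 1)) / 2
  gy <- (shift_mat(gray, -1, 0) - shift_mat(gray, 1, 0)) / 2
  sxx <- gx * gx; syy <- gy * gy; sxy <- gx * gy
  box <- function(m) {
    acc <- m
    for (k in seq_len(8)) acc <- acc + shift_mat(m, NBR_OFFSETS[k, 1], NBR_OFFSETS[k, 2])
    acc
  }
  sxx <- box(sxx); syy <- box(syy); sxy <- box(sxy)
  resp <- (sxx * syy - sxy^2) - 0.04 * (sxx + syy)^2
  # non-maximum suppression over the 8-neighbourhood
  is_max <- resp > 1e-8
  for (k in seq_len(8)) {
    is_max <- is_max & resp >= shift_mat(resp, NBR_OFFSETS[k, 1], NBR_OFFSETS[k, 2])
  }
  margin <- window + 6
  is_max[c(seq_len(margin), nrow(resp) - seq_len(margin) + 1), ] <- FALSE
  is_max[, c(seq_len(margin), ncol(resp) - seq_len(margin) + 1)] <- FALSE
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(idx)
  ord <- order(resp[is_max], decreasing = TRUE)
  head(idx[ord, , drop = FALSE], n_max)
}

patch_at <- function(gray, r, c, half = 5) {
  p <- gray[(r - half):(r + half), (c - half):(c + half)]
  p <- p - mean(p)
  n <- sqrt(sum(p^2))
  if (n < 1e-12) return(NULL)
  as.vector(p / n)
}

#' Register a frame to its background by local feature matching
#'
#' Detects Harris corners in both rasters, matches normalized patch
#' descriptors by correlation, estimates a similarity transform (scale,
#' rotation, translation) by least squares with one round of outlier
#' rejection, and resamples the image onto the background's grid.
#'
#' @param image,background RGB arrays `[rows, cols, 3]`.
#' @param min_matches minimum number of reliable feature matches.
#' @return the registered RGB array, with attributes `scale`, `rotation`
#'   (radians) and `translation` describing the estimated transform.
#' @export
register_to_background <- function(image, background, min_matches = 3) {
  g1 <- rgb_to_gray(image); g0 <- rgb_to_gray(background)
  c1 <- harris_corners(g1); c0 <- harris_corners(g0)
  if (nrow(c1) < min_matches || nrow(c0) < min_matches)
    abort("registration failure: fewer than 3 reliable feature matches", class = "registration_failure")
  d1 <- purrr::map(seq_len(nrow(c1)), ~ patch_at(g1, c1[.x, 1], c1[.x, 2]))
  d0 <- purrr::map(seq_len(nrow(c0)), ~ patch_at(g0, c0[.x, 1], c0[.x, 2]))
  keep1 <- !purrr::map_lgl(d1, is.null); keep0 <- !purrr::map_lgl(d0, is.null)
  c1 <- c1[keep1, , drop = FALSE]; c0 <- c0[keep0, , drop = FALSE]
  d1 <- do.call(rbind, d1[keep1]); d0 <- do.call(rbind, d0[keep0])
  if (is.null(d1) || is.null(d0) || nrow(c1) < min_matches || nrow(c0) < min_matches)
    abort("registration failure: fewer than 3 reliable feature matches", class = "registration_failure")
  sim <- d1 %*% t(d0)  # correlation of unit-norm patches
  best <- apply(sim, 1, which.max)
  score <- sim[cbind(seq_len(nrow(sim)), best)]
  ok <- score > 0.8
  if (sum(ok) < min_matches)
    abort("registration failure: fewer than 3 reliable feature matches", class = "registration_failure")
  # complex model: background_pt = z * image_pt + t.  Repetitive texture
  # makes many matches wrong, so fit by exhaustive two-point consensus
  # (deterministic RANSAC) and refine on the inliers by least squares.
  zi <- complex(real = c1[ok, 2], imaginary = c1[ok, 1])
  zb <- complex(real = c0[best[ok], 2], imaginary = c0[best[ok], 1])
  m <- length(zi)
  best_inl <- rep(FALSE, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      dz <- zi[i] - zi[j]
      if (Mod(dz) < 5) next
      z2 <- (zb[i] - zb[j]) / dz
      if (Mod(z2) < 0.2 || Mod(z2) > 5) next
      t2 <- zb[i] - z2 * zi[i]
      inl <- Mod(zb - (z2 * zi + t2)) < 3
      if (sum(inl) > sum(best_inl)) best_inl <- inl
    }
  }
  if (sum(best_inl) < min_matches)
    abort("registration failure: fewer than 3 reliable feature matches", class = "registration_failure")
  A <- cbind(zi[best_inl], rep(1 + 0i, sum(best_inl)))
  ab <- qr.solve(A, zb[best_inl])
  z <- unname(ab[1]); tr <- unname(ab[2])
  out <- warp_similarity(image, dim(background)[1:2], z, tr,
                         fill = apply(background, 3, function(ch) ch[1, 1]))
  attr(out, "scale") <- Mod(z)
  attr(out, "rotation") <- Arg(z)
  attr(out, "translation") <- c(Re(tr), Im(tr))
  out
}

# resample image under p_out = z * p_in + t (complex col + i*row), bilinear
warp_similarity <- function(image, out_dim, z, tr, fill = c(0, 0, 0)) {
  nr <- out_dim[1]; nc <- out_dim[2]
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  src <- (complex(real = cols, imaginary = rows) - tr) / z
  sx <- Re(src); sy <- Im(src)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  inside <- x0 >= 1 & y0 >= 1 & x0 < dim(image)[2] & y0 < dim(image)[1]
  out <- array(0, dim = c(nr, nc, 3))
  for (ch in 1:3) {
    pl <- image[, , ch]
    val <- matrix(fill[ch], nr, nc)
    idx <- function(dy, dx) pl[cbind(pmin(pmax(y0 + dy, 1), nrow(pl)),
                                     pmin(pmax(x0 + dx, 1), ncol(pl)))]
    bil <- (1 - fx) * (1 - fy) * idx(0, 0) + fx * (1 - fy) * idx(0, 1) +
      (1 - fx) * fy * idx(1, 0) + fx * fy * idx(1, 1)
    val[inside] <- bil[inside]
    out[, , ch] <- val
  }
  out
}

# ---- pipeline stages --------------------------------------------------------

#' Frame differencing against the background
#'
#' A pixel is foreground iff the maximum absolute channel difference
#' between the aligned frame and the background exceeds `threshold`.
#'
#' @param aligned,background RGB arrays of equal dimension.
#' @param threshold intensity threshold in `[0, 1]`.
#' @return binary matrix.
#' @export
frame_difference <- function(aligned, background, threshold = 15 / 255) {
  if (!all(dim(aligned) == dim(background))) abort("dimension mismatch")
  d <- pmax(abs(aligned[, , 1] - background[, , 1]),
            abs(aligned[, , 2] - background[, , 2]),
            abs(aligned[, , 3] - background[, , 3]))
  matrix(as.numeric(d > threshold), dim(aligned)[1], dim(aligned)[2])
}

#' Superimpose green pixels of the original image onto a rough mask
#'
#' Keeps original pixel values where the rough foreground mask is set and
#' the pixel's hue falls in the green band; all other pixels are zeroed,
#' removing non-green clutter (soil, pot film, lighting residue).
#'
#' @param image RGB array.
#' @param rough_mask binary matrix from [frame_difference()].
#' @param green_hue `(lo, hi)` hue interval regarded as green.
#' @return RGB array with non-plant pixels zeroed.
#' @export
green_superimpose <- function(image, rough_mask, green_hue = c(0.17, 0.45)) {
  if (!all(dim(image)[1:2] == dim(rough_mask))) abort("dimension mismatch")
  hsv <- rgb_to_hsv_array(image)
  keep <- rough_mask > 0 & hsv[, , 1] >= green_hue[1] & hsv[, , 1] <= green_hue[2] &
    hsv[, , 3] > 0
  out <- array(0, dim = dim(image))
  for (ch in 1:3) {
    pl <- image[, , ch]; pl[!keep] <- 0; out[, , ch] <- pl
  }
  out
}

#' HSV thresholding
#'
#' A pixel is set iff hue, saturation and value each fall inside their
#' range.  Pure black pixels (value 0) are never set, so the zeroed pixels
#' of [green_superimpose()] stay background.
#'
#' @param image RGB array.
#' @param hsv an [hsv_ranges()].
#' @return binary matrix.
#' @export
hsv_binarize <- function(image, hsv = hsv_ranges()) {
  a <- rgb_to_hsv_array(image)
  m <- a[, , 1] >= hsv$hue[1] & a[, , 1] <= hsv$hue[2] &
    a[, , 2] >= hsv$saturation[1] & a[, , 2] <= hsv$saturation[2] &
    a[, , 3] >= hsv$value[1] & a[, , 3] <= hsv$value[2] &
    a[, , 3] > 0
  matrix(as.numeric(m), dim(image)[1], dim(image)[2])
}

#' Morphological clean-up of a binary mask
#'
#' Erosion then dilation with disc elements removes speckle, optional
#' hole-filling closes small interior gaps, and only the largest
#' 8-connected component at least `min_component_area` px^2 survives.
#'
#' @param mask binary matrix.
#' @param config a [segmentation_config()].
#' @return binary matrix with exactly one component (or empty).
#' @export
morphological_clean <- function(mask, config = segmentation_config()) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(m)
  # fill small interior holes first: erosion would widen a pinhole through
  # a thin stroke before the dilation could close it again; holes above
  # max_hole_area are genuine enclosed background and stay open
  if (isTRUE(config$fill_holes)) {
    holes <- matrix(as.numeric(EBImage::fillHull(m) > 0 & m == 0), nrow(m), ncol(m))
    if (any(holes > 0)) {
      lab <- label_components(holes)
      sizes <- tabulate(lab[lab > 0])
      keep <- which(sizes <= config$max_hole_area)
      m[matrix(lab %in% keep, nrow(m), ncol(m)) & holes > 0] <- 1
    }
  }
  if (config$erosion_radius > 0) m <- EBImage::erode(m, disc_brush(config$erosion_radius))
  if (config$dilation_radius > 0) m <- EBImage::dilate(m, disc_brush(config$dilation_radius))
  largest_component(m, min_area = config$min_component_area)
}

#' Full plant segmentation
#'
#' Composition of the pipeline stages: (optional) registration, frame
#' differencing, green-pixel superimposition, HSV binarization and
#' morphological clean-up.
#'
#' @param image,background RGB arrays.
#' @param config a [segmentation_config()].
#' @return binary plant mask.
#' @export
segment_plant <- function(image, background, config = segmentation_config()) {
  if (isTRUE(config$register)) {
    image <- tryCatch(
      register_to_background(image, background),
      registration_failure = function(e) {
        warn("registration failed; proceeding unregistered")
        image
      }
    )
  }
  rough <- frame_difference(image, background, config$difference_threshold)
  green <- green_superimpose(image, rough, config$green_hue)
  bin <- hsv_binarize(green, config$hsv)
  morphological_clean(bin, config)
}
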