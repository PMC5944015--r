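#' @importFrom rlang abort warn .data
#' @importFrom stats coef integrate lm median qt quantile runif rnorm setNames vcov
#' @importFrom utils head tail
NULL

# Raster conventions used throughout the package:
#  * a mask is a numeric/logical matrix [rows x cols], 1 = plant;
#  * an RGB raster is an array [rows, cols, 3] with channels in [0, 1];
#  * user-facing coordinates are (x, y) = (column, row), y growing downwards
#    as in image space, so "bottom of the image" means maximal y.

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  src_r <- max(1, 1 - dr):min(nr, nr - dr)
  src_c <- max(1, 1 - dc):min(nc, nc - dc)
  if (length(src_r) == 0 || length(src_c) == 0) return(out)
  out[src_r + dr, src_c + dc] <- m[src_r, src_c]
  out
}

# offsets of the 8-neighbourhood, clockwise from north
NBR_OFFSETS <- cbind(
  dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
  dc = c(0, 1, 1, 1, 0, -1, -1, -1)
)

neighbor_count <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  acc <- matrix(0, nrow(m), ncol(m))
  for (k in seq_len(8)) {
    acc <- acc + shift_mat(m, NBR_OFFSETS[k, 1], NBR_OFFSETS[k, 2])
  }
  acc
}

disc_brush <- function(radius) {
  if (radius <= 0) return(matrix(1, 1, 1))
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

#' Label 8-connected components of a binary mask
#'
#' @param mask binary matrix.
#' @return integer matrix of component labels (0 = background).
#' @keywords internal
label_components <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(matrix(0L, nrow(m), ncol(m)))
  lab <- EBImage::bwlabel(m)  # 4-connected; merge labels touching diagonally
  nlab <- max(lab)
  if (nlab <= 1) return(matrix(as.integer(lab), nrow(m), ncol(m)))
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  for (k in c(2, 4, 6, 8)) {  # diagonal offsets
    sh <- shift_mat(lab, NBR_OFFSETS[k, 1], NBR_OFFSETS[k, 2])
    touch <- lab > 0 & sh > 0 & lab != sh
    if (any(touch)) {
      pairs <- unique(cbind(lab[touch], sh[touch]))
      for (r in seq_len(nrow(pairs))) unite(pairs[r, 1], pairs[r, 2])
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(roots, unique(roots))
  out <- matrix(0L, nrow(m), ncol(m))
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

count_components <- function(mask) {
  lab <- label_components(mask)
  max(lab)
}

largest_component <- function(mask, min_area = 0) {
  lab <- label_components(mask)
  if (max(lab) == 0) return(matrix(0, nrow(mask), ncol(mask)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  if (sizes[keep] < min_area) return(matrix(0, nrow(mask), ncol(mask)))
  matrix(as.numeric(lab == keep), nrow(mask), ncol(mask))
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b binary matrices of equal dimension.
#' @return scalar in \[0, 1\]; 1 for two empty masks.
#' @export
mask_iou <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  a <- a != 0; b <- b != 0
  un <- sum(a | b)
  if (un == 0) return(1)
  sum(a & b) / un
}

rgb_to_hsv_array <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] >= 3)
  hsv <- grDevices::rgb2hsv(
    r = as.vector(rgb[, , 1]), g = as.vector(rgb[, , 2]), b = as.vector(rgb[, , 3]),
    maxColorValue = 1
  )
  array(c(hsv[1, ], hsv[2, ], hsv[3, ]), dim = c(dim(rgb)[1], dim(rgb)[2], 3))
}

hsv_to_rgb_triple <- function(h, s, v) {
  as.vector(grDevices::col2rgb(grDevices::hsv(h, s, v))) / 255
}

#' Read / write rasters
#'
#' Thin wrappers over [EBImage::readImage()] that convert between EBImage's
#' width-by-height layout and this package's row-by-column matrices.
#'
#' @param path file path (PNG or JPEG).
#' @return `read_image_rgb()` returns an array `[rows, cols, 3]`;
#'   `read_mask()` a binary matrix.
#' @export
read_image_rgb <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 2) {
    g <- t(as.matrix(img))
    return(array(rep(g, 3), dim = c(dim(g), 3)))
  }
  arr <- array(0, dim = c(d[2], d[1], 3))
  for (ch in 1:3) arr[, , ch] <- t(img[, , ch])
  arr
}

#' @rdname read_image_rgb
#' @export
read_mask <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  m <- if (length(d) == 2) t(as.matrix(img)) else t(as.matrix(img[, , 1]))
  matrix(as.numeric(m > 0.5), nrow(m), ncol(m))
}

#' @rdname read_image_rgb
#' @param rgb RGB array `[rows, cols, 3]`.
#' @export
write_image_rgb <- function(rgb, path) {
  d <- dim(rgb)
  img <- EBImage::Image(dim = c(d[2], d[1], 3), colormode = "Color")
  for (ch in 1:3) img[, , ch] <- t(rgb[, , ch])
  EBImage::writeImage(img, path)
  invisible(path)
}

#' @rdname read_image_rgb
#' @param mask binary matrix.
#' @export
write_mask <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)))), path)
  invisible(path)
}
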