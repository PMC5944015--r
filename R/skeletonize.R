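#' Skeletonization of a binary plant mask
#'
#' Reduces the plant region to one-pixel-wide 8-connected curves by
#' iterative thinning (Zhang-Suen subiterations applied over whole-frame
#' matrix shifts, so each pass is vectorized), followed by removal of
#' residual 2x2 blocks by deleting simple pixels.  Thinning preserves the
#' connectivity of the input: the skeleton has the same number of
#' connected components as the mask, and every skeleton pixel lies inside
#' the mask.  The backend satisfies only this contract and is swappable.
#'
#' @param mask binary matrix with exactly one 8-connected foreground
#'   component.
#' @return a `skeleton` object: list with `mask` (binary matrix of the
#'   skeleton) and `pixels` (matrix of `(row, col)` skeleton pixels).
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  if (!any(m > 0)) abort("empty mask", class = "empty_input")
  if (count_components(m) != 1)
    abort("mask must have exactly one connected component")
  # thin inside the bounding box only, then re-embed
  rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
  r0 <- max(1, rr[1] - 1); r1 <- min(nrow(m), rr[2] + 1)
  c0 <- max(1, cc[1] - 1); c1 <- min(ncol(m), cc[2] + 1)
  sub <- m[r0:r1, c0:c1, drop = FALSE]
  sub <- thin_guo_hall(sub)
  sub <- thin_complete(sub)
  m[] <- 0
  m[r0:r1, c0:c1] <- sub
  structure(list(mask = m, pixels = which(m > 0, arr.ind = TRUE)),
            class = "skeleton")
}

# neighbours P2..P9 clockwise from north, as whole-matrix shifts
nbr_stack <- function(m) {
  lapply(seq_len(8), function(k)
    shift_mat(m, -NBR_OFFSETS[k, 1], -NBR_OFFSETS[k, 2]))
}

crossing_number <- function(P) {
  A <- matrix(0, nrow(P[[1]]), ncol(P[[1]]))
  for (k in seq_len(8)) {
    nxt <- if (k == 8) 1 else k + 1
    A <- A + (1 - P[[k]]) * P[[nxt]]
  }
  A
}

# Guo-Hall parallel thinning; avoids the two-pixel diagonal staircases
# that two-subiteration Zhang-Suen thinning is prone to.
thin_guo_hall <- function(m) {
  fg <- m > 0
  shl <- function(x, k) {
    out <- matrix(FALSE, nrow(x), ncol(x))
    dr <- -NBR_OFFSETS[k, 1]; dc <- -NBR_OFFSETS[k, 2]
    nr <- nrow(x); nc <- ncol(x)
    sr <- max(1, 1 - dr):min(nr, nr - dr); sc <- max(1, 1 - dc):min(nc, nc - dc)
    out[sr + dr, sc + dc] <- x[sr, sc]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shl(fg, 1); p3 <- shl(fg, 2); p4 <- shl(fg, 3); p5 <- shl(fg, 4)
      p6 <- shl(fg, 5); p7 <- shl(fg, 6); p8 <- shl(fg, 7); p9 <- shl(fg, 8)
      C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
        (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
      N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      n_ok <- N1 >= 2 & N2 >= 2 & (N1 <= 3 | N2 <= 3)
      O <- if (step == 1) (p6 | p7 | !p9) & p8 else (p2 | p3 | !p5) & p4
      del <- fg & C == 1 & n_ok & !O
      if (any(del)) {
        fg[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  matrix(as.numeric(fg), nrow(fg), ncol(fg))
}

# crossing number and neighbour count of one pixel under the current mask
pixel_topology <- function(m, r, c) {
  nb <- vapply(seq_len(8), function(k) {
    rr <- r + NBR_OFFSETS[k, 1]; cc <- c + NBR_OFFSETS[k, 2]
    if (rr < 1 || rr > nrow(m) || cc < 1 || cc > ncol(m)) 0 else m[rr, cc]
  }, numeric(1))
  a <- sum((1 - nb) * nb[c(2:8, 1)])
  list(A = a, B = sum(nb))
}

# Sequential completion: the parallel subiterations can leave two-pixel
# diagonal staircases and small knots near junctions.  Deleting, in fixed
# row-major order, every simple pixel (crossing number 1) that is not a
# curve endpoint (>= 2 neighbours) preserves both connectivity and
# endpoints and converges to a strictly one-pixel-wide skeleton.
thin_complete <- function(m) {
  repeat {
    changed <- FALSE
    idx <- which(m > 0, arr.ind = TRUE)
    ord <- order(idx[, 1], idx[, 2])
    idx <- idx[ord, , drop = FALSE]
    for (i in seq_len(nrow(idx))) {
      r <- idx[i, 1]; c <- idx[i, 2]
      if (m[r, c] == 0) next
      tp <- pixel_topology(m, r, c)
      if (tp$A == 1 && tp$B >= 2) {
        m[r, c] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' @export
print.skeleton <- function(x, ...) {
  cat("<skeleton> ", nrow(x$pixels), " pixels on a ",
      nrow(x$mask), "x", ncol(x$mask), " grid\n", sep = "")
  invisible(x)
}
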