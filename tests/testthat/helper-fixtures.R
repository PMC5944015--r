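# in-code fixtures shared across test files

# a thick Y: vertical trunk splitting into two diagonal branches
y_mask <- function(nr = 80, nc = 80, width = 5) {
  cl <- matrix(0, nr, nc)
  for (r in 40:75) cl[r, 40] <- 1
  for (i in 0:25) {
    cl[40 - i, 40 - i] <- 1
    cl[40 - i, 40 + i] <- 1
  }
  EBImage::dilate(cl, EBImage::makeBrush(width, "disc"))
}

bar_mask <- function(nr = 120, nc = 40, width = 5, len = 100) {
  m <- matrix(0, nr, nc)
  r0 <- (nr - len) %/% 2
  m[r0:(r0 + len - 1), 18:(18 + width - 1)] <- 1
  m
}

# straight thin-line skeleton input (already 1 px)
line_mask <- function(nr = 50, nc = 50) {
  m <- matrix(0, nr, nc)
  m[10:40, 25] <- 1
  m
}

random_gt_plant <- function(k = NULL) {
  if (is.null(k)) k <- sample(0:8, 1)
  leaves <- lapply(seq_len(k), function(i) {
    gt_leaf(i, sample(c("alive", "dead", "missing"), 1),
            tip = sample(0:500, 2), collar = sample(0:500, 2))
  })
  gt_plant(paste0("plant_", sample(1e6, 1)), base = sample(0:500, 2), leaves = leaves)
}

# brute-force maximum one-to-one matching within radius (oracle for greedy)
optimal_match_count <- function(det, gtd, radius) {
  n_d <- nrow(det); n_g <- nrow(gtd)
  if (n_d == 0 || n_g == 0) return(0)
  d <- outer(seq_len(n_d), seq_len(n_g), function(i, j) {
    sqrt((det$tip_x[i] - gtd$tip_x[j])^2 + (det$tip_y[i] - gtd$tip_y[j])^2)
  })
  best <- 0
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  # assign each detected to a gt (or none): enumerate gt subsets/orders
  idx <- seq_len(n_g)
  for (k in 0:min(n_d, n_g)) {
    if (k == 0) next
    combs <- utils::combn(idx, k, simplify = FALSE)
    dcombs <- utils::combn(seq_len(n_d), k, simplify = FALSE)
    for (gc in combs) for (dc in dcombs) for (p in perms(gc)) {
      if (all(d[cbind(dc, p)] <= radius)) best <- max(best, k)
    }
  }
  best
}
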