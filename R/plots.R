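#' Plotting helpers
#'
#' `autoplot()` methods and `plot_*()` functions render the usual
#' diagnostics: the typed plant graph with each leaf in a distinct color,
#' per-leaf growth trajectories, and genotype-effect trajectories with
#' their confidence bars.
#'
#' @name plots
NULL

#' @importFrom ggplot2 autoplot ggplot aes geom_path geom_point geom_line
#'   geom_errorbar geom_hline labs scale_y_reverse coord_fixed theme_minimal
#' @export
ggplot2::autoplot

#' @rdname plots
#' @param object a typed [plant_graph].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.plant_graph <- function(object, ...) {
  g <- object
  ed <- purrr::map_dfr(seq_len(nrow(g$edges)), function(i) {
    p <- g$edges$path[[i]]
    tibble::tibble(
      edge_id = g$edges$edge_id[i],
      kind = g$edges$kind[i] %||% "untyped",
      x = p[, 2], y = p[, 1]
    )
  })
  ed$label <- ifelse(ed$kind == "LEAF", paste0("leaf ", match(ed$edge_id, unique(ed$edge_id[ed$kind == "LEAF"]))), "stem")
  nd <- g$nodes
  ggplot(ed, aes(x = .data$x, y = .data$y, group = .data$edge_id,
                 colour = .data$label)) +
    geom_path(linewidth = 0.8) +
    geom_point(data = nd, aes(x = .data$col, y = .data$row, shape = .data$kind),
               inherit.aes = FALSE, size = 2) +
    scale_y_reverse() + coord_fixed() + theme_minimal() +
    labs(x = "x (px)", y = "y (px)", colour = NULL, shape = NULL)
}

#' @rdname plots
#' @param emergence tibble from [track_emergence()] (with `day`,
#'   `leaf_rank`, `length`).
#' @export
plot_leaf_growth <- function(emergence) {
  ggplot(emergence, aes(x = .data$day, y = .data$length,
                        colour = factor(.data$leaf_rank))) +
    geom_line() + geom_point(size = 1) + theme_minimal() +
    labs(x = "day", y = "leaf skeleton length (px)", colour = "leaf")
}

#' @rdname plots
#' @param series tibble from [genotype_series()].
#' @export
plot_genotype_series <- function(series) {
  ggplot(series, aes(x = .data$day, y = .data$estimate,
                     colour = factor(.data$genotype))) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_line() + geom_point(size = 1) +
    geom_errorbar(aes(ymin = .data$conf_low, ymax = .data$conf_high),
                  width = 0.2, alpha = 0.5) +
    theme_minimal() +
    labs(x = "day", y = "adjusted genotype effect", colour = "genotype")
}

#' Paint a typed graph over a mask as an RGB overlay
#'
#' Leaves are drawn in distinct colors over the silhouette, stem edges in
#' white; useful for the per-frame overlay PNGs.
#'
#' @param mask binary matrix the graph was derived from.
#' @param g typed [plant_graph].
#' @return RGB array `[rows, cols, 3]`.
#' @export
overlay_graph <- function(mask, g) {
  nr <- nrow(mask); nc <- ncol(mask)
  rgb <- array(0, dim = c(nr, nc, 3))
  for (ch in 1:3) rgb[, , ch] <- (mask != 0) * 0.25
  palette <- grDevices::col2rgb(grDevices::hcl.colors(max(1, sum(g$edges$kind == "LEAF")), "Dark 3")) / 255
  li <- 0
  for (i in seq_len(nrow(g$edges))) {
    p <- g$edges$path[[i]]
    colr <- if (identical(g$edges$kind[i], "LEAF")) {
      li <- li + 1
      palette[, ((li - 1) %% ncol(palette)) + 1]
    } else c(1, 1, 1)
    for (ch in 1:3) {
      pl <- rgb[, , ch]
      pl[p] <- colr[ch]
      rgb[, , ch] <- pl
    }
  }
  rgb
}
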