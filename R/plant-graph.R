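#' Typed plant graphs
#'
#' A plant skeleton is represented as a graph P = \{V, E\}: nodes are the
#' base of the plant, leaf tips (degree 1) and junctions (degree >= 3,
#' the collars where leaves join the stem); edges are leaves (one endpoint
#' a tip), inter-junction segments of the stem, and the base segment.
#' `graph_from_skeleton()` builds the raw graph (every skeleton pixel of
#' degree != 2 is a node, maximal degree-2 chains are edge paths),
#' `prune_spurs()` removes short spurious branches and collapses the
#' redundant degree-2 nodes they leave behind, and `classify()` assigns
#' node and edge types.
#'
#' @name plant_graph
NULL

new_plant_graph <- function(nodes, edges, cyclic = FALSE, classified = FALSE,
                            base_id = NA_integer_) {
  structure(
    list(nodes = nodes, edges = edges, cyclic = cyclic,
         classified = classified, base_id = base_id),
    class = "plant_graph"
  )
}

#' @export
print.plant_graph <- function(x, ...) {
  cat("<plant_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges",
      if (x$cyclic) " [cyclic]", if (x$classified) " [typed]", "\n", sep = "")
  if (x$classified) {
    cat("  nodes: ", paste(names(table(x$nodes$kind)), table(x$nodes$kind),
                           sep = "=", collapse = ", "), "\n", sep = "")
    cat("  edges: ", paste(names(table(x$edges$kind)), table(x$edges$kind),
                           sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

path_length_px <- function(path) {
  if (nrow(path) < 2) return(0)
  steps <- abs(diff(path[, 1])) + abs(diff(path[, 2]))
  sum(ifelse(steps == 2, sqrt(2), 1))
}

#' Build the raw graph of a skeleton
#'
#' @param skel a [skeletonize()] result.
#' @return an untyped [plant_graph]; `cyclic` is `TRUE` when the skeleton
#'   contains a cycle (e.g. a leaf crossover), in which case downstream
#'   classification refuses the graph.
#' @export
graph_from_skeleton <- function(skel) {
  m <- skel$mask
  if (!any(m > 0)) abort("empty skeleton", class = "empty_input")
  deg <- neighbor_count(m) * (m > 0)
  nodesel <- m > 0 & deg != 2
  node_idx <- which(nodesel, arr.ind = TRUE)
  pure_cycle <- FALSE
  if (nrow(node_idx) == 0) {  # a pure cycle: seed one artificial node
    first <- which(m > 0, arr.ind = TRUE)[1, , drop = FALSE]
    node_idx <- first
    pure_cycle <- TRUE
  }
  id_mat <- matrix(0L, nrow(m), ncol(m))
  id_mat[node_idx] <- seq_len(nrow(node_idx))

  nbrs_of <- function(r, c) {
    rr <- r + NBR_OFFSETS[, 1]; cc <- c + NBR_OFFSETS[, 2]
    ok <- rr >= 1 & rr <= nrow(m) & cc >= 1 & cc <= ncol(m)
    rr <- rr[ok]; cc <- cc[ok]
    on <- m[cbind(rr, cc)] > 0
    cbind(rr[on], cc[on])
  }
  used <- new.env(parent = emptyenv())
  step_key <- function(a, b) paste(a[1], a[2], b[1], b[2], sep = ",")

  edges <- list()
  for (i in seq_len(nrow(node_idx))) {
    start <- node_idx[i, ]
    for_nb <- nbrs_of(start[1], start[2])
    for (j in seq_len(nrow(for_nb))) {
      q <- for_nb[j, ]
      if (!is.null(used[[step_key(start, q)]])) next
      path <- list(start)
      prev <- start; cur <- q
      while (id_mat[cur[1], cur[2]] == 0L) {
        path[[length(path) + 1L]] <- cur
        nb <- nbrs_of(cur[1], cur[2])
        nxt <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2]), , drop = FALSE]
        if (nrow(nxt) == 0) break  # dead end mid-chain (should not happen)
        if (nrow(nxt) > 1) {
          # prefer 4-connected continuation; thin skeletons rarely hit this
          d4 <- abs(nxt[, 1] - cur[1]) + abs(nxt[, 2] - cur[2]) == 1
          nxt <- nxt[order(!d4), , drop = FALSE]
        }
        prev <- cur; cur <- nxt[1, ]
      }
      path[[length(path) + 1L]] <- cur
      used[[step_key(start, q)]] <- TRUE
      used[[step_key(cur, prev)]] <- TRUE
      pmat <- do.call(rbind, path)
      edges[[length(edges) + 1L]] <- list(
        from = i, to = id_mat[cur[1], cur[2]], path = pmat,
        length = path_length_px(pmat)
      )
    }
  }
  nodes <- tibble::tibble(
    node_id = seq_len(nrow(node_idx)),
    row = as.numeric(node_idx[, 1]), col = as.numeric(node_idx[, 2]),
    degree = 0L, kind = NA_character_
  )
  edges_tb <- if (length(edges) == 0) {
    tibble::tibble(edge_id = integer(), from = integer(), to = integer(),
                   length = numeric(), kind = NA_character_[0],
                   leaf_rank = integer(), path = list())
  } else {
    tibble::tibble(
      edge_id = seq_along(edges),
      from = vapply(edges, `[[`, integer(1), "from"),
      to = vapply(edges, `[[`, numeric(1), "to") |> as.integer(),
      length = vapply(edges, `[[`, numeric(1), "length"),
      kind = NA_character_,
      leaf_rank = NA_integer_,
      path = purrr::map(edges, "path")
    )
  }
  g <- new_plant_graph(nodes, edges_tb)
  g <- recompute_degrees(g)
  g$cyclic <- pure_cycle || (nrow(g$edges) >= nrow(g$nodes) && nrow(g$nodes) > 0)
  if (g$cyclic) warn("skeleton graph contains a cycle (possible leaf crossover)")
  g
}

recompute_degrees <- function(g) {
  deg <- integer(nrow(g$nodes))
  if (nrow(g$edges) > 0) {
    tab <- table(factor(c(g$edges$from, g$edges$to), levels = g$nodes$node_id))
    deg <- as.integer(tab)
  }
  g$nodes$degree <- deg
  g
}

base_node_id <- function(g) {
  nd <- g$nodes
  nd$node_id[order(-nd$row, nd$col)][1]
}

# orient an edge path so it starts at node `at`
orient_path <- function(path, node_row, node_col) {
  if (path[1, 1] == node_row && path[1, 2] == node_col) return(path)
  path[rev(seq_len(nrow(path))), , drop = FALSE]
}

#' Prune spurious skeleton branches
#'
#' An edge with a free (degree-1) endpoint other than the base whose
#' length is at most `threshold` pixels is a spur and is discarded.  The
#' redundant degree-2 nodes this leaves behind are removed by merging
#' their two incident edges, so each leaf or inter-junction ends up as a
#' single edge; junction pairs closer than `threshold` along the skeleton
#' (thinning artifacts of wide junction regions) are contracted.  The
#' whole process iterates to a fixpoint.
#'
#' @param g a raw [plant_graph].
#' @param threshold spur length threshold in px (default 10).
#' @return pruned [plant_graph] without degree-2 nodes.
#' @export
prune_spurs <- function(g, threshold = 10) {
  repeat {
    changed <- FALSE
    g <- recompute_degrees(g)
    base <- base_node_id(g)

    # 0. drop small artifact cycles left by thinning wide junction regions:
    #    short self-loops, and the longer edge of a short parallel pair
    if (nrow(g$edges) > 1) {
      loops <- which(g$edges$from == g$edges$to & g$edges$length <= 2 * threshold)
      if (length(loops) > 0) {
        g$edges <- g$edges[-loops, , drop = FALSE]
        g <- recompute_degrees(g)
        changed <- TRUE
      }
      pk <- paste(pmin(g$edges$from, g$edges$to), pmax(g$edges$from, g$edges$to))
      dup <- pk[duplicated(pk)]
      drop_idx <- integer()
      for (key in unique(dup)) {
        idx <- which(pk == key)
        lens <- g$edges$length[idx]
        if (min(lens) <= 2 * threshold) {
          keep <- idx[which.min(lens)]
          drop_idx <- c(drop_idx, setdiff(idx, keep))
        }
      }
      if (length(drop_idx) > 0) {
        g$edges <- g$edges[-drop_idx, , drop = FALSE]
        g <- recompute_degrees(g)
        changed <- TRUE
      }
    }

    # 1. drop short free-ended edges (never the base end, never the last edge)
    if (nrow(g$edges) > 1) {
      deg <- setNames(g$nodes$degree, g$nodes$node_id)
      is_spur <- vapply(seq_len(nrow(g$edges)), function(i) {
        e <- g$edges[i, ]
        if (e$length > threshold) return(FALSE)
        free_from <- deg[as.character(e$from)] == 1 && e$from != base
        free_to <- deg[as.character(e$to)] == 1 && e$to != base
        free_from || free_to
      }, logical(1))
      if (any(is_spur) && sum(!is_spur) >= 1) {
        g$edges <- g$edges[!is_spur, , drop = FALSE]
        g <- drop_isolated_nodes(g)
        g <- recompute_degrees(g)
        changed <- TRUE
      }
    }

    # 2. collapse redundant degree-2 nodes
    g <- recompute_degrees(g)
    two <- g$nodes$node_id[g$nodes$degree == 2]
    for (n in two) {
      eidx <- which(g$edges$from == n | g$edges$to == n)
      if (length(eidx) != 2) next  # self-loop at n: leave for cycle handling
      e1 <- g$edges[eidx[1], ]; e2 <- g$edges[eidx[2], ]
      nd <- g$nodes[g$nodes$node_id == n, ]
      a <- if (e1$from == n) e1$to else e1$from
      b <- if (e2$from == n) e2$to else e2$from
      p1 <- orient_path(e1$path[[1]], nd$row, nd$col)  # n -> a
      p2 <- orient_path(e2$path[[1]], nd$row, nd$col)  # n -> b
      newpath <- rbind(p1[rev(seq_len(nrow(p1))), , drop = FALSE],
                       p2[-1, , drop = FALSE])          # a -> n -> b
      g$edges$from[eidx[1]] <- a
      g$edges$to[eidx[1]] <- b
      g$edges$path[[eidx[1]]] <- newpath
      g$edges$length[eidx[1]] <- e1$length + e2$length
      g$edges <- g$edges[-eidx[2], , drop = FALSE]
      g$nodes <- g$nodes[g$nodes$node_id != n, , drop = FALSE]
      g <- recompute_degrees(g)
      changed <- TRUE
    }

    # 3. contract short internal edges between junction clusters
    g <- recompute_degrees(g)
    deg <- setNames(g$nodes$degree, g$nodes$node_id)
    internal <- which(vapply(seq_len(nrow(g$edges)), function(i) {
      e <- g$edges[i, ]
      e$from != e$to && e$length <= threshold &&
        deg[as.character(e$from)] >= 3 && deg[as.character(e$to)] >= 3
    }, logical(1)))
    if (length(internal) > 0) {
      i <- internal[1]
      e <- g$edges[i, ]
      keep <- e$from; drop <- e$to
      nk <- g$nodes[g$nodes$node_id == keep, ]
      ndrop <- g$nodes[g$nodes$node_id == drop, ]
      if (ndrop$row > nk$row) { tmp <- keep; keep <- drop; drop <- tmp }
      nk <- g$nodes[g$nodes$node_id == keep, ]
      ndrop <- g$nodes[g$nodes$node_id == drop, ]
      conn <- orient_path(e$path[[1]], nk$row, nk$col)  # keep -> drop
      g$edges <- g$edges[-i, , drop = FALSE]
      touch <- which(g$edges$from == drop | g$edges$to == drop)
      for (j in touch) {
        pj <- orient_path(g$edges$path[[j]], ndrop$row, ndrop$col)
        g$edges$path[[j]] <- rbind(conn, pj[-1, , drop = FALSE])
        g$edges$length[j] <- g$edges$length[j] + e$length
        if (g$edges$from[j] == drop) g$edges$from[j] <- keep
        if (g$edges$to[j] == drop) g$edges$to[j] <- keep
      }
      g$nodes <- g$nodes[g$nodes$node_id != drop, , drop = FALSE]
      g <- recompute_degrees(g)
      changed <- TRUE
    }

    if (!changed) break
  }
  g$cyclic <- nrow(g$edges) >= nrow(g$nodes) && nrow(g$nodes) > 0
  g
}

drop_isolated_nodes <- function(g) {
  used <- unique(c(g$edges$from, g$edges$to))
  base <- base_node_id(g)
  g$nodes <- g$nodes[g$nodes$node_id %in% c(used, base) |
                       g$nodes$node_id %in% used, , drop = FALSE]
  g
}

#' Classify nodes and edges of a pruned graph
#'
#' The base is the bottom-most node (maximal row; ties broken by the
#' leftmost column); remaining degree-1 nodes are tips; nodes of degree 3
#' or more are junctions.  An edge with a tip endpoint is a leaf; the edge
#' incident to the base is the base segment (the start of the stem) unless
#' its other endpoint is a tip, in which case the plant is a pre-junction
#' seedling and the single edge counts as its first leaf; edges between
#' junctions are inter-junctions.
#'
#' @param g pruned [plant_graph].
#' @return the typed graph.
#' @export
classify <- function(g) {
  if (g$cyclic)
    abort("cannot classify a cyclic graph (leaf crossover / self-occlusion)",
          class = "unsupported_topology")
  g <- recompute_degrees(g)
  base <- base_node_id(g)
  g$base_id <- base
  g$nodes$kind <- ifelse(
    g$nodes$node_id == base, "BASE",
    ifelse(g$nodes$degree == 1, "TIP", "JUNCTION")
  )
  kind_of <- setNames(g$nodes$kind, g$nodes$node_id)
  g$edges$kind <- vapply(seq_len(nrow(g$edges)), function(i) {
    e <- g$edges[i, ]
    kf <- kind_of[as.character(e$from)]; kt <- kind_of[as.character(e$to)]
    if (kf == "TIP" || kt == "TIP") return("LEAF")
    if (kf == "BASE" || kt == "BASE") return("BASE_SEGMENT")
    "INTER_JUNCTION"
  }, character(1))
  g$classified <- TRUE
  g
}

#' Count detected leaves
#'
#' @param g typed [plant_graph].
#' @param count_seedling_leaf should the single tip-terminated edge of a
#'   pre-junction seedling count as one leaf?
#' @return integer leaf count.
#' @export
count_leaves <- function(g, count_seedling_leaf = TRUE) {
  if (!g$classified) abort("graph must be classified first")
  leaf <- g$edges$kind == "LEAF"
  if (!count_seedling_leaf) {
    leaf <- leaf & !(g$edges$from == g$base_id | g$edges$to == g$base_id)
  }
  sum(leaf)
}

#' Extract the stem
#'
#' Walks from the base along base-segment and inter-junction edges,
#' visiting junctions in increasing path distance from the base.
#'
#' @param g typed [plant_graph].
#' @return list with `junctions` (tibble of junction coordinates in order,
#'   with cumulative distance) and `path` (pixel path matrix of the stem).
#' @export
extract_stem <- function(g) {
  if (!g$classified) abort("graph must be classified first")
  stem_kinds <- c("BASE_SEGMENT", "INTER_JUNCTION")
  ed <- g$edges[g$edges$kind %in% stem_kinds, , drop = FALSE]
  base <- g$base_id
  bn <- g$nodes[g$nodes$node_id == base, ]
  if (nrow(ed) == 0) {
    # seedling: the stem is the base-incident edge alone
    eidx <- which(g$edges$from == base | g$edges$to == base)
    path <- if (length(eidx) > 0)
      orient_path(g$edges$path[[eidx[1]]], bn$row, bn$col) else
        cbind(bn$row, bn$col)
    return(list(junctions = tibble::tibble(node_id = integer(), x = numeric(),
                                           y = numeric(), dist = numeric()),
                path = path))
  }
  visited <- base
  cur <- base; dist <- 0
  junctions <- list()
  path <- NULL
  repeat {
    nxt_idx <- which((ed$from == cur | ed$to == cur) &
                       !(ed$from %in% visited & ed$to %in% visited))
    if (length(nxt_idx) == 0) break
    # follow the longest continuation (the stem) first
    nxt_idx <- nxt_idx[order(-ed$length[nxt_idx])][1]
    e <- ed[nxt_idx, ]
    nxt <- if (e$from == cur) e$to else e$from
    cn <- g$nodes[g$nodes$node_id == cur, ]
    p <- orient_path(e$path[[1]], cn$row, cn$col)
    path <- if (is.null(path)) p else rbind(path, p[-1, , drop = FALSE])
    dist <- dist + e$length
    nn <- g$nodes[g$nodes$node_id == nxt, ]
    if (nn$kind == "JUNCTION") {
      junctions[[length(junctions) + 1L]] <- tibble::tibble(
        node_id = nxt, x = nn$col, y = nn$row, dist = dist
      )
    }
    visited <- c(visited, nxt)
    cur <- nxt
  }
  list(junctions = dplyr::bind_rows(junctions), path = path)
}

#' Detected leaves of a typed graph
#'
#' @param g typed [plant_graph].
#' @return tibble with one row per leaf edge: `edge_id`, tip and junction
#'   coordinates `(x, y)` and the skeleton path length.
#' @export
leaf_tips <- function(g) {
  if (!g$classified) abort("graph must be classified first")
  ed <- g$edges[g$edges$kind == "LEAF", , drop = FALSE]
  kind_of <- setNames(g$nodes$kind, g$nodes$node_id)
  purrr::map_dfr(seq_len(nrow(ed)), function(i) {
    e <- ed[i, ]
    tip_id <- if (kind_of[as.character(e$to)] == "TIP") e$to else e$from
    jn_id <- if (tip_id == e$to) e$from else e$to
    tn <- g$nodes[g$nodes$node_id == tip_id, ]
    jn <- g$nodes[g$nodes$node_id == jn_id, ]
    tibble::tibble(
      edge_id = e$edge_id, length = e$length,
      tip_x = tn$col, tip_y = tn$row,
      junction_x = jn$col, junction_y = jn$row
    )
  })
}

#' Track leaf emergence across a day sequence
#'
#' Matches detected leaves day to day by proximity: tips first (a tip
#' moves by at most one day's elongation and is unique to its leaf), then
#' collars for any leaf still unmatched.  Collar positions alone are
#' ambiguous because the newest leaf shares its detected collar with the
#' previous junction until the next leaf emerges.  A leaf's rank is the
#' order of its first appearance
#' (ties broken by the lower junction first) and is retained even if the
#' leaf goes missing on a later day.
#'
#' @param graphs list of typed [plant_graph]s, chronologically ordered.
#' @param days imaging day of each graph (defaults to 1..n).
#' @param radius matching radius in px.
#' @return tibble of (day, leaf_rank, tip and junction coordinates,
#'   length) for every detected leaf.
#' @export
track_emergence <- function(graphs, days = seq_along(graphs), radius = 20) {
  stopifnot(length(graphs) == length(days))
  registry <- tibble::tibble(leaf_rank = integer(), junction_x = numeric(),
                             junction_y = numeric(), tip_x = numeric(),
                             tip_y = numeric())
  out <- list()
  for (k in seq_along(graphs)) {
    det <- leaf_tips(graphs[[k]])
    if (nrow(det) == 0) next
    det$leaf_rank <- NA_integer_
    if (nrow(registry) > 0) {
      # pass 1: tip proximity; pass 2: junction proximity
      for (pass in c("tip", "junction")) {
        dx <- outer(det[[paste0(pass, "_x")]], registry[[paste0(pass, "_x")]], `-`)
        dy <- outer(det[[paste0(pass, "_y")]], registry[[paste0(pass, "_y")]], `-`)
        d <- sqrt(dx^2 + dy^2)
        d[!is.na(det$leaf_rank), ] <- Inf
        d[, registry$leaf_rank %in% det$leaf_rank] <- Inf
        repeat {
          if (all(!is.finite(d)) || min(d) > radius) break
          ij <- arrayInd(which.min(d), dim(d))
          det$leaf_rank[ij[1]] <- registry$leaf_rank[ij[2]]
          d[ij[1], ] <- Inf; d[, ij[2]] <- Inf
        }
      }
    }
    newbies <- which(is.na(det$leaf_rank))
    if (length(newbies) > 0) {
      newbies <- newbies[order(-det$junction_y[newbies])]  # lower collar first
      next_rank <- if (nrow(registry) == 0) 1L else max(registry$leaf_rank) + 1L
      det$leaf_rank[newbies] <- seq.int(next_rank, length.out = length(newbies))
    }
    for (i in seq_len(nrow(det))) {
      r <- det$leaf_rank[i]
      row <- tibble::tibble(leaf_rank = r, junction_x = det$junction_x[i],
                            junction_y = det$junction_y[i],
                            tip_x = det$tip_x[i], tip_y = det$tip_y[i])
      if (r %in% registry$leaf_rank) {
        registry[registry$leaf_rank == r, ] <- row
      } else {
        registry <- dplyr::bind_rows(registry, row)
      }
    }
    det$day <- days[k]
    out[[length(out) + 1L]] <- det
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(res)
  dplyr::select(res, "day", "leaf_rank", "length",
                "tip_x", "tip_y", "junction_x", "junction_y")
}

#' Extend leaf tips to the silhouette boundary
#'
#' Thinning retreats from the end of a stroke by about half the stroke
#' width, so the skeleton tip sits short of the silhouette.  Each leaf
#' path is continued from its tip node along the local tangent direction,
#' one pixel at a time, while still inside the mask (at most `max_steps`
#' pixels), restoring the lost tip length.
#'
#' @param g typed [plant_graph].
#' @param mask the binary mask the skeleton came from.
#' @param max_steps maximum extension in px.
#' @return the graph with extended leaf paths, lengths and tip nodes.
#' @export
extend_leaf_tips <- function(g, mask, max_steps = 12) {
  if (!g$classified) abort("graph must be classified first")
  kind_of <- setNames(g$nodes$kind, g$nodes$node_id)
  for (i in which(g$edges$kind == "LEAF")) {
    e <- g$edges[i, ]
    tip_id <- if (kind_of[as.character(e$to)] == "TIP") e$to else e$from
    jn_id <- if (tip_id == e$to) e$from else e$to
    jn <- g$nodes[g$nodes$node_id == jn_id, ]
    p <- orient_path(e$path[[1]], jn$row, jn$col)
    n <- nrow(p)
    if (n < 3) next
    k <- min(6L, n - 1L)
    dirv <- p[n, ] - p[n - k, ]
    nv <- sqrt(sum(dirv^2))
    if (nv < 1e-9) next
    dirv <- dirv / nv
    pos <- as.numeric(p[n, ])
    added <- list()
    for (s in seq_len(max_steps)) {
      cand <- pos + dirv * s
      rr <- round(cand[1]); cc <- round(cand[2])
      if (rr < 1 || rr > nrow(mask) || cc < 1 || cc > ncol(mask)) break
      if (mask[rr, cc] == 0) break
      if (length(added) > 0) {
        lastp <- added[[length(added)]]
        if (lastp[1] == rr && lastp[2] == cc) next
      } else if (p[n, 1] == rr && p[n, 2] == cc) next
      added[[length(added) + 1L]] <- c(rr, cc)
    }
    if (length(added) == 0) next
    ext <- do.call(rbind, added)
    newpath <- rbind(p, ext)
    g$edges$path[[i]] <- newpath
    g$edges$length[i] <- path_length_px(newpath)
    g$nodes$row[g$nodes$node_id == tip_id] <- ext[nrow(ext), 1]
    g$nodes$col[g$nodes$node_id == tip_id] <- ext[nrow(ext), 2]
  }
  g
}

#' Analyze one mask end to end
#'
#' Convenience wrapper: skeletonize, build the raw graph, prune spurs,
#' classify and extend leaf tips to the silhouette boundary.
#'
#' @param mask binary plant mask.
#' @param spur_threshold spur pruning threshold, px.
#' @param extend_tips extend leaf paths to the mask boundary (see
#'   [extend_leaf_tips()]).
#' @return typed [plant_graph].
#' @export
analyze_mask <- function(mask, spur_threshold = 10, extend_tips = TRUE) {
  skel <- skeletonize(mask)
  g <- suppressWarnings(graph_from_skeleton(skel))
  g <- prune_spurs(g, threshold = spur_threshold)
  g <- classify(g)
  if (isTRUE(extend_tips)) g <- extend_leaf_tips(g, mask)
  g
}

#' Serialize a plant graph to JSON
#'
#' @param g a [plant_graph].
#' @param path output file.
#' @export
write_graph_json <- function(g, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    abort("jsonlite is required for JSON serialization")
  doc <- list(
    nodes = g$nodes[, c("node_id", "row", "col", "degree", "kind")],
    edges = lapply(seq_len(nrow(g$edges)), function(i) {
      e <- g$edges[i, ]
      list(edge_id = e$edge_id, from = e$from, to = e$to, length = e$length,
           kind = e$kind, path = unname(apply(e$path[[1]], 1, as.integer, simplify = FALSE)))
    }),
    cyclic = g$cyclic
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
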