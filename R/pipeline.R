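#' End-to-end pipeline over an image-sequence manifest
#'
#' A manifest is a CSV (or tibble) with one row per captured image:
#' columns `plant_id`, `day`, `view`, `image`, `background` and optionally
#' `gt` (ground-truth XML) and `mask` (a reference mask, kept in simulated
#' datasets).  [run_sequence()] segments every frame, selects the side
#' view with the larger convex hull for each day, derives the plant graph
#' of the selected view, computes holistic and component phenotypes,
#' tracks leaf emergence and, where ground truth is present, scores
#' plant-level leaf detection accuracy.
#'
#' @name pipeline
NULL

#' Simulate a dataset on disk
#'
#' Renders `n_plants` seeded synthetic plants over `n_days` daily frames
#' for the requested side views, writes frame PNGs, truth-mask PNGs and
#' ground-truth XML, and a manifest CSV tying them together.  Output is
#' byte-deterministic given `seed`.
#'
#' @param seed integer master seed; per-plant seeds are derived from it.
#' @param n_plants,n_days dataset size (both >= 1).
#' @param out_dir output directory (created if needed).
#' @param views side views to render, subset of `c(0, 90)`.
#' @param n_leaves leaves per plant.
#' @param ranges sampler ranges, see [default_plant_ranges()].
#' @return the manifest tibble (also written to `out_dir/manifest.csv`).
#' @export
simulate_dataset <- function(seed, n_plants, n_days, out_dir,
                             views = c(0, 90), n_leaves = 6,
                             ranges = default_plant_ranges()) {
  if (n_plants < 1 || n_days < 1) abort("n_plants and n_days must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (p in seq_len(n_plants)) {
    spec_seed <- (as.integer(seed) %% 1000000L) * 1000L + p
    spec <- sample_plant_spec(spec_seed, n_leaves = n_leaves, ranges = ranges)
    pdir <- file.path(out_dir, spec$plant_id)
    dir.create(pdir, showWarnings = FALSE)
    bg_path <- file.path(pdir, "background.png")
    write_image_rgb(render_background(spec), bg_path)
    for (d in seq_len(n_days)) {
      for (v in views) {
        fr <- render_frame(spec, d, view = v)
        img <- file.path(pdir, sprintf("day%02d_view%d.png", d, v))
        msk <- file.path(pdir, sprintf("day%02d_view%d_mask.png", d, v))
        gt <- file.path(pdir, sprintf("day%02d_view%d.xml", d, v))
        write_image_rgb(fr$rgb, img)
        write_mask(fr$mask, msk)
        write_gt_xml(fr$truth, gt)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          plant_id = spec$plant_id, day = d, view = v,
          image = img, background = bg_path, gt = gt, mask = msk
        )
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  # the CSV stores paths relative to the dataset root so the tree is
  # relocatable (and byte-identical across runs in different directories)
  rel <- manifest
  prefix <- paste0(out_dir, "/")
  for (col in c("image", "background", "gt", "mask")) {
    hit <- startsWith(rel[[col]], prefix)
    rel[[col]][hit] <- substring(rel[[col]][hit], nchar(prefix) + 1)
  }
  readr::write_csv(rel, file.path(out_dir, "manifest.csv"))
  manifest
}

read_manifest <- function(manifest) {
  if (is.character(manifest)) {
    root <- dirname(manifest)
    manifest <- readr::read_csv(manifest, show_col_types = FALSE)
    for (col in intersect(c("image", "background", "gt", "mask"), names(manifest))) {
      rel <- !is.na(manifest[[col]]) & !grepl("^(/|[A-Za-z]:)", manifest[[col]])
      manifest[[col]][rel] <- file.path(root, manifest[[col]][rel])
    }
  }
  need <- c("plant_id", "day", "view", "image", "background")
  if (!all(need %in% names(manifest)))
    abort(paste0("manifest must have columns: ", paste(need, collapse = ", ")))
  manifest
}

#' Run the full pipeline over a manifest
#'
#' @param manifest manifest tibble or CSV path (see [pipeline]).
#' @param config a [segmentation_config()].
#' @param spur_threshold spur pruning threshold, px.
#' @param match_radius tip matching radius for accuracy scoring, px.
#' @param out_dir optional directory to write `holistic.csv`,
#'   `components.csv`, `stems.csv`, `accuracy.csv`, `emergence.csv` and
#'   `log.csv`.
#' @return list of tibbles: `holistic`, `components`, `stems`,
#'   `emergence`, `accuracy` (per image), `accuracy_summary` (per plant,
#'   plant-level accuracy in both per-image-mean and aggregate form) and
#'   `log` (one line per frame with status and leaf count).
#' @export
run_sequence <- function(manifest, config = segmentation_config(),
                         spur_threshold = 10, match_radius = 15,
                         out_dir = NULL) {
  manifest <- read_manifest(manifest)
  if (nrow(manifest) == 0) abort("empty manifest")
  holistic <- list(); components <- list(); stems <- list()
  accuracy <- list(); log <- list(); emergence <- list()

  for (pid in unique(manifest$plant_id)) {
    mp <- manifest[manifest$plant_id == pid, , drop = FALSE]
    days <- sort(unique(mp$day))
    day_graphs <- list(); graph_days <- integer()
    for (d in days) {
      md <- mp[mp$day == d, , drop = FALSE]
      masks <- list()
      for (i in seq_len(nrow(md))) {
        row <- md[i, ]
        m <- tryCatch({
          img <- read_image_rgb(row$image)
          bg <- read_image_rgb(row$background)
          segment_plant(img, bg, config)
        }, error = function(e) {
          log[[length(log) + 1L]] <<- tibble::tibble(
            plant_id = pid, day = d, view = row$view, status = "read_or_segment_error",
            message = conditionMessage(e), n_leaves = NA_integer_
          )
          NULL
        })
        if (!is.null(m)) masks[[as.character(row$view)]] <- m
      }
      if (length(masks) == 0) next
      m0 <- masks[["0"]]; m90 <- masks[["90"]]
      hrec <- holistic_record(m0, m90, plant_id = pid, day = d)
      holistic[[length(holistic) + 1L]] <- hrec
      sel <- hrec$selected_view
      selmask <- if (identical(sel, 90) && !is.null(m90)) m90 else (m0 %||% m90)
      selview <- if (identical(sel, 90) && !is.null(m90)) 90 else
        (if (!is.null(m0)) 0 else 90)
      g <- tryCatch(
        analyze_mask(selmask, spur_threshold = spur_threshold),
        error = function(e) {
          log[[length(log) + 1L]] <<- tibble::tibble(
            plant_id = pid, day = d, view = selview, status = "unanalyzable",
            message = conditionMessage(e), n_leaves = NA_integer_
          )
          NULL
        }
      )
      if (is.null(g)) next
      components[[length(components) + 1L]] <- component_phenotypes(g, pid, d)
      stems[[length(stems) + 1L]] <- stem_phenotypes(g, pid, d)
      day_graphs[[length(day_graphs) + 1L]] <- g
      graph_days <- c(graph_days, d)
      log[[length(log) + 1L]] <- tibble::tibble(
        plant_id = pid, day = d, view = selview, status = "ok",
        message = "", n_leaves = count_leaves(g)
      )
      # accuracy against ground truth, per annotated view
      if ("gt" %in% names(md)) {
        for (i in seq_len(nrow(md))) {
          row <- md[i, ]
          if (is.na(row$gt) || !nzchar(row$gt)) next
          vmask <- masks[[as.character(row$view)]]
          if (is.null(vmask)) next
          gv <- if (row$view == selview) g else
            tryCatch(analyze_mask(vmask, spur_threshold), error = function(e) NULL)
          if (is.null(gv)) next
          mt <- match_leaves(gv, read_gt_xml(row$gt), radius = match_radius)
          accuracy[[length(accuracy) + 1L]] <- tibble::tibble(
            plant_id = pid, day = d, view = row$view,
            n_d = mt$n_d, n_f = mt$n_f, n_g = mt$n_g
          )
        }
      }
    }
    if (length(day_graphs) > 0) {
      em <- track_emergence(day_graphs, days = graph_days)
      if (nrow(em) > 0) {
        em$plant_id <- pid
        emergence[[length(emergence) + 1L]] <- em
      }
    }
  }

  res <- list(
    holistic = dplyr::bind_rows(holistic),
    components = dplyr::bind_rows(components),
    stems = dplyr::bind_rows(stems),
    emergence = dplyr::bind_rows(emergence),
    accuracy = dplyr::bind_rows(accuracy),
    log = dplyr::bind_rows(log)
  )
  if (nrow(res$accuracy) > 0) {
    res$accuracy_summary <- res$accuracy |>
      dplyr::filter(.data$n_g > 0) |>
      dplyr::group_by(.data$plant_id) |>
      dplyr::summarise(
        n_images = dplyr::n(),
        n_leaves = sum(.data$n_g), detected = sum(.data$n_d),
        false = sum(.data$n_f),
        accuracy_mean = plant_level_accuracy(dplyr::pick(dplyr::everything()), "mean"),
        accuracy_aggregate = plant_level_accuracy(dplyr::pick(dplyr::everything()), "aggregate"),
        .groups = "drop"
      )
  } else {
    res$accuracy_summary <- tibble::tibble()
  }
  if (all(res$log$status != "ok"))
    abort("all frames failed; no analyzable images in the manifest")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(res)) {
      if (nrow(res[[nm]]) > 0) readr::write_csv(res[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
  }
  res
}
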