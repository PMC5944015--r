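#' Ground-truth annotations and leaf-detection accuracy
#'
#' Ground truth follows the UNL-CPPD XML dialect: a `plant` root element
#' with `id`, `base` (children `x`, `y`) and repeated `leaf` elements, each
#' holding `id` (emergence order), `status` (`alive`, `dead` or
#' `missing`), `tip` and `collar` coordinate elements.
#'
#' @name gt_eval
NULL

GT_STATUSES <- c("alive", "dead", "missing")

#' Construct ground-truth records
#'
#' @param leaf_id emergence order, integer >= 1.
#' @param status one of `"alive"`, `"dead"`, `"missing"`.
#' @param tip,collar `(x, y)` pixel coordinates.
#' @return `gt_leaf()` a leaf annotation; `gt_plant()` a plant record.
#' @export
gt_leaf <- function(leaf_id, status, tip, collar) {
  if (leaf_id < 1) abort("leaf_id must be >= 1")
  if (!status %in% GT_STATUSES)
    abort(paste0("unknown leaf status '", status, "'"))
  structure(
    list(leaf_id = as.integer(leaf_id), status = status,
         tip = as.integer(round(tip)), collar = as.integer(round(collar))),
    class = "gt_leaf"
  )
}

#' @rdname gt_leaf
#' @param plant_image_id identifier of the annotated image.
#' @param base `(x, y)` pixel coordinates of the plant base.
#' @param leaves list of [gt_leaf()] records.
#' @export
gt_plant <- function(plant_image_id, base, leaves = list()) {
  ids <- vapply(leaves, `[[`, integer(1), "leaf_id")
  if (anyDuplicated(ids)) abort("leaf ids must be unique")
  structure(
    list(plant_image_id = as.character(plant_image_id),
         base = as.integer(round(base)), leaves = leaves),
    class = "gt_plant"
  )
}

#' Tidy view of a ground-truth plant
#'
#' @param gt a [gt_plant()].
#' @return tibble with one row per annotated leaf.
#' @export
gt_leaves_df <- function(gt) {
  if (length(gt$leaves) == 0) {
    return(tibble::tibble(
      leaf_id = integer(), status = character(),
      tip_x = numeric(), tip_y = numeric(),
      collar_x = numeric(), collar_y = numeric()
    ))
  }
  purrr::map_dfr(gt$leaves, function(l) {
    tibble::tibble(
      leaf_id = l$leaf_id, status = l$status,
      tip_x = l$tip[1], tip_y = l$tip[2],
      collar_x = l$collar[1], collar_y = l$collar[2]
    )
  })
}

xml_point <- function(node, name) {
  el <- xml2::xml_find_first(node, name)
  if (is.na(el)) abort(paste0("schema error: missing <", name, "> element"))
  x <- suppressWarnings(as.numeric(xml2::xml_text(xml2::xml_find_first(el, "x"))))
  y <- suppressWarnings(as.numeric(xml2::xml_text(xml2::xml_find_first(el, "y"))))
  if (is.na(x) || is.na(y))
    abort(paste0("schema error: malformed coordinates in <", name, ">"))
  c(x, y)
}

#' Read and write ground-truth XML
#'
#' `write_gt_xml()` followed by `read_gt_xml()` is the identity on valid
#' records; coordinates are serialized as integer pixel locations and leaf
#' order is preserved as emergence order.
#'
#' @param path path of the XML document (`read_gt_xml()` also accepts an
#'   `xml_document` or a literal XML string).
#' @return `read_gt_xml()` returns a [gt_plant()].
#' @export
read_gt_xml <- function(path) {
  doc <- if (inherits(path, "xml_document")) path else xml2::read_xml(path)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "plant") abort("schema error: root element must be <plant>")
  id_el <- xml2::xml_find_first(root, "id")
  if (is.na(id_el)) abort("schema error: missing <id> element")
  base <- xml_point(root, "base")
  leaves <- purrr::map(xml2::xml_find_all(root, "leaf"), function(lf) {
    lid <- suppressWarnings(as.integer(xml2::xml_text(xml2::xml_find_first(lf, "id"))))
    if (is.na(lid)) abort("schema error: malformed <leaf><id>")
    status <- xml2::xml_text(xml2::xml_find_first(lf, "status"))
    if (!status %in% GT_STATUSES)
      abort(paste0("schema error: unknown leaf status '", status, "'"))
    gt_leaf(lid, status, xml_point(lf, "tip"), xml_point(lf, "collar"))
  })
  gt_plant(xml2::xml_text(id_el), base, leaves)
}

#' @rdname read_gt_xml
#' @param gt a [gt_plant()].
#' @param file optional path; if given the document is written there.
#' @return `write_gt_xml()` returns the `xml_document` (invisibly when
#'   `file` is given).
#' @export
write_gt_xml <- function(gt, file = NULL) {
  doc <- xml2::xml_new_root("plant")
  xml2::xml_add_child(doc, "id", gt$plant_image_id)
  b <- xml2::xml_add_child(doc, "base")
  xml2::xml_add_child(b, "x", as.character(gt$base[1]))
  xml2::xml_add_child(b, "y", as.character(gt$base[2]))
  for (l in gt$leaves) {
    lf <- xml2::xml_add_child(doc, "leaf")
    xml2::xml_add_child(lf, "id", as.character(l$leaf_id))
    xml2::xml_add_child(lf, "status", l$status)
    tp <- xml2::xml_add_child(lf, "tip")
    xml2::xml_add_child(tp, "x", as.character(l$tip[1]))
    xml2::xml_add_child(tp, "y", as.character(l$tip[2]))
    cl <- xml2::xml_add_child(lf, "collar")
    xml2::xml_add_child(cl, "x", as.character(l$collar[1]))
    xml2::xml_add_child(cl, "y", as.character(l$collar[2]))
  }
  if (!is.null(file)) {
    xml2::write_xml(doc, file)
    return(invisible(doc))
  }
  doc
}

#' Match detected leaves against ground truth
#'
#' One-to-one matching on tip coordinates: a detected leaf may pair with
#' any ground-truth tip within `radius`, and the assignment maximizes the
#' number of matched pairs (augmenting-path bipartite matching, closest
#' pairs preferred), so it coincides with the optimal assignment that a
#' brute-force evaluation finds on small instances.  Ground-truth leaves
#' with status `missing` are not matchable and are excluded from the
#' ground-truth count.
#'
#' @param detected tibble of detected leaves with columns `tip_x`, `tip_y`
#'   (e.g. from [leaf_geometries()]), or a typed [plant_graph].
#' @param gt a [gt_plant()].
#' @param radius matching radius in px.
#' @return list with `n_d` (detected count), `n_f` (false detections),
#'   `n_g` (matchable ground-truth leaves) and `matches`, a tibble of
#'   matched pairs and their tip distances.
#' @export
match_leaves <- function(detected, gt, radius = 15) {
  if (inherits(detected, "plant_graph")) detected <- leaf_tips(detected)
  gtd <- gt_leaves_df(gt)
  gtd <- gtd[gtd$status != "missing", , drop = FALSE]
  n_d <- nrow(detected); n_g <- nrow(gtd)
  matches <- tibble::tibble(detected = integer(), gt_leaf_id = integer(), dist = numeric())
  if (n_d > 0 && n_g > 0) {
    d <- outer(seq_len(n_d), seq_len(n_g), function(i, j) {
      sqrt((detected$tip_x[i] - gtd$tip_x[j])^2 + (detected$tip_y[i] - gtd$tip_y[j])^2)
    })
    # maximum bipartite matching by augmenting paths; each detected leaf
    # tries its admissible ground-truth tips nearest first
    match_of_gt <- rep(NA_integer_, n_g)
    try_assign <- function(i, seen) {
      for (j in order(d[i, ])) {
        if (d[i, j] > radius || seen[j]) next
        seen[j] <- TRUE
        if (is.na(match_of_gt[j]) ||
            Recall(match_of_gt[j], seen)) {
          match_of_gt[j] <<- i
          return(TRUE)
        }
      }
      FALSE
    }
    for (i in order(apply(d, 1, min))) {
      if (min(d[i, ]) <= radius) try_assign(i, rep(FALSE, n_g))
    }
    for (j in which(!is.na(match_of_gt))) {
      matches <- dplyr::bind_rows(matches, tibble::tibble(
        detected = match_of_gt[j], gt_leaf_id = gtd$leaf_id[j],
        dist = d[match_of_gt[j], j]
      ))
    }
  }
  list(n_d = n_d, n_f = n_d - nrow(matches), n_g = n_g, matches = matches)
}

#' Plant-level leaf detection accuracy
#'
#' For a sequence of n images with per-image detected count N_d, falsely
#' detected count N_f and ground-truth count N_G, the plant-level accuracy
#' is the mean over images of (N_d - N_f) / N_G.  The `"aggregate"` mode
#' instead reports (sum N_d - sum N_f) / sum N_G, the form in which
#' per-sequence benchmark counts are usually tabulated.
#'
#' @param per_image data frame with columns `n_d`, `n_f`, `n_g`.
#' @param mode `"mean"` (per-image average) or `"aggregate"`.
#' @param drop_empty if `TRUE`, images with `n_g == 0` are excluded;
#'   otherwise they raise an error.
#' @return accuracy ratio.
#' @export
plant_level_accuracy <- function(per_image, mode = c("mean", "aggregate"),
                                 drop_empty = FALSE) {
  mode <- match.arg(mode)
  stopifnot(all(c("n_d", "n_f", "n_g") %in% names(per_image)))
  if (nrow(per_image) == 0) abort("per_image must have at least one row")
  if (any(per_image$n_g == 0)) {
    if (!drop_empty) abort("accuracy undefined for images with zero ground-truth leaves")
    per_image <- per_image[per_image$n_g > 0, , drop = FALSE]
    if (nrow(per_image) == 0) abort("no images with ground-truth leaves left")
  }
  if (mode == "mean") {
    mean((per_image$n_d - per_image$n_f) / per_image$n_g)
  } else {
    (sum(per_image$n_d) - sum(per_image$n_f)) / sum(per_image$n_g)
  }
}

#' Published benchmark counts for the UNL-CPPD maize dataset
#'
#' Per-sequence aggregate leaf counts (ground truth, detected, false) and
#' plant-level accuracies reported for the 13 image sequences of the two
#' UNL-CPPD releases (I: 27 days, crossover-free; II: up to 32 days,
#' including crossovers).
#'
#' @return tibble with columns `plant_sequence`, `dataset`, `n_leaves`,
#'   `detected`, `false`, `accuracy`.
#' @export
cppd_benchmark <- function() {
  path <- system.file("extdata", "unl_cppd_accuracy.csv", package = "shootgraph")
  readr::read_csv(path, show_col_types = FALSE)
}
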