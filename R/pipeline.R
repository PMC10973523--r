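# End-to-end slide scoring: ROI -> detect -> segment -> stain -> score.

# Per-tile cell extraction; returns the cell table in slide coordinates.
process_tile <- function(img, offset_x, offset_y, cfg) {
  dp <- detect_params(sigma = cfg$detect$sigma,
                      min_separation = cfg$detect$min_separation,
                      threshold = cfg$detect$threshold)
  sp <- segment_params(fg_threshold = cfg$segment$fg_threshold,
                       fg_sigma = cfg$segment$fg_sigma,
                       lambda = cfg$segment$lambda,
                       dilation_radius = cfg$segment$dilation_radius)
  pp <- positivity_params(t = cfg$stain$t,
                          dab_od_threshold = cfg$stain$dab_od_threshold)
  pts <- detect_centers(img, dp)
  if (nrow(pts) == 0) return(NULL)
  labels <- point_to_mask(img, pts, sp)
  dil <- dilate_labels(labels, sp$dilation_radius)
  cells <- extract_cells(labels, dil)
  if (nrow(cells) == 0) return(NULL)
  ch <- separate_stains(img)
  brown <- brown_mask(ch, pp)
  ratio <- cell_dab_ratio(dil, brown)
  cells$dab_ratio <- as.numeric(ratio[as.character(cells$id)])
  cells$is_positive <- classify_positive(cells$dab_ratio, pp$t)
  cells$x <- cells$x + offset_x
  cells$y <- cells$y + offset_y
  cells
}

#' Run the full PD-L1 scoring pipeline on a slide directory
#'
#' Executes ROI delineation, per-tile cell detection, point-to-mask
#' segmentation with dilation, stain separation and positivity calls, and
#' the area-ranked TPS* rule, in that order. Deterministic given the
#' configuration. Slides with fewer than `min_cells` detected cells yield
#' a structured unscorable result rather than an error.
#'
#' @param slide_dir tile directory with `manifest.json` (see
#'   [generate_slide()] / [load_slide_tiles()]).
#' @param config a [pipeline_config()].
#' @param annotations optional non-ROI polygons (list of matrices, or a
#'   path to an ASAP XML file). Used when `config$roi$source` is
#'   `"annotation"`; defaults to `<slide_dir>/non_roi.xml` if present.
#' @param output_dir if non-`NULL`, writes `score.json`, `cells.csv` and
#'   `run_log.txt` there.
#' @return list of class `pipeline_result`: `score` (a `slide_score`),
#'   `cells` (per-cell table in slide coordinates), `roi` (the
#'   `roi_mask`), and `config`.
#' @export
run_pipeline <- function(slide_dir, config = pipeline_config(),
                         annotations = NULL,
                         output_dir = config$output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  slide <- load_slide_tiles(slide_dir)
  ts <- slide$tile_size
  grid <- tile_slide(c(slide$cols * ts, slide$rows * ts), ts)

  roi <- if (identical(config$roi$source, "annotation")) {
    if (is.character(annotations)) annotations <- read_asap_annotations(annotations)
    if (is.null(annotations)) {
      xml <- file.path(slide_dir, "non_roi.xml")
      annotations <- if (file.exists(xml)) read_asap_annotations(xml)
                     else list()
    }
    invert_non_roi(annotations, grid$extent, grid,
                   overlap_threshold = config$roi$overlap_threshold)
  } else {
    classify_tiles(slide$tiles,
                   baseline_tile_classifier(
                     min_tissue_fraction = config$roi$min_tissue_fraction,
                     saturation_threshold = config$roi$saturation_threshold),
                   grid = grid)
  }

  cells_list <- list()
  for (t in slide$tiles) {
    if (!roi$labels[t$row + 1, t$col + 1]) next
    cc <- tryCatch(
      process_tile(t$image, t$col * ts, t$row * ts, config),
      error = function(e) stop("stage error in tile r", t$row, "_c", t$col,
                               ": ", conditionMessage(e)))
    if (!is.null(cc)) cells_list[[length(cells_list) + 1]] <- cc
  }
  cells <- if (length(cells_list)) do.call(rbind, cells_list) else
    data.frame(id = integer(0), x = numeric(0), y = numeric(0),
               nucleus_area = numeric(0), dilated_area = numeric(0),
               dab_ratio = numeric(0), is_positive = logical(0))
  cells$id <- seq_len(nrow(cells))
  rownames(cells) <- NULL

  sp <- scoring_params(m = config$score$m, k = config$score$k,
                       t = config$stain$t, cutoffs = config$score$cutoffs,
                       min_cells = config$score$min_cells)
  score <- tps_star(cells, sp)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      unclass(score)[c("tps_star", "tps_traditional", "n_total",
                       "n_after_exclusion", "n_selected",
                       "n_positive_selected", "stratum", "under_k",
                       "scorable", "area_histogram")],
      file.path(output_dir, "score.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
    write.csv(cells, file.path(output_dir, "cells.csv"), row.names = FALSE)
    writeLines(c(
      sprintf("slide: %s", slide_dir),
      sprintf("m=%g k=%d t=%g cutoffs=%s", sp$m, sp$k, sp$t,
              paste(sp$cutoffs, collapse = ",")),
      sprintf("roi source: %s (%d/%d tiles in)", roi$source,
              sum(roi$labels), length(roi$labels)),
      sprintf("rng_seed: %d", config$rng_seed),
      sprintf("cells detected: %d", nrow(cells)),
      sprintf("tps_star: %s",
              ifelse(score$scorable, sprintf("%.4f", score$tps_star),
                     "unscorable (insufficient cells)"))),
      file.path(output_dir, "run_log.txt"))
  }
  structure(list(score = score, cells = cells, roi = roi, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$score)
  invisible(x)
}

#' Positivity overlay for a patch
#'
#' Debug rendering: paints the boundary of every dilated cell region onto
#' the patch, red for PD-L1-positive cells and green for negative ones.
#'
#' @param img RGB patch.
#' @param dilated dilated `label_map`.
#' @param positive logical vector indexed by label id.
#' @return RGB array.
#' @export
positivity_overlay <- function(img, dilated, positive) {
  img <- as_rgb_array(img)
  m <- as_label_matrix(dilated)
  d <- dim(m)
  edge <- m > 0 &
    (rbind(m[-1, , drop = FALSE], 0L) != m |
     rbind(0L, m[-d[1], , drop = FALSE]) != m |
     cbind(m[, -1, drop = FALSE], 0L) != m |
     cbind(0L, m[, -d[2], drop = FALSE]) != m)
  idx <- which(edge)
  is_pos <- positive[m[idx]]
  pos_px <- neg_px <- matrix(FALSE, d[1], d[2])
  pos_px[idx[is_pos %in% TRUE]] <- TRUE
  neg_px[idx[!(is_pos %in% TRUE)]] <- TRUE
  for (k in 1:3) {
    ch <- img[, , k]
    ch[pos_px] <- c(1, 0, 0)[k]
    ch[neg_px] <- c(0, 0.7, 0)[k]
    img[, , k] <- ch
  }
  img
}
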