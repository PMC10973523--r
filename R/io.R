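# Annotation formats, label-map rasters, and pipeline configuration.

#' Read non-ROI polygon annotations (ASAP XML dialect)
#'
#' Parses `Annotations/Annotation/Coordinates/Coordinate` elements with
#' `X`, `Y`, `Order` attributes into polygons in slide pixel coordinates,
#' preserving vertex order.
#'
#' @param path XML file path.
#' @return list of n x 2 matrices (columns `x`, `y`), one per annotation.
#' @export
read_asap_annotations <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("parse error in ", path, ": ", conditionMessage(e)))
  anns <- xml2::xml_find_all(doc, ".//Annotation")
  lapply(anns, function(a) {
    co <- xml2::xml_find_all(a, ".//Coordinate")
    ord <- as.numeric(xml2::xml_attr(co, "Order"))
    x <- as.numeric(xml2::xml_attr(co, "X"))
    y <- as.numeric(xml2::xml_attr(co, "Y"))
    idx <- order(ord)
    cbind(x = x[idx], y = y[idx])
  })
}

#' Write polygons as an ASAP XML annotation file
#'
#' @param polygons list of n x 2 matrices (columns x, y).
#' @param path output path.
#' @param group annotation group name (default "non_roi").
#' @return `path`, invisibly.
#' @export
write_asap_annotations <- function(polygons, path, group = "non_roi") {
  doc <- xml2::xml_new_root("ASAP_Annotations")
  anns <- xml2::xml_add_child(doc, "Annotations")
  for (i in seq_along(polygons)) {
    p <- polygons[[i]]
    a <- xml2::xml_add_child(anns, "Annotation",
                             Name = sprintf("Annotation %d", i - 1),
                             Type = "Polygon", PartOfGroup = group,
                             Color = "#F4FA58")
    co <- xml2::xml_add_child(a, "Coordinates")
    for (j in seq_len(nrow(p))) {
      xml2::xml_add_child(co, "Coordinate", Order = as.character(j - 1),
                          X = format(p[j, 1], digits = 15),
                          Y = format(p[j, 2], digits = 15))
    }
  }
  groups <- xml2::xml_add_child(doc, "AnnotationGroups")
  xml2::xml_add_child(groups, "Group", Name = group, PartOfGroup = "None",
                      Color = "#F4FA58")
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read cell center points (LabelMe JSON dialect)
#'
#' Returns one point per shape with `shape_type == "point"`; other shapes
#' are skipped with a warning.
#'
#' @param path JSON file path.
#' @return data.frame `x`, `y`.
#' @export
read_labelme_points <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$shapes))
    stop("parse error in ", path, ": missing 'shapes' key")
  pts <- lapply(doc$shapes, function(s) {
    if (!identical(s$shape_type, "point")) return(NULL)
    p <- s$points[[1]]
    c(as.numeric(p[[1]]), as.numeric(p[[2]]))
  })
  skipped <- sum(vapply(pts, is.null, TRUE))
  if (skipped > 0)
    warning(skipped, " non-point shape(s) skipped")
  pts <- do.call(rbind, pts)
  if (is.null(pts)) return(data.frame(x = numeric(0), y = numeric(0)))
  data.frame(x = pts[, 1], y = pts[, 2])
}

#' Write cell center points as LabelMe JSON
#'
#' @param points data.frame with `x`, `y`.
#' @param path output path.
#' @param label shape label (default "cell").
#' @return `path`, invisibly.
#' @export
write_labelme_points <- function(points, path, label = "cell") {
  shapes <- lapply(seq_len(nrow(points)), function(i) {
    list(label = label, shape_type = "point",
         points = list(list(points$x[i], points$y[i])))
  })
  jsonlite::write_json(
    list(version = "5.0.1", shapes = shapes,
         imagePath = "", imageHeight = NULL, imageWidth = NULL),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write / read a label map as 16-bit TIFF
#'
#' @param labels a `label_map` (or integer matrix) with values < 65536.
#' @param path file path.
#' @return `write_label_map` returns `path` invisibly; `read_label_map`
#'   returns an integer matrix (registry attributes are not persisted).
#' @export
write_label_map <- function(labels, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for label-map I/O")
  m <- as_label_matrix(labels)
  stopifnot(max(m) < 65536)
  tiff::writeTIFF(t(m) / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for label-map I/O")
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(t(m) * 65535)), ncol(m), nrow(m))
}

#' Load the tiles of a slide directory
#'
#' Reads `manifest.json` and the coordinate-named tiles written by
#' [generate_slide()] (or any tool following the same layout).
#'
#' @param dir slide directory.
#' @return list with `rows`, `cols`, `tile_size`, and `tiles`, a list of
#'   `list(row, col, image)` entries in row-major order.
#' @export
load_slide_tiles <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  tiles <- list()
  for (r in seq_len(man$rows) - 1L) {
    for (cc in seq_len(man$cols) - 1L) {
      path <- file.path(dir, sprintf("tile_r%d_c%d.png", r, cc))
      if (!file.exists(path)) stop("missing tile: ", path)
      tiles[[length(tiles) + 1]] <- list(row = r, col = cc,
                                         image = read_rgb_png(path))
    }
  }
  list(rows = man$rows, cols = man$cols, tile_size = man$tile_size,
       tiles = tiles)
}

# ---- pipeline configuration ------------------------------------------------

#' Pipeline configuration
#'
#' Nested parameter blocks for every stage, each defaulting to the module
#' defaults. Unknown keys are rejected; the structure round-trips
#' losslessly through YAML.
#'
#' @param ... named overrides as nested lists, e.g.
#'   `score = list(k = 1500)`.
#' @return nested list of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(score = list(k = 500, m = 0.06))
#' cfg$score$k
pipeline_config <- function(...) {
  defaults <- list(
    roi = list(tile_size = 256, overlap_threshold = 0.5,
               min_tissue_fraction = 0.02, saturation_threshold = 0.08,
               source = "classifier"),
    detect = list(sigma = 2, min_separation = 6, threshold = 0.15),
    segment = list(fg_threshold = 0.1, fg_sigma = 0.5, lambda = 100,
                   dilation_radius = 3),
    stain = list(t = 0.1, dab_od_threshold = 0.15),
    score = list(m = 0.06, k = 3000, cutoffs = c(5, 50), min_cells = NULL),
    concordance = list(cutoffs = c(5, 50), aggregate = "mean"),
    rng_seed = 0,
    output_dir = NULL)
  overrides <- list(...)
  cfg <- merge_config(defaults, overrides, path = "")
  structure(cfg, class = "pipeline_config")
}

merge_config <- function(base, over, path) {
  for (nm in names(over)) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      stop("unknown configuration key: ", full)
    if (is.list(base[[nm]]) && !is.null(over[[nm]])) {
      if (!is.list(over[[nm]]))
        stop("configuration key ", full, " must be a block")
      base[[nm]] <- merge_config(base[[nm]], over[[nm]], full)
    } else {
      base[nm] <- over[nm]   # [ ] keeps explicit NULLs
    }
  }
  base
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config a `pipeline_config`.
#' @return `read_pipeline_config` returns a validated `pipeline_config`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
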