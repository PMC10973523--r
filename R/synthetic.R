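# Synthetic IHC generator.
#
# Renders PD-L1-like patches: hematoxylin-stained nuclear disks on a near-
# white background, with DAB membrane annuli (possibly partial arcs) around
# positive cells. Colors come from the forward Beer-Lambert model
# RGB = exp(-(OD_bg + c_H * V_H + c_D * V_D)) with the same H-DAB stain
# vectors the stain module inverts, so deconvolution is exact up to 8-bit
# quantization. Three cell classes encode the DLBCL morphology premise:
# tumor B cells are larger than small lymphocytes, and a few oversized
# non-tumor cells (macrophage/endothelial stand-ins) exceed both.

#' Synthetic generator configuration
#'
#' @param patch_size pixels per side of a square patch.
#' @param cells_per_patch target number of cells placed per patch.
#' @param class_mix named proportions of `tumor`, `small_lymphocyte`,
#'   `large_nontumor`; must sum to 1.
#' @param nucleus_radius_range named list of `c(min, max)` nucleus radii in
#'   pixels per class. Tumor radii must exceed small-lymphocyte radii in the
#'   median (the morphology premise the scoring rule relies on).
#' @param positive_fraction named per-class probability that a cell carries
#'   a DAB membrane.
#' @param membrane_intensity_range range of DAB concentrations (OD scale)
#'   sampled per positive cell.
#' @param hematoxylin_range range of nuclear hematoxylin concentrations.
#' @param membrane_thickness_range membrane annulus thickness range, px.
#' @param arc_fraction_range range of the rendered membrane arc fraction;
#'   values below 1 emulate incomplete membranes.
#' @param background_color RGB (0-255) of the unstained background.
#' @param artifact_fraction fraction of slide tiles rendered as non-ROI
#'   artifact (debris/voids) instead of tissue.
#' @param spacing_factor pairwise minimum center distance is
#'   `spacing_factor * (r_i + r_j)`; lower it to emulate crowding.
#' @param rng_seed integer seed; all outputs are deterministic in it.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(patch_size = 256,
                         cells_per_patch = 130,
                         class_mix = c(tumor = 0.45, small_lymphocyte = 0.50,
                                       large_nontumor = 0.05),
                         nucleus_radius_range = list(
                           tumor = c(6, 11),
                           small_lymphocyte = c(3, 5),
                           large_nontumor = c(12, 18)),
                         positive_fraction = c(tumor = 0.30,
                                               small_lymphocyte = 0.10,
                                               large_nontumor = 0.00),
                         membrane_intensity_range = c(0.3, 1.0),
                         hematoxylin_range = c(0.5, 0.9),
                         membrane_thickness_range = c(2, 4),
                         arc_fraction_range = c(0.5, 1.0),
                         background_color = c(244, 242, 246),
                         artifact_fraction = 0,
                         spacing_factor = 1.1,
                         rng_seed = 0) {
  cfg <- structure(
    list(patch_size = patch_size, cells_per_patch = cells_per_patch,
         class_mix = class_mix, nucleus_radius_range = nucleus_radius_range,
         positive_fraction = positive_fraction,
         membrane_intensity_range = membrane_intensity_range,
         hematoxylin_range = hematoxylin_range,
         membrane_thickness_range = membrane_thickness_range,
         arc_fraction_range = arc_fraction_range,
         background_color = background_color,
         artifact_fraction = artifact_fraction,
         spacing_factor = spacing_factor,
         rng_seed = rng_seed),
    class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (length(cfg$patch_size) != 1 || cfg$patch_size <= 0)
    stop("configuration error: patch_size must be a positive scalar")
  if (length(cfg$class_mix) == 0)
    stop("configuration error: class_mix must not be empty")
  if (abs(sum(cfg$class_mix) - 1) > 1e-8)
    stop("configuration error: class_mix must sum to 1")
  cls <- names(cfg$class_mix)
  if (is.null(cls) || !all(cls %in% names(cfg$nucleus_radius_range)))
    stop("configuration error: every class needs a nucleus_radius_range")
  if (!all(cls %in% names(cfg$positive_fraction)))
    stop("configuration error: every class needs a positive_fraction")
  pf <- cfg$positive_fraction
  if (any(pf < 0 | pf > 1))
    stop("configuration error: positive_fraction must lie in [0,1]")
  if (cfg$artifact_fraction < 0 || cfg$artifact_fraction > 1)
    stop("configuration error: artifact_fraction must lie in [0,1]")
  if (all(c("tumor", "small_lymphocyte") %in% cls)) {
    med <- function(r) mean(cfg$nucleus_radius_range[[r]])
    if (!(med("tumor") > med("small_lymphocyte")))
      stop("configuration error: tumor median radius must exceed ",
           "small_lymphocyte median radius")
  }
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "synth_config: %d px patches, ~%d cells, mix {%s}, seed %d\n",
    x$patch_size, x$cells_per_patch,
    paste(sprintf("%s %.2f", names(x$class_mix), x$class_mix), collapse = ", "),
    x$rng_seed))
  invisible(x)
}

# Sample per-cell generative attributes (no placement); used internally and
# for scoring-rule studies where only the label-level population matters.
sample_cell_attributes <- function(cfg, n) {
  cls <- sample(names(cfg$class_mix), n, replace = TRUE, prob = cfg$class_mix)
  rr <- cfg$nucleus_radius_range
  radius <- vapply(cls, function(k) runif(1, rr[[k]][1], rr[[k]][2]), 0)
  pos <- runif(n) < cfg$positive_fraction[cls]
  data.frame(
    class = cls,
    radius = radius,
    is_positive = as.logical(pos),
    h_conc = runif(n, cfg$hematoxylin_range[1], cfg$hematoxylin_range[2]),
    dab_conc = ifelse(pos, runif(n, cfg$membrane_intensity_range[1],
                                 cfg$membrane_intensity_range[2]), 0),
    thickness = runif(n, cfg$membrane_thickness_range[1],
                      cfg$membrane_thickness_range[2]),
    arc_fraction = runif(n, cfg$arc_fraction_range[1],
                         cfg$arc_fraction_range[2]),
    arc_start = runif(n, 0, 2 * pi),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Sample a cell population without rendering
#'
#' Draws per-cell generative labels (class, nucleus radius and analytic
#' area, positivity) from a configuration, with uniform random centers but
#' no spacing constraint and no image. Intended for scoring-rule studies,
#' where only the label-level population matters.
#'
#' @param config a [synth_config()].
#' @param n number of cells (default `config$cells_per_patch`).
#' @param seed seed (default `config$rng_seed`).
#' @return data.frame with columns `id, x, y, class, radius, nucleus_area,
#'   is_positive`.
#' @export
sample_cell_population <- function(config, n = config$cells_per_patch,
                                   seed = config$rng_seed) {
  validate_synth_config(config)
  with_seed(seed, {
    att <- sample_cell_attributes(config, n)
    data.frame(id = seq_len(n),
               x = runif(n, 0, config$patch_size),
               y = runif(n, 0, config$patch_size),
               class = att$class, radius = att$radius,
               nucleus_area = pi * att$radius^2,
               is_positive = att$is_positive,
               stringsAsFactors = FALSE)
  })
}

# Sequential dart-throwing placement under the pairwise spacing rule.
# Returns centers for each attribute row that could be placed.
place_cells <- function(cfg, att) {
  n <- nrow(att)
  size <- cfg$patch_size
  margin <- att$radius + att$thickness + 1
  xs <- ys <- numeric(0)
  rs <- numeric(0)
  keep <- logical(n)
  cx <- cy <- rep(NA_real_, n)
  max_tries <- 60L
  for (i in seq_len(n)) {
    if (2 * margin[i] >= size) next   # cell cannot fit
    for (try in seq_len(max_tries)) {
      x <- runif(1, margin[i], size - margin[i])
      y <- runif(1, margin[i], size - margin[i])
      if (length(xs) == 0 ||
          all((xs - x)^2 + (ys - y)^2 >=
              (cfg$spacing_factor * (rs + att$radius[i]))^2)) {
        xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, att$radius[i])
        keep[i] <- TRUE; cx[i] <- x; cy[i] <- y
        break
      }
    }
  }
  cbind(x = cx, y = cy)[keep, , drop = FALSE] -> pts
  att <- att[keep, , drop = FALSE]
  att$x <- pts[, "x"]; att$y <- pts[, "y"]
  att
}

# Stamp one cell's nucleus and (optionally) membrane into the concentration
# rasters. Rasters are environments so stamping mutates in place.
stamp_cell <- function(env, cell, size) {
  rmax <- cell$radius + cell$thickness
  ix <- max(1, floor(cell$x - rmax)):min(size, ceiling(cell$x + rmax) + 1)
  iy <- max(1, floor(cell$y - rmax)):min(size, ceiling(cell$y + rmax) + 1)
  px <- ix - 0.5   # pixel-center coordinates (0-based pixel ix has center ix+0.5)
  py <- iy - 0.5
  dx <- outer(px - cell$x, rep(1, length(iy)))
  dy <- outer(rep(1, length(ix)), py - cell$y)
  d2 <- dx^2 + dy^2
  nuc <- d2 <= cell$radius^2
  if (any(nuc)) {
    sub <- env$ch[ix, iy]
    sub[nuc] <- pmax(sub[nuc], cell$h_conc)
    env$ch[ix, iy] <- sub
    sub <- env$nuclab[ix, iy]
    sub[nuc & sub == 0L] <- cell$id
    env$nuclab[ix, iy] <- sub
  }
  if (cell$is_positive) {
    ann <- d2 > cell$radius^2 & d2 <= rmax^2
    if (cell$arc_fraction < 1) {
      theta <- (atan2(dy, dx) - cell$arc_start) %% (2 * pi)
      ann <- ann & theta <= 2 * pi * cell$arc_fraction
    }
    if (any(ann)) {
      sub <- env$cd[ix, iy]
      sub[ann] <- pmax(sub[ann], cell$dab_conc)
      env$cd[ix, iy] <- sub
      sub <- env$memb[ix, iy]
      sub[ann] <- TRUE
      env$memb[ix, iy] <- sub
    }
  }
  invisible(NULL)
}

# Forward Beer-Lambert rendering of concentration rasters to quantized RGB.
render_rgb <- function(ch, cd, background_color,
                       stain_matrix = stain_matrix_hdab()) {
  size <- dim(ch)
  od_bg <- -log(pmax(background_color / 255, 1 / 512))
  img <- array(0, c(size[1], size[2], 3))
  for (k in 1:3) {
    od <- od_bg[k] + ch * stain_matrix[k, 1] + cd * stain_matrix[k, 2]
    img[, , k] <- exp(-od)
  }
  quantize8(img)
}

#' Generate one synthetic IHC patch with ground truth
#'
#' Places cells by dart throwing under a pairwise spacing rule, stamps
#' hematoxylin nuclei and DAB membrane annuli into concentration rasters,
#' and renders RGB through the forward Beer-Lambert model. Every rendered
#' cell is recorded in the truth, along with the nucleus label raster and
#' the rendered-membrane raster (pixel-level oracles for segmentation and
#' stain tests).
#'
#' @param config a [synth_config()].
#' @param seed overrides `config$rng_seed` if given.
#' @return list with `image` (RGB array, `[0,1]`, 8-bit quantized) and
#'   `truth`, a `synthetic_truth` object: `cells` data.frame (`id, x, y,
#'   class, radius, nucleus_area, is_positive`, plus render parameters),
#'   `true_tps` (percent positive among tumor cells), `artifact_polygons`
#'   (empty for a patch), `nucleus_labels` (integer raster keyed by cell
#'   id), and `membrane_mask` (logical raster of rendered DAB membrane).
#' @export
#' @examples
#' p <- generate_patch(synth_config(patch_size = 96, cells_per_patch = 15,
#'                                  rng_seed = 7))
#' nrow(p$truth$cells)
generate_patch <- function(config, seed = config$rng_seed) {
  validate_synth_config(config)
  size <- as.integer(config$patch_size)
  with_seed(seed, {
    att <- sample_cell_attributes(config, config$cells_per_patch)
    cells <- place_cells(config, att)
    if (nrow(cells) > 0) cells$id <- seq_len(nrow(cells))
    env <- new.env()
    env$ch <- matrix(0, size, size)
    env$cd <- matrix(0, size, size)
    env$memb <- matrix(FALSE, size, size)
    env$nuclab <- matrix(0L, size, size)
    for (i in seq_len(nrow(cells))) stamp_cell(env, cells[i, ], size)
    img <- render_rgb(env$ch, env$cd, config$background_color)
    cells <- if (nrow(cells) > 0) {
      data.frame(id = cells$id, x = cells$x, y = cells$y,
                 class = cells$class, radius = cells$radius,
                 nucleus_area = pi * cells$radius^2,
                 is_positive = cells$is_positive,
                 h_conc = cells$h_conc, dab_conc = cells$dab_conc,
                 thickness = cells$thickness,
                 arc_fraction = cells$arc_fraction,
                 stringsAsFactors = FALSE)
    } else empty_truth_cells()
    truth <- structure(
      list(cells = cells,
           true_tps = true_tps_from_cells(cells),
           artifact_polygons = list(),
           nucleus_labels = env$nuclab,
           membrane_mask = env$memb,
           patch_size = size),
      class = "synthetic_truth")
    list(image = img, truth = truth)
  })
}

empty_truth_cells <- function() {
  data.frame(id = integer(0), x = numeric(0), y = numeric(0),
             class = character(0), radius = numeric(0),
             nucleus_area = numeric(0), is_positive = logical(0),
             h_conc = numeric(0), dab_conc = numeric(0),
             thickness = numeric(0), arc_fraction = numeric(0),
             stringsAsFactors = FALSE)
}

#' True tumor proportion score of a generated cell table
#'
#' `100 * (positive tumor cells) / (tumor cells)`; `NA` when the table has
#' no tumor cells.
#'
#' @param cells a truth cell data.frame with `class` and `is_positive`.
#' @return percent in `[0, 100]`, or `NA`.
#' @export
true_tps_from_cells <- function(cells) {
  tum <- cells$class == "tumor"
  if (!any(tum)) return(NA_real_)
  100 * sum(cells$is_positive[tum]) / sum(tum)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d cells, true TPS %s, %d artifact polygons\n",
              nrow(x$cells),
              ifelse(is.na(x$true_tps), "NA", sprintf("%.1f%%", x$true_tps)),
              length(x$artifact_polygons)))
  invisible(x)
}

# Debris/void artifact tile: achromatic grey blobs on background -- zero
# saturation, so the baseline ROI classifier and annotations agree on it.
render_artifact_tile <- function(size, seed) {
  with_seed(seed, {
    g <- matrix(0.97, size, size)
    nblob <- sample(6:14, 1)
    for (b in seq_len(nblob)) {
      cx <- runif(1, 0, size); cy <- runif(1, 0, size)
      r <- runif(1, size / 20, size / 5)
      lev <- runif(1, 0.45, 0.85)
      ix <- max(1, floor(cx - r)):min(size, ceiling(cx + r))
      iy <- max(1, floor(cy - r)):min(size, ceiling(cy + r))
      d2 <- outer((ix - 0.5 - cx)^2, rep(1, length(iy))) +
            outer(rep(1, length(ix)), (iy - 0.5 - cy)^2)
      sub <- g[ix, iy]
      sub[d2 <= r^2] <- pmin(sub[d2 <= r^2], lev)
      g[ix, iy] <- sub
    }
    quantize8(array(rep(g, 3), c(size, size, 3)))
  })
}

#' Generate a synthetic slide as a directory of tiles
#'
#' Writes `rows x cols` PNG tiles named `tile_r{row}_c{col}.png`, a
#' `manifest.json`, a `truth.json` sidecar, and a `non_roi.xml` ASAP
#' annotation covering the artifact tiles. A deterministic
#' `round(artifact_fraction * rows * cols)` tiles are rendered as achromatic
#' debris (no cells) and recorded as non-ROI rectangles; the slide-level
#' `true_tps` is computed over the tissue tiles only. A `1 x 1` grid with
#' `artifact_fraction = 0` reproduces [generate_patch()] exactly for the
#' same seed.
#'
#' @param config a [synth_config()]; `patch_size` is the tile size.
#' @param rows,cols grid dimensions (>= 1).
#' @param dir output directory (created; must be writable).
#' @return list of class `synthetic_slide`: `dir`, `rows`, `cols`,
#'   `tile_size`, `truth` (slide-coordinate `synthetic_truth` whose cells
#'   carry `tile_row`/`tile_col`), and `artifact_tiles` (data.frame of
#'   row/col indices).
#' @export
generate_slide <- function(config, rows, cols, dir) {
  validate_synth_config(config)
  stopifnot(rows >= 1, cols >= 1)
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("I/O error: cannot create output directory ", dir)
  size <- as.integer(config$patch_size)
  n_tiles <- rows * cols
  n_art <- round(config$artifact_fraction * n_tiles)
  art_idx <- if (n_art > 0) {
    with_seed(derive_seed(config$rng_seed, 104729),
              sort(sample.int(n_tiles, n_art)))
  } else integer(0)
  cells_all <- list()
  polys <- list()
  art_tiles <- data.frame(row = integer(0), col = integer(0))
  for (r in seq_len(rows) - 1L) {
    for (cc in seq_len(cols) - 1L) {
      idx <- r * cols + cc          # row-major, 0-based
      tseed <- derive_seed(config$rng_seed, idx)
      path <- file.path(dir, sprintf("tile_r%d_c%d.png", r, cc))
      if ((idx + 1L) %in% art_idx) {
        img <- render_artifact_tile(size, tseed)
        x0 <- cc * size; y0 <- r * size
        polys[[length(polys) + 1]] <- cbind(
          x = c(x0, x0 + size, x0 + size, x0),
          y = c(y0, y0, y0 + size, y0 + size))
        art_tiles <- rbind(art_tiles, data.frame(row = r, col = cc))
      } else {
        p <- generate_patch(config, seed = tseed)
        img <- p$image
        if (nrow(p$truth$cells) > 0) {
          tc <- p$truth$cells
          tc$x <- tc$x + cc * size
          tc$y <- tc$y + r * size
          tc$tile_row <- r
          tc$tile_col <- cc
          cells_all[[length(cells_all) + 1]] <- tc
        }
      }
      write_rgb_png(img, path)
    }
  }
  cells <- if (length(cells_all)) do.call(rbind, cells_all) else {
    cbind(empty_truth_cells(),
          data.frame(tile_row = integer(0), tile_col = integer(0)))
  }
  cells$id <- seq_len(nrow(cells))
  truth <- structure(
    list(cells = cells, true_tps = true_tps_from_cells(cells),
         artifact_polygons = polys, patch_size = size),
    class = "synthetic_truth")
  manifest <- list(rows = rows, cols = cols, tile_size = size,
                   rng_seed = config$rng_seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(cells = cells, true_tps = truth$true_tps,
         artifact_tiles = art_tiles),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, na = "null")
  write_asap_annotations(polys, file.path(dir, "non_roi.xml"))
  structure(list(dir = dir, rows = rows, cols = cols, tile_size = size,
                 truth = truth, artifact_tiles = art_tiles),
            class = "synthetic_slide")
}

#' Read the ground-truth sidecar of a generated slide
#'
#' @param dir slide directory written by [generate_slide()].
#' @return list with `cells` data.frame, `true_tps`, `artifact_tiles`.
#' @export
read_slide_truth <- function(dir) {
  x <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  x$true_tps <- x$true_tps %||% NA_real_
  x
}
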