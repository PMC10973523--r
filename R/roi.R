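# ROI delineation at the slide level.
#
# A slide is processed as a grid of tiles; each tile is labelled in-ROI or
# out either by inverting expert non-ROI polygon annotations or by a
# per-tile classifier. Cells are then restricted to in-ROI tiles. Tile
# bounds are half-open [x0, x1) x [y0, y1), 0-based, origin top-left: a
# point on a shared boundary belongs to the tile to its lower-right.

#' Partition a slide extent into a tile grid
#'
#' Tiles are non-overlapping, cover the extent exactly (edge tiles are
#' clipped to the extent and flagged `padded` when the nominal tile
#' overhangs it), and use half-open pixel bounds.
#'
#' @param extent `c(width, height)` of the slide in pixels.
#' @param tile_size tile side in pixels (default 256).
#' @return object of class `tile_grid`: list with `tile_size`, `extent`,
#'   `nrow`, `ncol` and a `tiles` data.frame (`row, col, x0, x1, y0, y1,
#'   padded`), rows in row-major order.
#' @export
#' @examples
#' tile_slide(c(1024, 1024), 256)$nrow
tile_slide <- function(extent, tile_size = 256) {
  if (length(tile_size) != 1 || tile_size <= 0)
    stop("configuration error: tile_size must be positive")
  stopifnot(length(extent) == 2, all(extent > 0))
  w <- extent[1]; h <- extent[2]
  ncol <- max(1L, as.integer(ceiling(w / tile_size)))
  nrow <- max(1L, as.integer(ceiling(h / tile_size)))
  g <- expand.grid(col = seq_len(ncol) - 1L, row = seq_len(nrow) - 1L)
  tiles <- data.frame(
    row = g$row, col = g$col,
    x0 = g$col * tile_size, x1 = pmin((g$col + 1) * tile_size, w),
    y0 = g$row * tile_size, y1 = pmin((g$row + 1) * tile_size, h))
  tiles$padded <- (g$col + 1) * tile_size > w | (g$row + 1) * tile_size > h
  structure(list(tile_size = tile_size, extent = c(w, h),
                 nrow = nrow, ncol = ncol, tiles = tiles),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("tile_grid: %d x %d tiles of %d px over %g x %g px\n",
              x$nrow, x$ncol, x$tile_size, x$extent[1], x$extent[2]))
  invisible(x)
}

# ROI mask constructor: labels is an nrow x ncol logical matrix, TRUE = in.
new_roi_mask <- function(labels, grid, source = "unknown") {
  stopifnot(is.matrix(labels), is.logical(labels),
            nrow(labels) == grid$nrow, ncol(labels) == grid$ncol)
  structure(list(labels = labels, grid = grid, source = source),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask (%s): %d/%d tiles in-ROI\n", x$source,
              sum(x$labels), length(x$labels)))
  invisible(x)
}

# Even-odd (crossing-number) point-in-polygon test, vectorized over points.
# Self-intersecting rings are filled by the even-odd rule.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4) return(FALSE)
  seg <- cbind(poly, poly[c(2:n, 1), ])
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next
      p <- seg[i, ]; q <- seg[j, ]
      d1 <- cross(p[3] - p[1], p[4] - p[2], q[1] - p[1], q[2] - p[2])
      d2 <- cross(p[3] - p[1], p[4] - p[2], q[3] - p[1], q[4] - p[2])
      d3 <- cross(q[3] - q[1], q[4] - q[2], p[1] - q[1], p[2] - q[2])
      d4 <- cross(q[3] - q[1], q[4] - q[2], p[3] - q[1], p[4] - q[2])
      if (d1 * d2 < 0 && d3 * d4 < 0) return(TRUE)
    }
  }
  FALSE
}

#' Invert non-ROI polygon annotations into a tile-level ROI mask
#'
#' A tile is out-of-ROI iff the fraction of its pixel centers lying inside
#' the union of the annotated polygons exceeds `overlap_threshold`; the ROI
#' is the complement. Self-intersecting polygons are filled by the even-odd
#' rule with a warning.
#'
#' @param polygons list of polygons (each an n x 2 matrix of slide-pixel
#'   x, y vertices).
#' @param extent slide extent `c(width, height)` in pixels.
#' @param tile_size tile side in pixels, or a `tile_grid`.
#' @param overlap_threshold fraction above which a tile is marked out
#'   (default 0.5).
#' @return a `roi_mask`.
#' @export
invert_non_roi <- function(polygons, extent, tile_size = 256,
                           overlap_threshold = 0.5) {
  grid <- if (inherits(tile_size, "tile_grid")) tile_size
          else tile_slide(extent, tile_size)
  labels <- matrix(TRUE, grid$nrow, grid$ncol)
  if (length(polygons) == 0) return(new_roi_mask(labels, grid, "annotation"))
  for (p in polygons) {
    if (polygon_self_intersects(p))
      warning("self-intersecting non-ROI polygon; filled by even-odd rule")
  }
  bbs <- lapply(polygons, function(p)
    c(min(p[, 1]), max(p[, 1]), min(p[, 2]), max(p[, 2])))
  for (i in seq_len(nrow(grid$tiles))) {
    tl <- grid$tiles[i, ]
    hit <- which(vapply(bbs, function(b)
      b[2] > tl$x0 && b[1] < tl$x1 && b[4] > tl$y0 && b[3] < tl$y1, TRUE))
    if (length(hit) == 0) next
    xs <- seq(tl$x0, tl$x1 - 1) + 0.5
    ys <- seq(tl$y0, tl$y1 - 1) + 0.5
    px <- rep(xs, times = length(ys))
    py <- rep(ys, each = length(xs))
    inside <- rep(FALSE, length(px))
    for (h in hit) {
      inside <- inside | point_in_polygon(px, py, polygons[[h]])
    }
    if (mean(inside) > overlap_threshold)
      labels[tl$row + 1, tl$col + 1] <- FALSE
  }
  new_roi_mask(labels, grid, "annotation")
}

#' Baseline in/out tile classifier
#'
#' Training-free stand-in for a learned patch classifier: a tile is in-ROI
#' iff at least `min_tissue_fraction` of its pixels look like stained
#' tissue (chromatic and not near-white). Artifact tiles from the
#' synthetic generator are achromatic, and blank tiles are near-white, so
#' both fall below the cutoff.
#'
#' @param min_tissue_fraction minimum stained-pixel fraction (default 0.02).
#' @param saturation_threshold minimum HSV-style saturation for a pixel to
#'   count as stained (default 0.08).
#' @param value_threshold pixels with value (max channel) at or above this
#'   are background regardless of saturation (default 0.97).
#' @return classifier function `patch -> list(label = "in"|"out",
#'   score in [0,1])`, usable with [classify_tiles()].
#' @export
baseline_tile_classifier <- function(min_tissue_fraction = 0.02,
                                     saturation_threshold = 0.08,
                                     value_threshold = 0.97) {
  function(img) {
    img <- as_rgb_array(img)
    v <- pmax(img[, , 1], img[, , 2], img[, , 3])
    mn <- pmin(img[, , 1], img[, , 2], img[, , 3])
    s <- ifelse(v > 0, (v - mn) / v, 0)
    frac <- mean(s > saturation_threshold & v < value_threshold)
    list(label = if (frac >= min_tissue_fraction) "in" else "out",
         score = min(1, frac / max(min_tissue_fraction, 1e-12) / 2))
  }
}

#' Classify tiles into an ROI mask
#'
#' Applies a per-tile classifier honoring the pluggable contract
#' `patch -> list(label = "in"|"out", score in [0,1])` and assembles the
#' labels into a `roi_mask`.
#'
#' @param tiles list of tiles, each `list(row, col, image)` with 0-based
#'   grid indices (as returned by [load_slide_tiles()]).
#' @param classifier classifier function; default
#'   [baseline_tile_classifier()].
#' @param grid optional `tile_grid`; inferred from the tiles otherwise.
#' @return a `roi_mask`.
#' @export
classify_tiles <- function(tiles, classifier = baseline_tile_classifier(),
                           grid = NULL) {
  stopifnot(length(tiles) > 0)
  if (is.null(grid)) {
    ts <- dim(as_rgb_array(tiles[[1]]$image))[1]
    nr <- max(vapply(tiles, function(t) t$row, 0)) + 1
    nc <- max(vapply(tiles, function(t) t$col, 0)) + 1
    grid <- tile_slide(c(nc * ts, nr * ts), ts)
  }
  labels <- matrix(NA, grid$nrow, grid$ncol)
  for (t in tiles) {
    res <- classifier(t$image)
    if (!is.list(res) || is.null(res$label) ||
        !res$label %in% c("in", "out") ||
        is.null(res$score) || res$score < 0 || res$score > 1)
      stop("contract violation: classifier must return list(label = ",
           "'in'|'out', score in [0,1])")
    labels[t$row + 1, t$col + 1] <- res$label == "in"
  }
  if (anyNA(labels)) labels[is.na(labels)] <- FALSE
  new_roi_mask(labels, grid, "classifier")
}

#' Keep only cells whose centers lie in in-ROI tiles
#'
#' Tile membership uses the half-open convention: a center at exactly
#' `x = x1` of a tile belongs to the next tile to the right.
#'
#' @param cells data.frame with slide-coordinate `x`, `y` columns.
#' @param mask a `roi_mask`.
#' @return the retained rows of `cells`.
#' @export
restrict_cells_to_roi <- function(cells, mask) {
  stopifnot(inherits(mask, "roi_mask"))
  if (nrow(cells) == 0) return(cells)
  ts <- mask$grid$tile_size
  col <- floor(cells$x / ts) + 1
  row <- floor(cells$y / ts) + 1
  ok <- row >= 1 & row <= nrow(mask$labels) &
        col >= 1 & col <= ncol(mask$labels)
  keep <- ok
  keep[ok] <- mask$labels[cbind(row[ok], col[ok])]
  cells[keep, , drop = FALSE]
}
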