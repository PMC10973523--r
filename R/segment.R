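# Point-to-mask nucleus segmentation and boundary dilation.
#
# The default backend is classical: seeded region competition (EBImage's
# Voronoi-based propagate) on the hematoxylin OD channel, restricted to a
# nuclear foreground mask. Dilation grows each nucleus outward by a fixed
# radius so the region covers the membrane; contested pixels go to the
# nearest region (Euclidean), ties to the lower label id, so regions stay
# disjoint by construction.

new_label_map <- function(mat, centers, flagged = integer(0)) {
  storage.mode(mat) <- "integer"
  structure(mat, centers = centers, flagged = flagged, class = "label_map")
}

as_label_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "centers") <- NULL
  attr(m, "flagged") <- NULL
  m
}

label_ids <- function(x) {
  ctr <- attr(x, "centers")
  if (!is.null(ctr)) ctr$id else sort(unique(as.integer(x[x > 0])))
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("label_map: %d x %d px, %d labels (%d flagged on background)\n",
              nrow(x), ncol(x), length(label_ids(x)),
              length(attr(x, "flagged"))))
  invisible(x)
}

#' Segmentation parameters
#'
#' @param fg_threshold hematoxylin OD above which a pixel is nuclear
#'   foreground (default 0.1).
#' @param fg_sigma smoothing bandwidth for the foreground mask, px. Kept
#'   small (default 0.5) so mask inflation around a nucleus stays well
#'   within the area tolerances downstream.
#' @param lambda spatial-regularization weight of the region competition;
#'   large values make boundaries between touching nuclei near-equidistant.
#' @param dilation_radius boundary dilation radius in pixels (default 3).
#' @return list of class `segment_params`.
#' @export
segment_params <- function(fg_threshold = 0.1, fg_sigma = 0.5,
                           lambda = 100, dilation_radius = 3) {
  stopifnot(fg_threshold > 0, fg_sigma > 0, lambda > 0)
  if (dilation_radius < 0)
    stop("configuration error: dilation radius must be >= 0")
  structure(list(fg_threshold = fg_threshold, fg_sigma = fg_sigma,
                 lambda = lambda, dilation_radius = dilation_radius),
            class = "segment_params")
}

#' Segment nuclei from seed points
#'
#' Marker-controlled instance segmentation: each seed claims a region of
#' the nuclear foreground by seeded competition on the hematoxylin OD
#' channel. Seeds falling on background claim a minimal 3-px disk so every
#' detected cell has nonzero area (those labels are flagged). Duplicate
#' seeds (same pixel) are merged with a warning.
#'
#' @param img RGB patch.
#' @param seeds data.frame with `x`, `y` seed coordinates (0-based).
#' @param params a [segment_params()].
#' @param stain_matrix stain matrix for [separate_stains()].
#' @return a `label_map`: integer raster (0 = background, i = cell i) with
#'   a `centers` registry `(id, x, y)` and `flagged` ids.
#' @export
point_to_mask <- function(img, seeds, params = segment_params(),
                          stain_matrix = stain_matrix_hdab()) {
  img <- as_rgb_array(img)
  d <- dim(img)[1:2]
  if (nrow(seeds) == 0)
    return(new_label_map(matrix(0L, d[1], d[2]),
                         data.frame(id = integer(0), x = numeric(0),
                                    y = numeric(0))))
  stopifnot(all(seeds$x >= 0 & seeds$x < d[1]),
            all(seeds$y >= 0 & seeds$y < d[2]))
  px <- floor(seeds$x) + 1L
  py <- floor(seeds$y) + 1L
  dup <- duplicated(cbind(px, py))
  if (any(dup)) {
    warning(sum(dup), " duplicate seed(s) merged")
    seeds <- seeds[!dup, , drop = FALSE]
    px <- px[!dup]; py <- py[!dup]
  }
  centers <- data.frame(id = seq_len(nrow(seeds)), x = seeds$x, y = seeds$y)
  od <- separate_stains(img, stain_matrix)$hematoxylin
  sm <- EBImage::gblur(od, sigma = params$fg_sigma)
  fg <- sm > params$fg_threshold
  seedimg <- matrix(0L, d[1], d[2])
  seedimg[cbind(px, py)] <- centers$id
  fg[cbind(px, py)] <- TRUE                       # a seed is always claimable
  lab <- EBImage::propagate(sm, seeds = seedimg, mask = fg,
                            lambda = params$lambda)
  lab <- matrix(as.integer(EBImage::imageData(lab)), d[1], d[2])
  # Background seeds end up with (near-)empty regions: give them a 3-px disk.
  sizes <- tabulate(lab, nbins = nrow(centers))
  flagged <- which(sizes <= 1L)
  for (i in flagged) {
    ix <- max(1, px[i] - 1):min(d[1], px[i] + 1)
    iy <- max(1, py[i] - 1):min(d[2], py[i] + 1)
    sub <- lab[ix, iy]
    sub[sub == 0L] <- i
    lab[ix, iy] <- sub
  }
  new_label_map(lab, centers, as.integer(flagged))
}

#' Dilate every labelled region by a fixed radius
#'
#' Each region grows into the background up to Euclidean distance
#' `radius`. Contested pixels are assigned to the nearest region, ties to
#' the lower label id; existing labels never change, so the output
#' partitions pixels exactly like the input plus a disjoint margin.
#' `radius = 0` is the identity.
#'
#' @param labels a `label_map`.
#' @param radius dilation radius in pixels (>= 0).
#' @return a `label_map` with the same label registry.
#' @export
dilate_labels <- function(labels, radius) {
  if (length(radius) != 1 || is.na(radius) || radius < 0)
    stop("configuration error: dilation radius must be >= 0")
  mat <- as_label_matrix(labels)
  if (radius == 0 || all(mat == 0L))
    return(new_label_map(mat, attr(labels, "centers"),
                         attr(labels, "flagged")))
  d <- dim(mat)
  out <- mat
  best <- matrix(Inf, d[1], d[2])
  pad <- ceiling(radius) + 1L
  ids <- sort(unique(as.integer(mat[mat > 0])))
  for (i in ids) {
    w <- which(mat == i, arr.ind = TRUE)
    ix <- max(1, min(w[, 1]) - pad):min(d[1], max(w[, 1]) + pad)
    iy <- max(1, min(w[, 2]) - pad):min(d[2], max(w[, 2]) + pad)
    region <- mat[ix, iy, drop = FALSE] == i
    dist <- EBImage::distmap(1 - region)
    upd <- mat[ix, iy, drop = FALSE] == 0L & dist > 0 & dist <= radius &
           dist < best[ix, iy]
    if (any(upd)) {
      subo <- out[ix, iy, drop = FALSE]; subo[upd] <- i
      out[ix, iy] <- subo
      subb <- best[ix, iy, drop = FALSE]; subb[upd] <- dist[upd]
      best[ix, iy] <- subb
    }
  }
  new_label_map(out, attr(labels, "centers"), attr(labels, "flagged"))
}

#' Extract per-cell records from nucleus and dilated label maps
#'
#' Counts pixels per label in both maps and joins them with the seed
#' registry into the cell table the scoring rule consumes.
#'
#' @param labels nucleus `label_map`.
#' @param dilated dilated `label_map` (same registry, e.g. from
#'   [dilate_labels()]).
#' @return data.frame `id, x, y, nucleus_area, dilated_area, dab_ratio,
#'   is_positive` (the last two `NA` until the stain module fills them).
#' @export
extract_cells <- function(labels, dilated) {
  ids_n <- sort(unique(as.integer(labels[labels > 0])))
  ids_d <- sort(unique(as.integer(dilated[dilated > 0])))
  if (!identical(ids_n, ids_d))
    stop("consistency error: label sets of nucleus and dilated maps differ")
  centers <- attr(labels, "centers")
  if (is.null(centers))
    centers <- data.frame(id = ids_n, x = NA_real_, y = NA_real_)
  if (length(ids_n) == 0)
    return(data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      nucleus_area = numeric(0), dilated_area = numeric(0),
                      dab_ratio = numeric(0), is_positive = logical(0)))
  nmax <- max(ids_n)
  na <- tabulate(as_label_matrix(labels), nbins = nmax)
  da <- tabulate(as_label_matrix(dilated), nbins = nmax)
  keep <- centers$id %in% ids_n
  data.frame(id = centers$id[keep],
             x = centers$x[keep], y = centers$y[keep],
             nucleus_area = na[centers$id[keep]],
             dilated_area = da[centers$id[keep]],
             dab_ratio = NA_real_, is_positive = NA,
             row.names = NULL)
}
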