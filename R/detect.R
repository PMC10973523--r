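# Cell center detection and evaluation.
#
# The default detector is classical and training-free: nuclei absorb
# hematoxylin, so cell centers appear as local maxima of the smoothed
# hematoxylin optical-density channel. Learned detectors (density-map
# regressors etc.) can be plugged in through the same patch -> points
# contract; the density-map target builder for training such models is
# provided as well.

#' Detection parameters
#'
#' @param sigma Gaussian smoothing bandwidth (px) before peak picking.
#' @param min_separation minimum distance between reported peaks, px; the
#'   default equals the smallest nucleus diameter of the default generator
#'   classes.
#' @param threshold minimum smoothed hematoxylin OD at a peak.
#' @return list of class `detect_params`.
#' @export
detect_params <- function(sigma = 2, min_separation = 6, threshold = 0.15) {
  stopifnot(sigma > 0, min_separation >= 1, threshold > 0)
  structure(list(sigma = sigma, min_separation = min_separation,
                 threshold = threshold), class = "detect_params")
}

#' Detect cell centers on an RGB patch
#'
#' Separates stains, smooths the hematoxylin OD channel, and reports local
#' maxima (within a disc of diameter `min_separation`) whose smoothed OD
#' reaches `threshold`. Plateaus collapse to their centroid. Coordinates
#' are 0-based pixel centers.
#'
#' @param img RGB patch.
#' @param params a [detect_params()].
#' @param stain_matrix stain matrix for [separate_stains()].
#' @return data.frame `x`, `y` (a point set; possibly 0 rows).
#' @export
detect_centers <- function(img, params = detect_params(),
                           stain_matrix = stain_matrix_hdab()) {
  img <- as_rgb_array(img)
  if (any(dim(img)[1:2] == 0))
    return(data.frame(x = numeric(0), y = numeric(0)))
  od <- separate_stains(img, stain_matrix)$hematoxylin
  sm <- EBImage::gblur(od, sigma = params$sigma)
  side <- 2L * floor(params$min_separation / 2) + 1L
  mx <- EBImage::dilate(sm, EBImage::makeBrush(max(3L, side), "disc"))
  peaks <- sm >= params$threshold & sm >= mx - 1e-9
  if (!any(peaks)) return(data.frame(x = numeric(0), y = numeric(0)))
  lab <- EBImage::bwlabel(peaks)
  idx <- which(lab > 0, arr.ind = TRUE)
  grp <- lab[lab > 0]
  cx <- tapply(idx[, 1] - 0.5, grp, mean)   # 0-based pixel-center coords
  cy <- tapply(idx[, 2] - 0.5, grp, mean)
  pts <- data.frame(x = as.numeric(cx), y = as.numeric(cy))
  pts[order(pts$y, pts$x), , drop = FALSE] -> pts
  rownames(pts) <- NULL
  pts
}

#' Gaussian density-map target for point annotations
#'
#' Builds the regression target used to train density-based cell counters:
#' a unit-mass Gaussian kernel per annotated point, renormalized after
#' boundary truncation so the map integrates to the point count.
#'
#' @param points data.frame with `x`, `y` (0-based pixel coordinates).
#' @param sigma kernel bandwidth in pixels (> 0).
#' @param size map side in pixels (or `c(nx, ny)`).
#' @return numeric matrix whose sum equals `nrow(points)` up to float error.
#' @export
density_target <- function(points, sigma, size) {
  stopifnot(sigma > 0)
  if (length(size) == 1) size <- c(size, size)
  map <- matrix(0, size[1], size[2])
  if (nrow(points) == 0) return(map)
  r <- ceiling(4 * sigma)
  for (i in seq_len(nrow(points))) {
    px <- points$x[i]; py <- points$y[i]
    ix <- max(1, floor(px - r) + 1):min(size[1], floor(px + r) + 1)
    iy <- max(1, floor(py - r) + 1):min(size[2], floor(py + r) + 1)
    kx <- exp(-((ix - 0.5 - px)^2) / (2 * sigma^2))
    ky <- exp(-((iy - 0.5 - py)^2) / (2 * sigma^2))
    k <- outer(kx, ky)
    map[ix, iy] <- map[ix, iy] + k / sum(k)
  }
  map
}

# Exhaustive maximum matching for tiny instances: maximizes match count,
# then minimizes total distance. Independent of the greedy path.
match_points_optimal <- function(d, radius) {
  np <- nrow(d); nt <- ncol(d)
  if (np > 10) stop("optimal matcher is exhaustive; limited to <= 10 predictions")
  best <- list(count = -1, dist = Inf, pairs = NULL)
  recurse <- function(i, used, pairs, dist) {
    if (i > np) {
      cnt <- nrow(pairs) %||% 0
      if (cnt > best$count || (cnt == best$count && dist < best$dist))
        best <<- list(count = cnt, dist = dist, pairs = pairs)
      return(invisible(NULL))
    }
    recurse(i + 1, used, pairs, dist)  # leave pred i unmatched
    for (j in seq_len(nt)) {
      if (!used[j] && d[i, j] <= radius) {
        used[j] <- TRUE
        recurse(i + 1, used, rbind(pairs, c(i, j)), dist + d[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1, rep(FALSE, nt), NULL, 0)
  best$pairs
}

#' Match predicted to true points and score detection
#'
#' One-to-one matching of predictions to truth within `radius`. The
#' default greedy matcher takes candidate pairs in ascending distance,
#' breaking ties by the truth point's `(y, x)`; `method = "optimal"` uses
#' exhaustive maximum matching (small instances only).
#'
#' @param pred,truth data.frames with `x`, `y`.
#' @param radius maximum match distance in pixels (> 0).
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return object of class `detection_eval`: `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`, `match_radius`, and the matched pairs.
#'   Precision of an empty prediction set is 0 by convention.
#' @export
match_points <- function(pred, truth, radius = 5, method = c("greedy", "optimal")) {
  stopifnot(radius > 0)
  method <- match.arg(method)
  np <- nrow(pred); nt <- nrow(truth)
  pairs <- NULL
  if (np > 0 && nt > 0) {
    d <- sqrt(outer(pred$x, truth$x, "-")^2 + outer(pred$y, truth$y, "-")^2)
    if (method == "optimal") {
      pairs <- match_points_optimal(d, radius)
    } else {
      cand <- which(d <= radius, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        ord <- order(d[cand], truth$y[cand[, 2]], truth$x[cand[, 2]])
        cand <- cand[ord, , drop = FALSE]
        pused <- rep(FALSE, np); tused <- rep(FALSE, nt)
        keep <- logical(nrow(cand))
        for (i in seq_len(nrow(cand))) {
          pi <- cand[i, 1]; ti <- cand[i, 2]
          if (!pused[pi] && !tused[ti]) {
            pused[pi] <- TRUE; tused[ti] <- TRUE; keep[i] <- TRUE
          }
        }
        pairs <- cand[keep, , drop = FALSE]
      }
    }
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  fp <- np - tp; fn <- nt - tp
  precision <- if (np == 0) {if (nt == 0) 1 else 0} else tp / np
  recall <- if (nt == 0) 1 else tp / nt
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  matches <- if (is.null(pairs) || nrow(pairs) == 0) {
    data.frame(pred = integer(0), truth = integer(0), dist = numeric(0))
  } else {
    d <- sqrt((pred$x[pairs[, 1]] - truth$x[pairs[, 2]])^2 +
              (pred$y[pairs[, 1]] - truth$y[pairs[, 2]])^2)
    data.frame(pred = pairs[, 1], truth = pairs[, 2], dist = d)
  }
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, match_radius = radius,
                 matches = matches),
            class = "detection_eval")
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf(
    "detection_eval: tp %d fp %d fn %d | P %.3f R %.3f F1 %.3f (radius %g px)\n",
    x$tp, x$fp, x$fn, x$precision, x$recall, x$f1, x$match_radius))
  invisible(x)
}
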