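# Stain separation and positivity calls.
#
# Brightfield IHC obeys Beer-Lambert: transmitted intensity I = I0 *
# exp(-sum_s c_s * V_s) per RGB channel, where V_s is the unit optical-
# density (OD) vector of stain s and c_s its concentration. Inverting
# OD = -log(I/I0) onto the stain basis separates the hematoxylin (blue,
# nuclear) and DAB (brown, membrane) contributions per pixel.

#' Ruifrok-Johnston H-DAB stain matrix
#'
#' Unit optical-density vectors for hematoxylin and DAB, as columns of a
#' 3 x 2 matrix (rows R, G, B). These are the standard published vectors
#' for H-DAB brightfield deconvolution; per-slide matrices can be supplied
#' wherever a stain matrix is accepted, e.g. to absorb scanner- or
#' batch-level staining variation.
#'
#' @return numeric 3 x 2 matrix with unit-norm columns `hematoxylin`, `dab`.
#' @export
#' @examples
#' colSums(stain_matrix_hdab()^2)  # unit columns
stain_matrix_hdab <- function() {
  m <- cbind(
    hematoxylin = c(0.650, 0.704, 0.286),
    dab         = c(0.269, 0.568, 0.778)
  )
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

#' Separate hematoxylin and DAB optical densities
#'
#' Converts an RGB patch to per-pixel optical density and projects it onto
#' the stain basis by least squares (pseudo-inverse of the stain matrix).
#' Negative concentrations are clipped to zero.
#'
#' @param img RGB image: `[0,1]` array `(nx, ny, 3)`, an `EBImage::Image`,
#'   or a 0-255 array.
#' @param stain_matrix 3 x 2 matrix of unit OD vectors; default
#'   [stain_matrix_hdab()].
#' @return object of class `stain_channels`: list with matrices
#'   `hematoxylin` and `dab` (same x/y shape as the input, OD units, >= 0)
#'   and the `matrix` used.
#' @export
#' @examples
#' white <- array(1, c(8, 8, 3))
#' ch <- separate_stains(white)
#' max(ch$dab)  # ~0: no absorbance
separate_stains <- function(img, stain_matrix = stain_matrix_hdab()) {
  img <- as_rgb_array(img)
  stopifnot(is.matrix(stain_matrix), nrow(stain_matrix) == 3,
            ncol(stain_matrix) == 2)
  d <- dim(img)
  od <- -log(pmax(img, 1 / 512))          # guard pure black
  odm <- matrix(od, ncol = 3)             # pixels x channels
  pinv <- solve(crossprod(stain_matrix), t(stain_matrix))  # 2 x 3
  conc <- odm %*% t(pinv)
  conc[conc < 0] <- 0
  structure(
    list(
      hematoxylin = matrix(conc[, 1], d[1], d[2]),
      dab         = matrix(conc[, 2], d[1], d[2]),
      matrix      = stain_matrix
    ),
    class = "stain_channels"
  )
}

#' @export
print.stain_channels <- function(x, ...) {
  cat(sprintf("stain_channels: %d x %d px, max H OD %.3f, max DAB OD %.3f\n",
              nrow(x$hematoxylin), ncol(x$hematoxylin),
              max(x$hematoxylin), max(x$dab)))
  invisible(x)
}

#' Positivity parameters
#'
#' @param t brown-area ratio threshold in `[0,1]` at or above which a cell
#'   is called PD-L1 positive. Default 0.1.
#' @param dab_od_threshold DAB optical density at or above which a pixel
#'   counts as brown. Default 0.15.
#' @return list of class `positivity_params`.
#' @export
positivity_params <- function(t = 0.1, dab_od_threshold = 0.15) {
  stopifnot(length(t) == 1, t >= 0, t <= 1,
            length(dab_od_threshold) == 1, dab_od_threshold > 0)
  structure(list(t = t, dab_od_threshold = dab_od_threshold),
            class = "positivity_params")
}

#' Brown-pixel mask
#'
#' A pixel is brown iff its DAB optical density is at least
#' `params$dab_od_threshold`. Depends on the DAB channel only, so it is
#' invariant to hematoxylin intensity.
#'
#' @param channels a `stain_channels` object from [separate_stains()].
#' @param params a [positivity_params()] object.
#' @return logical matrix, same shape as the channels.
#' @export
brown_mask <- function(channels, params = positivity_params()) {
  stopifnot(inherits(channels, "stain_channels"))
  channels$dab >= params$dab_od_threshold
}

#' Brown-area ratio per cell
#'
#' For each cell, the fraction of pixels inside its dilated boundary that
#' are brown. Accepts either a single logical region mask or a label map
#' (returns one ratio per registered label).
#'
#' @param region logical matrix (one cell's dilated region) or an integer
#'   `label_map` of dilated regions.
#' @param brown logical brown-pixel matrix from [brown_mask()].
#' @return single ratio, or a named numeric vector (one entry per label).
#'   Labels with empty regions raise an error for the single-region form
#'   and yield `NA` in the label-map form.
#' @export
cell_dab_ratio <- function(region, brown) {
  if (is.logical(region)) {
    n <- sum(region)
    if (n == 0) stop("empty region: brown-area ratio is undefined")
    return(sum(brown[region]) / n)
  }
  labels <- as_label_matrix(region)
  ids <- label_ids(region)
  if (length(ids) == 0) return(setNames(numeric(0), character(0)))
  nmax <- max(ids)
  tot <- tabulate(labels, nbins = nmax)
  brn <- tabulate(labels[brown], nbins = nmax)
  ratio <- ifelse(tot[ids] > 0, brn[ids] / tot[ids], NA_real_)
  setNames(ratio, ids)
}

#' Classify cells as PD-L1 positive
#'
#' A cell is positive iff its brown-area ratio is greater than or equal to
#' the threshold `t`; at `t = 0` the rule degenerates to "any brown pixel
#' makes the cell positive" (a cell with ratio exactly 0 stays negative).
#' Positive sets are nested across thresholds: raising `t` can only shrink
#' the positive set.
#'
#' @param ratio numeric vector of brown-area ratios in `[0,1]`.
#' @param t threshold in `[0,1]`.
#' @return logical vector.
#' @export
#' @examples
#' classify_positive(c(0.30, 0.05, 0.10), t = 0.1)
classify_positive <- function(ratio, t = 0.1) {
  stopifnot(all(is.na(ratio) | (ratio >= 0 & ratio <= 1)),
            length(t) == 1, t >= 0, t <= 1)
  if (t == 0) ratio > 0 else ratio >= t
}
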