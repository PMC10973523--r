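# Shared helpers: seeded evaluation, image array handling, PNG round-trips.
#
# Canonical in-memory image: numeric array dim c(nx, ny, 3), values in [0, 1],
# x rightward, y downward, origin top-left, 0-based pixel coordinates in the
# API (pixel (ix, iy) covers [ix, ix+1) x [iy, iy+1); array index ix+1, iy+1).

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are pure functions of their configuration.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a per-unit seed from a base seed; stays below .Machine$integer.max.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(index)) %% 2147483647)
}

# Coerce input to the canonical [0,1] x-major RGB array. Accepts EBImage
# Image objects, y-major arrays from png::readPNG, and 0-255 integer arrays.
as_rgb_array <- function(img) {
  if (inherits(img, "Image")) img <- EBImage::imageData(img)
  if (is.matrix(img)) stop("expected an RGB image, got a single-channel matrix")
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]  # drop alpha
  if (length(dim(img)) != 3 || dim(img)[3] != 3)
    stop("expected an RGB image with 3 channels")
  img <- img * 1.0
  if (max(img) > 1) img <- img / 255
  img
}

# Write/read canonical arrays as 8-bit PNG (transposing to png's y-major
# layout). Quantization to 8 bits is part of the generator contract.
write_rgb_png <- function(img, path) {
  img <- round(pmin(pmax(img, 0), 1) * 255) / 255
  png::writePNG(aperm(img, c(2, 1, 3)), target = path)
  invisible(path)
}

read_rgb_png <- function(path) {
  as_rgb_array(aperm(png::readPNG(path), c(2, 1, 3)))
}

# Quantize a [0,1] image to the 8-bit grid (what writing + reading PNG does).
quantize8 <- function(img) round(pmin(pmax(img, 0), 1) * 255) / 255

`%||%` <- function(a, b) if (is.null(a)) b else a
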