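# The generator is the oracle for everything downstream, so its own
# contracts get tested first: determinism, label/pixel consistency, and
# that the stored truth is exactly recomputable from the cell table.

test_that("default patch renders >100 cells at the stated size, deterministically", {
  cfg <- synth_config(rng_seed = 7)
  p <- generate_patch(cfg)
  expect_equal(dim(p$image), c(256, 256, 3))
  expect_gt(nrow(p$truth$cells), 100)
  p2 <- generate_patch(cfg)
  expect_identical(p$image, p2$image)
  expect_identical(p$truth$cells, p2$truth$cells)
  # written tiles are byte-identical too
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  pdl1quant:::write_rgb_png(p$image, f1)
  pdl1quant:::write_rgb_png(p2$image, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("truth invariants hold: recomputable TPS, in-bounds centers, valid labels", {
  for (seed in c(1, 7, 23)) {
    p <- generate_patch(small_config(seed))
    cells <- p$truth$cells
    expect_equal(p$truth$true_tps, true_tps_from_cells(cells))
    expect_true(all(cells$x >= 0 & cells$x < 160))
    expect_true(all(cells$y >= 0 & cells$y < 160))
    expect_true(all(cells$class %in% names(small_config()$class_mix)))
    # nucleus label raster is keyed by cell id
    expect_true(all(unique(as.integer(p$truth$nucleus_labels)) %in%
                      c(0L, cells$id)))
  }
})

test_that("generated positivity labels follow the configured Bernoulli rates", {
  # pooled tumor cells across patches vs a binomial 3-sigma band at p = 0.5
  cfg <- synth_config(cells_per_patch = 230,
                      positive_fraction = c(tumor = 0.5,
                                            small_lymphocyte = 0.1,
                                            large_nontumor = 0))
  pooled <- do.call(rbind, lapply(1:20, function(s)
    sample_cell_population(cfg, seed = s)))
  tum <- pooled[pooled$class == "tumor", ]
  expect_gt(nrow(tum), 1500)
  phat <- mean(tum$is_positive)
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / nrow(tum)))
})

test_that("positive membranes are darker in DAB than any negative cell boundary", {
  p <- generate_patch(small_config(11))
  ch <- separate_stains(p$image)
  cells <- p$truth$cells
  ann_mean <- vapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    size <- p$truth$patch_size
    px <- matrix(rep(seq_len(size) - 0.5, size), size, size)
    py <- t(px)
    d2 <- (px - cl$x)^2 + (py - cl$y)^2
    ring <- d2 > cl$radius^2 & d2 <= (cl$radius + cl$thickness)^2
    mean(ch$dab[ring])
  }, 0)
  pos <- cells$is_positive
  skip_if(!any(pos) || !any(!pos))
  # arc fractions can halve a positive annulus mean, but DAB >= 0.3 on at
  # least half the ring still dominates the background leak on negatives
  expect_gt(min(ann_mean[pos]), max(ann_mean[!pos]))
})

test_that("slides tile the artifact fraction exactly and invert to a clean ROI", {
  cfg <- small_config(1, artifact_fraction = 0.25)
  dir <- tempfile("slide")
  sl <- generate_slide(cfg, 4, 4, dir)
  expect_length(list.files(dir, pattern = "^tile_.*png$"), 16)
  expect_equal(nrow(sl$artifact_tiles), 4)
  expect_length(sl$truth$artifact_polygons, 4)
  expect_equal(sl$truth$true_tps, true_tps_from_cells(sl$truth$cells))
  # sidecars round-trip
  tr <- read_slide_truth(dir)
  expect_equal(tr$true_tps, sl$truth$true_tps)
  expect_equal(nrow(tr$cells), nrow(sl$truth$cells))
  polys <- read_asap_annotations(file.path(dir, "non_roi.xml"))
  expect_length(polys, 4)

  # no artifacts -> empty annotation, ROI covers everything after inversion
  sl0 <- generate_slide(small_config(1), 2, 2, tempfile("slide"))
  expect_length(sl0$truth$artifact_polygons, 0)
  mask <- invert_non_roi(sl0$truth$artifact_polygons,
                         c(2 * 160, 2 * 160), 160)
  expect_true(all(mask$labels))
})

test_that("a 1x1 slide reproduces generate_patch for the same seed", {
  cfg <- small_config(5)
  dir <- tempfile("slide")
  generate_slide(cfg, 1, 1, dir)
  tile <- pdl1quant:::read_rgb_png(file.path(dir, "tile_r0_c0.png"))
  p <- generate_patch(cfg)
  expect_identical(tile, p$image)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(patch_size = 0), "configuration error")
  expect_error(synth_config(class_mix = c(tumor = 0.5)), "configuration error")
  expect_error(synth_config(positive_fraction = c(tumor = 1.5,
                                                  small_lymphocyte = 0,
                                                  large_nontumor = 0)),
               "configuration error")
  expect_error(synth_config(nucleus_radius_range = list(
    tumor = c(3, 5), small_lymphocyte = c(6, 11), large_nontumor = c(12, 18))),
    "median radius")
})
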