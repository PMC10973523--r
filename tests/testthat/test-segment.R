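test_that("a seeded disk nucleus segments to its analytic area", {
  img <- render_disks(96, cbind(48, 48), 8)
  lab <- point_to_mask(img, data.frame(x = 48, y = 48))
  area <- sum(lab == 1L)
  expect_lt(abs(area - pi * 64) / (pi * 64), 0.20)
  # the seed pixel carries its own label
  expect_equal(lab[49, 49], 1L)
})

test_that("touching nuclei split into disjoint regions containing their seeds", {
  img <- render_disks(96, rbind(c(40, 48), c(57, 48)), c(8, 8))
  seeds <- data.frame(x = c(40, 57), y = c(48, 48))
  lab <- point_to_mask(img, seeds)
  expect_equal(sort(unique(as.integer(lab[lab > 0]))), c(1L, 2L))
  expect_equal(lab[41, 49], 1L)
  expect_equal(lab[58, 49], 2L)
  # disjointness is structural (single raster), both regions substantial
  expect_gt(sum(lab == 1L), 100)
  expect_gt(sum(lab == 2L), 100)
})

test_that("degenerate seed inputs are handled", {
  img <- render_disks(64, cbind(32, 32), 6)
  empty <- point_to_mask(img, data.frame(x = numeric(0), y = numeric(0)))
  expect_true(all(empty == 0L))

  expect_warning(
    lab <- point_to_mask(img, data.frame(x = c(32, 32.2), y = c(32, 32.3))),
    "duplicate")
  expect_equal(length(pdl1quant:::label_ids(lab)), 1)

  # background seed claims a minimal disk and is flagged
  lab2 <- point_to_mask(img, data.frame(x = c(32, 5), y = c(32, 5)))
  expect_true(2L %in% attr(lab2, "flagged"))
  expect_gt(sum(lab2 == 2L), 0)
})

test_that("label dilation grows areas by the analytic margin and stays disjoint", {
  img <- render_disks(96, cbind(48, 48), 8)
  lab <- point_to_mask(img, data.frame(x = 48, y = 48))

  expect_identical(as.vector(dilate_labels(lab, 0)), as.vector(lab))
  expect_error(dilate_labels(lab, -1), "configuration error")

  dil <- dilate_labels(lab, 3)
  expect_lt(abs(sum(dil == 1L) - pi * 121) / (pi * 121), 0.15)

  # adjacent regions: disjoint after dilation, union bounded by the
  # independently dilated masks (per-pixel nearest-label oracle)
  img2 <- render_disks(96, rbind(c(40, 48), c(57, 48)), c(8, 8))
  lab2 <- point_to_mask(img2, data.frame(x = c(40, 57), y = c(48, 48)))
  dil2 <- dilate_labels(lab2, 3)
  a1 <- sum(dil2 == 1L); a2 <- sum(dil2 == 2L)
  only1 <- dilate_labels(pdl1quant:::new_label_map(
    ifelse(pdl1quant:::as_label_matrix(lab2) == 1L, 1L, 0L),
    data.frame(id = 1L, x = 40, y = 48)), 3)
  only2 <- dilate_labels(pdl1quant:::new_label_map(
    ifelse(pdl1quant:::as_label_matrix(lab2) == 2L, 1L, 0L),
    data.frame(id = 1L, x = 57, y = 48)), 3)
  expect_lte(a1 + a2, sum(only1 == 1L) + sum(only2 == 1L))
  # competition resolves by nearest region: midpoint column splits evenly
  expect_gt(a1, 0.8 * a2); expect_gt(a2, 0.8 * a1)
})

test_that("dilation is monotone in radius and conserves the label set", {
  p <- generate_patch(small_config(13))
  pts <- detect_centers(p$image)
  lab <- point_to_mask(p$image, pts)
  prev <- NULL
  for (r in c(0, 1, 2, 3, 5)) {
    d <- dilate_labels(lab, r)
    expect_identical(sort(unique(as.integer(d[d > 0]))),
                     sort(unique(as.integer(lab[lab > 0]))))
    areas <- tabulate(pdl1quant:::as_label_matrix(d))
    if (!is.null(prev)) expect_true(all(areas >= prev))
    prev <- areas
  }
})

test_that("extract_cells reproduces raster pixel counts", {
  empty <- pdl1quant:::new_label_map(
    matrix(0L, 8, 8), data.frame(id = integer(0), x = numeric(0),
                                 y = numeric(0)))
  expect_equal(nrow(extract_cells(empty, empty)), 0)

  # hand-built 50 px region dilated to 80 px
  m <- matrix(0L, 20, 20); m[3:12, 3:7] <- 1L        # 50 px
  d <- matrix(0L, 20, 20); d[3:12, 3:10] <- 1L       # 80 px
  reg <- data.frame(id = 1L, x = 7, y = 4)
  cells <- extract_cells(pdl1quant:::new_label_map(m, reg),
                         pdl1quant:::new_label_map(d, reg))
  expect_equal(cells$nucleus_area, 50)
  expect_equal(cells$dilated_area, 80)

  # synthetic patch: sum of areas equals the foreground pixel count
  p <- generate_patch(small_config(2))
  pts <- detect_centers(p$image)
  lab <- point_to_mask(p$image, pts)
  dil <- dilate_labels(lab, 3)
  cells <- extract_cells(lab, dil)
  expect_equal(nrow(cells), nrow(pts))
  expect_equal(sum(cells$nucleus_area), sum(lab > 0))
  expect_true(all(cells$dilated_area >= cells$nucleus_area))
  expect_true(all(cells$nucleus_area > 0))

  # label present in one map only is a consistency error
  d2 <- d; d2[15, 15] <- 2L
  expect_error(
    extract_cells(pdl1quant:::new_label_map(m, reg),
                  pdl1quant:::new_label_map(d2, reg)),
    "consistency error")
})
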