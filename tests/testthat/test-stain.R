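test_that("a white patch carries no optical density", {
  white <- array(1, c(16, 16, 3))
  ch <- separate_stains(white)
  expect_lt(max(ch$hematoxylin), 0.02)
  expect_lt(max(ch$dab), 0.02)
  expect_false(any(brown_mask(ch)))
})

test_that("forward-model pixels invert to their stain concentrations", {
  M <- stain_matrix_hdab()
  # DAB 0.8, hematoxylin 0
  rgb_d <- pdl1quant:::quantize8(array(exp(-0.8 * M[, 2]), c(1, 1, 3)))
  ch <- separate_stains(rgb_d)
  expect_lt(abs(ch$dab[1, 1] - 0.8) / 0.8, 0.02)
  expect_lt(ch$hematoxylin[1, 1], 0.05)
  # hematoxylin only: no DAB above the brown threshold
  rgb_h <- pdl1quant:::quantize8(array(exp(-0.9 * M[, 1]), c(1, 1, 3)))
  ch2 <- separate_stains(rgb_h)
  expect_lt(ch2$dab[1, 1], positivity_params()$dab_od_threshold)
  expect_lt(abs(ch2$hematoxylin[1, 1] - 0.9) / 0.9, 0.02)

  expect_error(separate_stains(matrix(0.5, 8, 8)), "RGB")
})

test_that("whole-patch round-trip recovers concentrations to quantization error", {
  # grid of known (h, d) pairs through the same forward model
  hs <- c(0, 0.2, 0.5, 0.9); ds <- c(0, 0.3, 0.6, 1.0)
  grid <- expand.grid(h = hs, d = ds)
  ch_mat <- matrix(grid$h, 4, 4)
  cd_mat <- matrix(grid$d, 4, 4)
  img <- pdl1quant:::render_rgb(ch_mat, cd_mat, c(255, 255, 255))
  ch <- separate_stains(img)
  expect_lt(max(abs(ch$hematoxylin - ch_mat)), 0.02)
  expect_lt(max(abs(ch$dab - cd_mat)), 0.02)
})

test_that("the brown mask finds rendered membranes and ignores negative cells", {
  p <- generate_patch(small_config(21))
  ch <- separate_stains(p$image)
  br <- brown_mask(ch)
  memb <- p$truth$membrane_mask
  skip_if(sum(memb) == 0)
  expect_gte(sum(br & memb) / sum(memb), 0.9)          # recall on membrane px

  # a rendered negative cell's dilated surroundings stay non-brown
  cells <- p$truth$cells
  neg <- cells[!cells$is_positive, ][1, ]
  size <- p$truth$patch_size
  px <- matrix(rep(seq_len(size) - 0.5, size), size, size); py <- t(px)
  region <- (px - neg$x)^2 + (py - neg$y)^2 <= (neg$radius + 3)^2
  expect_lt(mean(br[region]), 0.05)
})

test_that("the brown mask is invariant to hematoxylin intensity", {
  cd <- matrix(c(0, 0.3, 0.6, 0.9), 2, 2)
  img_a <- pdl1quant:::render_rgb(matrix(0.2, 2, 2), cd, c(255, 255, 255))
  img_b <- pdl1quant:::render_rgb(matrix(0.9, 2, 2), cd, c(255, 255, 255))
  expect_identical(brown_mask(separate_stains(img_a)),
                   brown_mask(separate_stains(img_b)))
})

test_that("brown-area ratios are exact pixel counts", {
  region <- matrix(FALSE, 20, 20); region[1:10, 1:10] <- TRUE   # 100 px
  brown <- matrix(FALSE, 20, 20); brown[1:10, 1:3] <- TRUE      # 30 inside
  expect_equal(cell_dab_ratio(region, brown), 0.30)
  expect_equal(cell_dab_ratio(region, region), 1.0)
  expect_error(cell_dab_ratio(matrix(FALSE, 4, 4), brown[1:4, 1:4]),
               "undefined")

  # label-map form agrees with a per-cell brute-force recount
  p <- generate_patch(small_config(8))
  pts <- detect_centers(p$image)
  lab <- point_to_mask(p$image, pts)
  dil <- dilate_labels(lab, 3)
  br <- brown_mask(separate_stains(p$image))
  ratios <- cell_dab_ratio(dil, br)
  dm <- pdl1quant:::as_label_matrix(dil)
  for (id in sample(pdl1quant:::label_ids(dil), 10)) {
    expect_equal(unname(ratios[as.character(id)]),
                 sum(br[dm == id]) / sum(dm == id))
  }
  expect_true(all(ratios >= 0 & ratios <= 1, na.rm = TRUE))
})

test_that("positivity overlays paint cell boundaries by call", {
  img <- render_disks(64, cbind(32, 32), 8, dab_conc = 0.8, annulus = 3)
  lab <- point_to_mask(img, data.frame(x = 32, y = 32))
  dil <- dilate_labels(lab, 3)
  ov <- positivity_overlay(img, dil, positive = c(TRUE))
  expect_equal(dim(ov), dim(img))
  red <- ov[, , 1] == 1 & ov[, , 2] == 0 & ov[, , 3] == 0
  expect_gt(sum(red), 20)   # boundary ring marked in red
})

test_that("positivity calls follow the threshold convention and nest across t", {
  expect_true(classify_positive(0.30, 0.1))
  expect_false(classify_positive(0, 0.3))
  expect_true(classify_positive(0.1, 0.1))    # boundary: ratio == t is positive
  expect_false(classify_positive(0, 0))       # t = 0 still needs brown pixels
  expect_true(classify_positive(0.001, 0))

  set.seed(4)
  ratios <- runif(300)
  ts <- c(0, 0.01, 0.05, 0.1, 0.3, 0.5)
  prev <- NULL
  for (t in ts) {
    pos <- which(classify_positive(ratios, t))
    if (!is.null(prev)) expect_true(all(pos %in% prev))  # subset property
    prev <- pos
  }
})
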