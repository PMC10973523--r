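# Shared fixtures: small configurations and hand-built raster scenes.

small_config <- function(seed = 7, ...) {
  synth_config(patch_size = 160, cells_per_patch = 40, rng_seed = seed, ...)
}

# Render isolated disks (and optional DAB annuli) on a white background
# through the same forward model the generator uses: a controlled scene
# where analytic areas and concentrations are known exactly.
render_disks <- function(size, centers, radii, h_conc = 0.7,
                         dab_conc = 0, annulus = 0,
                         background = c(255, 255, 255)) {
  ch <- matrix(0, size, size)
  cd <- matrix(0, size, size)
  h_conc <- rep(h_conc, length.out = length(radii))
  dab_conc <- rep(dab_conc, length.out = length(radii))
  annulus <- rep(annulus, length.out = length(radii))
  px <- matrix(rep(seq_len(size) - 0.5, size), size, size)
  py <- t(px)
  for (i in seq_along(radii)) {
    d2 <- (px - centers[i, 1])^2 + (py - centers[i, 2])^2
    ch[d2 <= radii[i]^2] <- pmax(ch[d2 <= radii[i]^2], h_conc[i])
    if (dab_conc[i] > 0 && annulus[i] > 0) {
      ring <- d2 > radii[i]^2 & d2 <= (radii[i] + annulus[i])^2
      cd[ring] <- pmax(cd[ring], dab_conc[i])
    }
  }
  pdl1quant:::render_rgb(ch, cd, background)
}

# Cell-table builder for scoring tests.
make_cells <- function(areas, positive, x = seq_along(areas),
                       y = rep(1, length(areas))) {
  data.frame(id = seq_along(areas), x = x, y = y,
             nucleus_area = areas, is_positive = positive)
}

# Independent ANOVA oracle via base aov(): long-format two-way fit, mean
# squares read off the ANOVA table. No code shared with icc3k().
aov_icc3k <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  long <- data.frame(y = as.vector(tab),
                     target = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  a <- summary(stats::aov(y ~ target + rater, data = long))[[1]]
  ms_r <- a["target", "Mean Sq"]
  ms_e <- a["Residuals", "Mean Sq"]
  list(icc = (ms_r - ms_e) / ms_r, f = ms_r / ms_e)
}

# Brute-force reimplementation of the scoring rule used as an oracle:
# plain sort + head/tail arithmetic, no shared code with tps_star().
oracle_tps_star <- function(cells, m, k) {
  ord <- order(-cells$nucleus_area, cells$y, cells$x, cells$id)
  v <- cells$is_positive[ord]
  n <- length(v)
  drop <- floor(m * n)
  if (drop > 0) v <- v[-(1:drop)]
  sel <- v[seq_len(min(k, length(v)))]
  100 * sum(sel) / length(sel)
}
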