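test_that("area ranking is descending with the deterministic tie rule", {
  cells <- make_cells(c(5, 9, 9, 2), c(TRUE, FALSE, TRUE, FALSE),
                      x = c(1, 4, 2, 3), y = c(1, 2, 1, 1))
  r <- rank_by_area(cells)
  expect_equal(r$nucleus_area, c(9, 9, 5, 2))
  expect_equal(r$id[1:2], c(3L, 2L))          # tie broken by (y, x, id)

  one <- make_cells(7, TRUE)
  expect_equal(rank_by_area(one)$id, 1L)

  set.seed(10)
  big <- make_cells(sample(1000), runif(1000) < 0.5,
                    x = runif(1000), y = runif(1000))
  expect_equal(rank_by_area(big)$nucleus_area,
               sort(big$nucleus_area, decreasing = TRUE))
})

test_that("top-m exclusion removes exactly floor(m*N) largest cells", {
  r100 <- rank_by_area(make_cells(1:100, rep(FALSE, 100)))
  expect_equal(nrow(exclude_top_m(r100, 0.06)), 94)
  expect_identical(exclude_top_m(r100, 0), r100)
  r50 <- rank_by_area(make_cells(1:50, rep(FALSE, 50)))
  kept <- exclude_top_m(r50, 0.06)
  expect_equal(nrow(kept), 47)                       # floor(3.0) = 3 removed
  expect_equal(kept$nucleus_area, sort(1:47, decreasing = TRUE))
})

test_that("top-k selection saturates with an under-k flag", {
  r <- rank_by_area(make_cells(1:10, rep(TRUE, 10)))
  s4 <- select_top_k(r, 4)
  expect_equal(s4$nucleus_area, 10:7)
  expect_false(attr(s4, "under_k"))
  s99 <- select_top_k(r, 99)
  expect_equal(nrow(s99), 10)
  expect_true(attr(s99, "under_k"))

  # default operating point on a 5000-cell slide selects exactly k cells
  pop <- sample_cell_population(synth_config(), n = 5000, seed = 1)
  sel <- select_top_k(exclude_top_m(rank_by_area(pop), 0.06), 3000)
  expect_equal(nrow(sel), 3000)
  expect_false(attr(sel, "under_k"))
})

test_that("TPS* composes the rule and matches hand enumeration", {
  cells <- make_cells(10:1, c(TRUE, FALSE, TRUE, FALSE, rep(TRUE, 6)))
  s <- tps_star(cells, scoring_params(m = 0, k = 4, min_cells = 1))
  expect_equal(s$tps_star, 50)                  # 2 positives in the 4 largest
  expect_equal(s$n_selected, 4)
  expect_equal(s$n_after_exclusion, 10)

  all_pos <- make_cells(1:8, rep(TRUE, 8))
  expect_equal(tps_star(all_pos, scoring_params(m = 0, k = 8,
                                                min_cells = 1))$tps_star, 100)
  none <- make_cells(1:8, rep(FALSE, 8))
  expect_equal(tps_star(none, scoring_params(m = 0, k = 8,
                                             min_cells = 1))$tps_star, 0)
})

test_that("slides below the minimum cell count are structurally unscorable", {
  few <- make_cells(1:5, rep(TRUE, 5))
  s <- tps_star(few, scoring_params(k = 3000))   # min_cells defaults to k
  expect_false(s$scorable)
  expect_true(is.na(s$tps_star))
  expect_match(s$reason, "insufficient cells")
})

test_that("TPS* equals the brute-force oracle on random instances", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(500, 1)
    cells <- make_cells(runif(n, 1, 400), runif(n) < runif(1),
                        x = runif(n), y = runif(n))
    m <- runif(1, 0, 0.2); k <- sample(n, 1)
    s <- tps_star(cells, scoring_params(m = m, k = k, min_cells = 1))
    expect_equal(s$tps_star, oracle_tps_star(cells, m, k))
  }
})

test_that("TPS* is invariant to the input order of cells", {
  set.seed(3)
  cells <- make_cells(runif(200, 1, 100), runif(200) < 0.4,
                      x = runif(200), y = runif(200))
  p <- scoring_params(m = 0.06, k = 80, min_cells = 1)
  s1 <- tps_star(cells, p)
  s2 <- tps_star(cells[sample(200), ], p)
  expect_equal(s1$tps_star, s2$tps_star)
})

test_that("the degenerate rule (m=0, k>=N, t=0) counts any-brown cells", {
  set.seed(5)
  n <- 150
  cells <- make_cells(runif(n, 1, 100), rep(FALSE, n),
                      x = runif(n), y = runif(n))
  cells$dab_ratio <- ifelse(runif(n) < 0.4, runif(n, 0.01, 1), 0)
  s <- tps_star(cells, scoring_params(m = 0, k = n, t = 0, min_cells = 1))
  expect_equal(s$tps_star, 100 * mean(cells$dab_ratio > 0))
})

test_that("traditional TPS is the positive fraction of viable tumor cells", {
  expect_equal(tps_traditional(30, 100), 30)
  expect_equal(tps_traditional(0, 57), 0)
  expect_error(tps_traditional(1, 0), "undefined")
  expect_error(tps_traditional(5, 3))
  pop <- sample_cell_population(synth_config(), n = 800, seed = 2)
  tum <- pop[pop$class == "tumor", ]
  expect_equal(tps_traditional(sum(tum$is_positive), nrow(tum)),
               true_tps_from_cells(pop))
})

test_that("stratification uses left-closed guideline intervals", {
  expect_equal(stratify(c(4.9, 5, 49.9, 50, 100)),
               c("low", "intermediate", "intermediate", "high", "high"))
  expect_equal(stratify(0), "low")
  expect_equal(unique(stratify(c(0.5, 2), cutoffs = 1)),
               c("stratum_1", "stratum_2"))
  set.seed(6)
  v <- runif(100, 0, 100)
  manual <- ifelse(v < 5, "low", ifelse(v < 50, "intermediate", "high"))
  expect_equal(stratify(v), manual)
})

test_that("the parameter sweep reproduces direct scoring and behaves monotonically", {
  set.seed(12)
  cells <- make_cells(runif(400, 1, 300), rep(FALSE, 400),
                      x = runif(400), y = runif(400))
  cells$dab_ratio <- ifelse(runif(400) < 0.5, runif(400, 0.02, 0.9), 0)

  g1 <- sweep_parameters(cells, 0.06, 100, 0.1)
  direct <- tps_star(cells, scoring_params(m = 0.06, k = 100, t = 0.1,
                                           min_cells = 1))
  expect_equal(g1$tps_star_mean, direct$tps_star)

  sw <- sweep_parameters(cells, c(0, 0.06), c(100, 200),
                         c(0.01, 0.05, 0.1, 0.3, 0.5))
  for (mm in unique(sw$m)) for (kk in unique(sw$k)) {
    slice <- sw[sw$m == mm & sw$k == kk, ]
    expect_true(all(diff(slice$tps_star_mean[order(slice$t)]) <= 0))
  }

  ref <- direct$tps_star
  swr <- sweep_parameters(cells, 0.06, 100, 0.1, reference = ref)
  expect_equal(swr$log_mse, -12)               # perfect reference: eps floor
})
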