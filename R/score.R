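# The area-ranked PD-L1 quantification rule for DLBCL.
#
# DLBCL slides have no delimited tumor regions, so tumor cells are
# identified morphologically: rank all in-ROI cells by nucleus area
# (descending), drop the top m% largest (likely macrophages or endothelial
# cells), and designate the next k largest as the tumor cells. The
# modified tumor proportion score is then
#   TPS* = 100 * (PD-L1+ cells among the top-k) / k,
# while the traditional TPS = 100 * (PD-L1+ tumor cells) / (viable tumor
# cells) needs an external viable-tumor-cell count (e.g. synthetic truth).

#' Scoring-rule parameters
#'
#' Defaults are the operating point used throughout: `m = 0.06`,
#' `k = 3000`, `t = 0.1`.
#'
#' @param m fraction in `[0, 1)` of largest cells excluded before
#'   selection.
#' @param k number of largest remaining cells designated tumor cells.
#' @param t brown-area ratio threshold for positivity (used when cells
#'   carry `dab_ratio`).
#' @param cutoffs strictly increasing stratification cutoffs in (0, 100),
#'   default `c(5, 50)`.
#' @param min_cells minimum total cells required to score a slide;
#'   defaults to `k`.
#' @return list of class `scoring_params`.
#' @export
scoring_params <- function(m = 0.06, k = 3000, t = 0.1,
                           cutoffs = c(5, 50), min_cells = NULL) {
  stopifnot(m >= 0, m < 1, k >= 1, t >= 0, t <= 1)
  if (length(cutoffs) > 0) {
    stopifnot(all(diff(cutoffs) > 0), all(cutoffs > 0), all(cutoffs < 100))
  }
  structure(list(m = m, k = as.integer(k), t = t, cutoffs = cutoffs,
                 min_cells = as.integer(min_cells %||% k)),
            class = "scoring_params")
}

#' Rank cells by nucleus area, largest first
#'
#' Ties are broken by `(y, x, id)` so the ordering (and everything built
#' on it) is deterministic and invariant to input order.
#'
#' @param cells data.frame with `nucleus_area` (> 0) and `x`, `y`, `id`.
#' @return the rows of `cells`, reordered.
#' @export
rank_by_area <- function(cells) {
  stopifnot(all(cells$nucleus_area > 0))
  ord <- order(-cells$nucleus_area, cells$y, cells$x, cells$id)
  out <- cells[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude the top m% largest cells
#'
#' Removes exactly `floor(m * N)` head elements from an area-ranked table.
#'
#' @param ranked area-ranked cells (see [rank_by_area()]).
#' @param m fraction in `[0, 1)`.
#' @return the remaining rows, order preserved.
#' @export
#' @examples
#' # N = 100, m = 0.06 drops the 6 largest
exclude_top_m <- function(ranked, m) {
  stopifnot(m >= 0, m < 1)
  n_drop <- floor(m * nrow(ranked))
  if (n_drop == 0) return(ranked)
  out <- ranked[-seq_len(n_drop), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the top-k largest cells as the tumor cells
#'
#' @param ranked area-ranked cells (after exclusion).
#' @param k positive integer.
#' @return the first `min(k, N)` rows, with attribute `under_k = TRUE`
#'   when fewer than `k` cells were available.
#' @export
select_top_k <- function(ranked, k) {
  stopifnot(k >= 1)
  n <- min(k, nrow(ranked))
  out <- ranked[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "under_k") <- nrow(ranked) < k
  out
}

#' Compute the modified tumor proportion score TPS*
#'
#' Composes rank -> exclude top m% -> select top k -> count positives.
#' When cells carry a `dab_ratio` column, positivity is (re)derived as
#' `dab_ratio >= t`; otherwise the `is_positive` column is used as-is.
#' The denominator is `k` whenever `k` cells are available; if fewer
#' survive exclusion the score falls back to the selected count and is
#' flagged `under_k`. Slides with fewer than `min_cells` cells in total
#' are unscorable and yield no numeric TPS*.
#'
#' @param cells cell table (`id, x, y, nucleus_area`, and `dab_ratio`
#'   and/or `is_positive`).
#' @param params a [scoring_params()].
#' @param n_viable_tumor optional externally known viable-tumor-cell count
#'   (with `n_positive_tumor`) to also fill the traditional TPS.
#' @param n_positive_tumor see `n_viable_tumor`.
#' @return object of class `slide_score`: `tps_star`, `tps_traditional`,
#'   counts at each filtering stage (`n_total`, `n_after_exclusion`,
#'   `n_selected`, `n_positive_selected`), `stratum`, `under_k`,
#'   `scorable`, the `area_histogram` summary, and the parameters used.
#' @export
#' @examples
#' cells <- data.frame(id = 1:10, x = 1:10, y = 1, nucleus_area = 10:1,
#'                     is_positive = rep(c(TRUE, FALSE), 5))
#' tps_star(cells, scoring_params(m = 0, k = 4, min_cells = 1))$tps_star
tps_star <- function(cells, params = scoring_params(),
                     n_viable_tumor = NULL, n_positive_tumor = NULL) {
  stopifnot(inherits(params, "scoring_params"))
  n_total <- nrow(cells)
  tps_trad <- if (!is.null(n_viable_tumor) && !is.null(n_positive_tumor))
    tps_traditional(n_positive_tumor, n_viable_tumor) else NA_real_
  if (n_total < params$min_cells) {
    return(structure(
      list(tps_star = NA_real_, tps_traditional = tps_trad,
           n_total = n_total, n_after_exclusion = NA_integer_,
           n_selected = NA_integer_, n_positive_selected = NA_integer_,
           stratum = NA_character_, under_k = NA, scorable = FALSE,
           reason = "insufficient cells", area_histogram = NULL,
           params = params),
      class = "slide_score"))
  }
  if (!is.null(cells$dab_ratio) && !all(is.na(cells$dab_ratio))) {
    cells$is_positive <- classify_positive(cells$dab_ratio, params$t)
  }
  stopifnot(!is.null(cells$is_positive))
  ranked <- rank_by_area(cells)
  kept <- exclude_top_m(ranked, params$m)
  sel <- select_top_k(kept, params$k)
  n_sel <- nrow(sel)
  n_pos <- sum(sel$is_positive)
  hist_breaks <- pretty(ranked$nucleus_area, 20)
  structure(
    list(tps_star = 100 * n_pos / n_sel,
         tps_traditional = tps_trad,
         n_total = n_total,
         n_after_exclusion = nrow(kept),
         n_selected = n_sel,
         n_positive_selected = n_pos,
         stratum = stratify(100 * n_pos / n_sel, params$cutoffs),
         under_k = isTRUE(attr(sel, "under_k")),
         scorable = TRUE, reason = NULL,
         area_histogram = list(
           breaks = hist_breaks,
           counts = as.integer(table(cut(ranked$nucleus_area, hist_breaks,
                                         include.lowest = TRUE)))),
         params = params),
    class = "slide_score")
}

#' @export
print.slide_score <- function(x, ...) {
  if (!x$scorable) {
    cat(sprintf("slide_score: unscorable (%s; %d cells, min %d)\n",
                x$reason, x$n_total, x$params$min_cells))
    return(invisible(x))
  }
  cat(sprintf(
    paste0("slide_score: TPS* %.1f%% (stratum %s)%s\n",
           "  cells: %d total -> %d after top-%.0f%% exclusion -> ",
           "%d selected (%d positive)\n"),
    x$tps_star, x$stratum, if (x$under_k) " [under k]" else "",
    x$n_total, x$n_after_exclusion, 100 * x$params$m,
    x$n_selected, x$n_positive_selected))
  if (!is.na(x$tps_traditional))
    cat(sprintf("  traditional TPS: %.1f%%\n", x$tps_traditional))
  invisible(x)
}

#' Traditional tumor proportion score
#'
#' `100 * n_positive_tumor / n_viable_tumor`; requires an externally
#' supplied viable-tumor-cell count.
#'
#' @param n_positive_tumor PD-L1-positive tumor cells (0..n_viable_tumor).
#' @param n_viable_tumor viable tumor cells (>= 1).
#' @return percent.
#' @export
tps_traditional <- function(n_positive_tumor, n_viable_tumor) {
  if (n_viable_tumor < 1) stop("undefined score: no viable tumor cells")
  stopifnot(n_positive_tumor >= 0, n_positive_tumor <= n_viable_tumor)
  100 * n_positive_tumor / n_viable_tumor
}

#' Assign a TPS to a clinical stratum
#'
#' Intervals are left-closed: a score equal to a cutoff enters the higher
#' stratum. Default cutoffs 5 and 50 give the guideline strata
#' `low` `[0,5)`, `intermediate` `[5,50)`, `high` `[50,100]`.
#'
#' @param tps score(s) in `[0, 100]`.
#' @param cutoffs strictly increasing cutoffs in (0, 100).
#' @return character vector of stratum labels.
#' @export
#' @examples
#' stratify(c(4.9, 5, 50))
stratify <- function(tps, cutoffs = c(5, 50)) {
  stopifnot(all(tps >= 0 & tps <= 100, na.rm = TRUE),
            all(diff(cutoffs) > 0))
  labs <- if (identical(as.numeric(cutoffs), c(5, 50))) {
    c("low", "intermediate", "high")
  } else {
    paste0("stratum_", seq_len(length(cutoffs) + 1))
  }
  labs[findInterval(tps, cutoffs) + 1]
}

#' Sweep the scoring parameters over a grid
#'
#' Recomputes TPS* for every `(m, k, t)` combination and, when reference
#' scores are supplied, the log-scale MSE against them — the sensitivity
#' analysis used to pick the operating point.
#'
#' @param cells one cell table or a list of cell tables (one per slide);
#'   tables must carry `dab_ratio` so `t` can be re-applied.
#' @param m_grid,k_grid,t_grid parameter values to cross.
#' @param reference optional numeric reference score per slide (e.g. mean
#'   rater TPS, or synthetic truth).
#' @param cutoffs passed to [scoring_params()].
#' @return data.frame with one row per combination: `m, k, t`, per-slide
#'   mean TPS* (`tps_star_mean`), and `log_mse` when a reference is given.
#' @export
sweep_parameters <- function(cells, m_grid, k_grid, t_grid,
                             reference = NULL, cutoffs = c(5, 50)) {
  if (is.data.frame(cells)) cells <- list(cells)
  stopifnot(length(m_grid) > 0, length(k_grid) > 0, length(t_grid) > 0)
  if (!is.null(reference)) stopifnot(length(reference) == length(cells))
  grid <- expand.grid(m = m_grid, k = k_grid, t = t_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- scoring_params(m = grid$m[i], k = grid$k[i], t = grid$t[i],
                        cutoffs = cutoffs, min_cells = 1)
    scores <- vapply(cells, function(cc) tps_star(cc, p)$tps_star, 0)
    data.frame(m = grid$m[i], k = grid$k[i], t = grid$t[i],
               tps_star_mean = mean(scores),
               log_mse = if (is.null(reference)) NA_real_
                         else mse_log(scores, reference))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
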