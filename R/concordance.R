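# Rater-concordance statistics.
#
# Agreement between raters (pathologists and/or the algorithm) over a set
# of target slides is summarized by ICC3k: the two-way mixed-effects,
# consistency, average-measures intraclass correlation over a fixed rater
# panel. From the two-way ANOVA decomposition with MS_R the between-target
# mean square and MS_E the residual mean square,
#   ICC3k = (MS_R - MS_E) / MS_R,   F = MS_R / MS_E,
#   df1 = n - 1,  df2 = (n - 1)(k - 1),
# with the 95% CI by F-quantile inversion: 1 - 1/(F/F_u) and 1 - 1/(F*F_l)
# bounds from the upper quantiles of F(df1, df2) and F(df2, df1).

#' Two-way mixed, consistency, average-measures ICC (ICC3k)
#'
#' @param table numeric matrix or data.frame, rows = targets (slides),
#'   columns = raters. Rows containing missing values are dropped listwise
#'   with a message.
#' @param conf confidence level for the CI (default 0.95).
#' @return object of class `icc_result`: `icc`, `f_stat`, `df1`, `df2`,
#'   `pval`, `ci95 = c(lower, upper)`, `n_targets`, `n_raters`,
#'   `n_dropped`.
#' @export
#' @examples
#' set.seed(1)
#' truth <- runif(12, 0, 100)
#' tab <- sapply(1:3, function(i) truth + rnorm(12, 0, 4))
#' icc3k(tab)$icc
icc3k <- function(table, conf = 0.95) {
  x <- as.matrix(table)
  storage.mode(x) <- "double"
  complete <- stats::complete.cases(x)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message(n_dropped, " target(s) with missing ratings dropped")
    x <- x[complete, , drop = FALSE]
  }
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2)
    stop("ICC needs at least 2 targets and 2 raters after dropping ",
         "incomplete rows")
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_r <- k * sum((row_m - grand)^2)
  ss_c <- n * sum((col_m - grand)^2)
  ss_t <- sum((x - grand)^2)
  ss_e <- ss_t - ss_r - ss_c
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  ms_r <- ss_r / df1
  ms_e <- ss_e / df2
  if (ms_r <= .Machine$double.eps * max(1, abs(grand))^2)
    stop("degenerate input: no between-target variance, ICC undefined")
  icc <- (ms_r - ms_e) / ms_r
  f <- ms_r / ms_e
  alpha <- 1 - conf
  fl <- f / qf(1 - alpha / 2, df1, df2)
  fu <- f * qf(1 - alpha / 2, df2, df1)
  structure(
    list(icc = icc, f_stat = f, df1 = df1, df2 = df2,
         pval = pf(f, df1, df2, lower.tail = FALSE),
         ci95 = c(lower = 1 - 1 / fl, upper = 1 - 1 / fu),
         n_targets = n, n_raters = k, n_dropped = n_dropped),
    class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    paste0("ICC3k = %.3f (95%% CI %.3f, %.3f)\n",
           "  F(%d, %d) = %.2f, p = %.3g, %d targets x %d raters\n"),
    x$icc, x$ci95[1], x$ci95[2], x$df1, x$df2, x$f_stat, x$pval,
    x$n_targets, x$n_raters))
  invisible(x)
}

#' Aggregate rater columns per target
#'
#' @param table matrix/data.frame, rows = targets, columns = raters.
#' @param method `"mean"` or `"median"`.
#' @param columns rater columns to aggregate (names or indices); default
#'   all.
#' @return numeric vector, one value per target.
#' @export
aggregate_raters <- function(table, method = c("mean", "median"),
                             columns = NULL) {
  method <- match.arg(method)
  x <- as.matrix(table)
  if (!is.null(columns)) x <- x[, columns, drop = FALSE]
  stopifnot(ncol(x) >= 1)
  apply(x, 1, if (method == "mean") mean else median)
}

#' Stratified agreement between algorithm and rater scores
#'
#' Cross-tabulates the clinical strata of the two score vectors; the
#' diagonal holds concordant calls and the exact-match rate is their
#' fraction.
#'
#' @param algorithm numeric algorithm scores per target.
#' @param raters numeric aggregated rater scores per target.
#' @param cutoffs stratification cutoffs (default `c(5, 50)`).
#' @return list with `table` (strata cross-tabulation, algorithm in rows),
#'   `match_rate`, and `n`.
#' @export
stratified_agreement <- function(algorithm, raters, cutoffs = c(5, 50)) {
  if (length(algorithm) != length(raters))
    stop("alignment error: score vectors have different lengths")
  labs <- unique(stratify(c(0, cutoffs), cutoffs))
  a <- factor(stratify(algorithm, cutoffs), levels = labs)
  r <- factor(stratify(raters, cutoffs), levels = labs)
  tab <- table(algorithm = a, raters = r)
  list(table = tab, match_rate = sum(diag(tab)) / length(algorithm),
       n = length(algorithm))
}

#' Log-scale mean squared error
#'
#' `log10(MSE + 1e-12)`; the epsilon keeps exact agreement finite at -12.
#'
#' @param pred,ref equal-length numeric vectors.
#' @return single numeric value.
#' @export
mse_log <- function(pred, ref) {
  if (length(pred) == 0 || length(ref) == 0)
    stop("empty score vectors")
  if (length(pred) != length(ref))
    stop("alignment error: score vectors have different lengths")
  log10(mean((pred - ref)^2) + 1e-12)
}

#' Simulate a rater panel around true slide scores
#'
#' Convenience generator for concordance studies: each rater reports the
#' true score plus independent Gaussian noise (clamped to `[0, 100]`).
#'
#' @param true_scores numeric vector of per-slide true TPS values.
#' @param n_raters number of raters.
#' @param noise_sd rating noise standard deviation in TPS points.
#' @param seed RNG seed.
#' @return matrix targets x raters with columns `rater1..raterN`.
#' @export
simulate_rater_table <- function(true_scores, n_raters = 3, noise_sd = 3,
                                 seed = 0) {
  with_seed(seed, {
    m <- vapply(seq_len(n_raters), function(i)
      pmin(100, pmax(0, true_scores + rnorm(length(true_scores), 0, noise_sd))),
      numeric(length(true_scores)))
    colnames(m) <- paste0("rater", seq_len(n_raters))
    m
  })
}
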