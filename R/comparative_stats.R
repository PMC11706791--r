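#' Kruskal-Wallis test on a grouped trait table
#'
#' Rank test for differences in a trait (chromosome number, genome size in
#' Mb, ...) among groups (e.g., copepod orders), with the standard tie
#' correction, via [stats::kruskal.test()]. Identical values across all
#' groups give H = 0, p = 1.
#'
#' @param table data.frame with columns `group` and `value` (a `species`
#'   column may be present and is ignored by the test).
#' @return List of class `RankTestResult`: `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(table) {
  stopifnot(all(c("group", "value") %in% names(table)))
  if (length(unique(table$group)) < 2) stopf("need at least 2 groups")
  if (any(table$value <= 0)) stopf("trait values must be positive")
  if (length(unique(table$value)) == 1L) {
    res <- list(H = 0, df = length(unique(table$group)) - 1L, p_value = 1)
  } else {
    kt <- stats::kruskal.test(table$value, factor(table$group))
    res <- list(H = unname(kt$statistic), df = unname(kt$parameter),
                p_value = kt$p.value)
  }
  structure(res, class = "RankTestResult")
}

#' @export
print.RankTestResult <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.2f, DF = %d, P = %.2g\n",
              x$H, x$df, x$p_value))
  invisible(x)
}

#' Pairwise Wilcoxon rank-sum tests between groups
#'
#' Two-sided rank-sum (Mann-Whitney) test for every group pair, corrected
#' for multiple testing. Exact p-values are used for small tie-free
#' samples; otherwise the tie- and continuity-corrected normal
#' approximation (the [stats::wilcox.test()] default behaviour).
#'
#' @param table data.frame with columns `group` and `value`.
#' @param adjust p-value adjustment method (default `"BH"`).
#' @return Symmetric matrix of adjusted p-values (diagonal `NA`).
#' @export
pairwise_wilcoxon <- function(table, adjust = "BH") {
  groups <- sort(unique(table$group))
  if (length(groups) < 2) stopf("need at least 2 groups")
  pairs <- utils::combn(groups, 2)
  p <- apply(pairs, 2, function(gp) {
    x <- table$value[table$group == gp[1]]
    y <- table$value[table$group == gp[2]]
    suppressWarnings(stats::wilcox.test(x, y)$p.value)
  })
  p <- stats::p.adjust(p, method = adjust)
  m <- matrix(NA_real_, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (j in seq_len(ncol(pairs)))
    m[pairs[1, j], pairs[2, j]] <- m[pairs[2, j], pairs[1, j]] <- p[j]
  m
}

#' Group medians of a trait table
#'
#' @param table data.frame with columns `group` and `value`.
#' @return Named numeric vector of medians (even counts average the
#'   central pair).
#' @export
group_medians <- function(table) {
  vapply(split(table$value, table$group), stats::median, numeric(1))
}

#' Sample Pearson correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y differ in length")
  if (length(x) < 3) stopf("need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("zero variance in x or y")
  stats::cor(x, y, method = "pearson")
}

#' Effective population size from Watterson's theta
#'
#' Under neutrality `theta_W = 4 * Ne * mu` per site, so
#' `Ne = theta_W / (4 * mu)`. Besides the exact value, two rounded forms
#' are reported: one significant figure (`ne_rounded`) and the nearest
#' power of ten (`ne_magnitude`), the "approximately 10^6" form in which
#' such estimates are usually quoted.
#'
#' @param theta_w Watterson's theta per site (> 0).
#' @param mu Mutation rate per site per generation (> 0).
#' @return List: `theta_w`, `mu`, `ne` (exact), `ne_rounded` (1 s.f.),
#'   `ne_magnitude` (nearest power of 10).
#' @export
effective_pop_size <- function(theta_w, mu) {
  if (theta_w <= 0 || mu <= 0) stopf("theta_w and mu must be positive")
  ne <- theta_w / (4 * mu)
  list(theta_w = theta_w, mu = mu, ne = ne, ne_rounded = signif(ne, 1),
       ne_magnitude = 10^round(log10(ne)))
}
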