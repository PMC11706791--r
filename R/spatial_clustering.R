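#' Adjacent-gene spacings for a labeled subset
#'
#' Distances (bp) between midpoints of consecutive subset genes along each
#' chromosome, pooled across chromosomes. Flank-to-telomere distances are
#' not included; a chromosome with fewer than two subset genes contributes
#' no spacings. Zero spacings (tied midpoints) are kept.
#'
#' @param bundle A `GenomeBundle`.
#' @param subset_label Label tag selecting the gene subset.
#' @return A `SpacingSet`: list with `spacings` (pooled), `per_chrom`
#'   (list of spacing vectors), `midpoints` (list per chromosome, sorted),
#'   `counts` (genes per chromosome), `chrom_lengths`, `n_genes`.
#' @export
gene_spacings <- function(bundle, subset_label) {
  ids <- genes_with_label(bundle, subset_label)
  if (!length(ids))
    stopf("no genes carry label '%s'; available: %s", subset_label,
          paste(available_labels(bundle), collapse = ", "))
  g <- bundle$genes[bundle$genes$gene_id %in% ids, , drop = FALSE]
  mids <- split(g$midpoint, g$chrom)
  lens <- stats::setNames(bundle$chromosomes$length,
                          bundle$chromosomes$name)
  spacing_set(lapply(mids, sort), lens[names(mids)])
}

#' Construct a spacing set from midpoints
#'
#' @param midpoints_by_chrom Named list of per-chromosome gene midpoints
#'   (bp); sorted internally.
#' @param chrom_lengths Named numeric of chromosome lengths (bp), needed
#'   for the position-uniform and Monte-Carlo nulls.
#' @return A `SpacingSet` (see [gene_spacings()]).
#' @export
spacing_set <- function(midpoints_by_chrom, chrom_lengths = NULL) {
  mids <- lapply(midpoints_by_chrom, sort)
  per_chrom <- lapply(mids, diff)
  pooled <- as.numeric(unlist(per_chrom, use.names = FALSE))
  n_genes <- sum(lengths(mids))
  if (!length(pooled))
    stopf("fewer than 2 subset genes on every chromosome; no spacings")
  structure(list(spacings = pooled, per_chrom = per_chrom,
                 midpoints = mids, counts = lengths(mids),
                 chrom_lengths = chrom_lengths, n_genes = n_genes),
            class = "SpacingSet")
}

# internal: one-sample KS statistic of sample x against CDF values F(x_(i))
# D = sup over ECDF step points of |ECDF - CDF|
ks_stat_from_cdf <- function(Fv) {
  n <- length(Fv)
  Fv <- sort(Fv)
  i <- seq_len(n)
  max(pmax(i / n - Fv, Fv - (i - 1) / n))
}

# internal: KS distance between sample x and a reference ECDF given by the
# sorted pool y. Between consecutive x step points F_x is constant and F_y
# is monotone, so the sup is attained either at an x step (right limit) or
# just before the next x step (left limit); both are evaluated with
# findInterval, giving the exact two-sample D in O(n log m).
ks_stat_two_sample <- function(x, y_sorted) {
  n <- length(x)
  m <- length(y_sorted)
  xs <- sort(x)
  i <- seq_len(n)
  Fy_le <- findInterval(xs, y_sorted) / m                    # F_y(x_i)
  Fy_lt <- findInterval(xs, y_sorted, left.open = TRUE) / m  # F_y(x_i^-)
  max(max(abs(i / n - Fy_le)), max(abs((i - 1) / n - Fy_lt)))
}

#' Asymptotic Kolmogorov one-sample p-value
#'
#' Upper-tail probability of the Kolmogorov distribution with the standard
#' finite-n correction `lambda = (sqrt(n) + 0.12 + 0.11/sqrt(n)) * D`.
#'
#' @param D KS statistic.
#' @param n Sample size.
#' @return p-value in (0, 1].
#' @export
kolmogorov_p <- function(D, n) {
  lambda <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * D
  j <- 1:101
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(1, max(p, .Machine$double.xmin))
}

# internal: pooled spacings from one uniform placement matched to counts
sample_uniform_spacings <- function(counts, chrom_lengths) {
  out <- vector("list", length(counts))
  for (i in seq_along(counts)) {
    if (counts[i] >= 2)
      out[[i]] <- diff(sort(stats::runif(counts[i], 0, chrom_lengths[i])))
  }
  as.numeric(unlist(out, use.names = FALSE))
}

# internal: B independent uniform placements at once. The c+1 gaps cut by
# c uniform points on (0, L) are jointly L * Dirichlet(1, ..., 1), i.e.
# normalized iid exponentials, so the c-1 adjacent spacings per placement
# can be drawn without any sorting. Returns a matrix with one placement's
# pooled spacings per column.
sample_uniform_spacings_batch <- function(counts, chrom_lengths, B) {
  blocks <- list()
  for (i in seq_along(counts)) {
    ci <- counts[i]
    if (ci < 2) next
    E <- matrix(stats::rexp((ci + 1) * B), ci + 1, B)
    gaps <- E[2:ci, , drop = FALSE] /
      rep(colSums(E), each = ci - 1) * chrom_lengths[i]
    blocks[[length(blocks) + 1]] <- gaps
  }
  do.call(rbind, blocks)
}

#' Kolmogorov-Smirnov test for clustering of gene spacings
#'
#' Tests whether the adjacent-gene spacing distribution of a subset
#' deviates from what uniform placement along the chromosomes would give.
#' Three null modes:
#' \describe{
#'   \item{`uniform-spacing`}{literal reading: one-sample KS of the pooled
#'     spacings against Uniform(0, max observed spacing); asymptotic
#'     Kolmogorov p. Clustered sets pile up small spacings and give large
#'     D.}
#'   \item{`position-uniform`}{one-sample KS of midpoint/chromosome-length
#'     against Uniform(0, 1), pooled; asymptotic p.}
#'   \item{`montecarlo`}{statistically calibrated: D between the observed
#'     spacings and spacings pooled from `n_null` uniform placements with
#'     matched per-chromosome gene counts; the p-value is Monte-Carlo,
#'     comparing the observed D with `n_mc` null placements' D against the
#'     same pool: p = (1 + #\{D_null >= D_obs\}) / (1 + n_mc).}
#' }
#'
#' @param sset A `SpacingSet`.
#' @param null_mode One of `"uniform-spacing"`, `"position-uniform"`,
#'   `"montecarlo"`.
#' @param seed Optional integer seed for the Monte-Carlo mode.
#' @param n_null Placements pooled into the Monte-Carlo reference (1000).
#' @param n_mc Null draws for the Monte-Carlo p-value (199).
#' @return List of class `SpacingTestResult`: `D`, `p_value`, `n`,
#'   `null_mode`.
#' @export
ks_clustering_test <- function(sset,
                               null_mode = c("uniform-spacing",
                                             "position-uniform",
                                             "montecarlo"),
                               seed = NULL, n_null = 1000, n_mc = 199) {
  null_mode <- match.arg(null_mode)
  x <- sset$spacings
  n <- length(x)
  if (n < 5 && null_mode != "montecarlo")
    stopf("only %d spacings; use null_mode = 'montecarlo' for small samples",
          n)
  if (null_mode == "uniform-spacing") {
    upper <- max(x)
    if (upper <= 0) stopf("all spacings are zero")
    D <- ks_stat_from_cdf(pmin(1, sort(x) / upper))
    p <- kolmogorov_p(D, n)
  } else if (null_mode == "position-uniform") {
    if (is.null(sset$chrom_lengths))
      stopf("chromosome lengths required for position-uniform null")
    u <- unlist(mapply(function(m, L) m / L, sset$midpoints,
                       sset$chrom_lengths[names(sset$midpoints)],
                       SIMPLIFY = FALSE), use.names = FALSE)
    D <- ks_stat_from_cdf(sort(u))
    p <- kolmogorov_p(D, length(u))
    n <- length(u)
  } else {
    if (is.null(sset$chrom_lengths))
      stopf("chromosome lengths required for montecarlo null")
    if (!is.null(seed)) set.seed(seed)
    counts <- sset$counts
    lens <- sset$chrom_lengths[names(sset$midpoints)]
    pool <- sort(as.numeric(sample_uniform_spacings_batch(counts, lens,
                                                          n_null)))
    D <- ks_stat_two_sample(x, pool)
    nullmat <- sample_uniform_spacings_batch(counts, lens, n_mc)
    d_null <- vapply(seq_len(n_mc), function(i)
      ks_stat_two_sample(nullmat[, i], pool), numeric(1))
    p <- (1 + sum(d_null >= D)) / (1 + n_mc)
  }
  structure(list(D = D, p_value = p, n = n, null_mode = null_mode),
            class = "SpacingTestResult")
}

#' @export
print.SpacingTestResult <- function(x, ...) {
  cat(sprintf("KS clustering test (%s null): D = %.3f, n = %d, P = %.3g\n",
              x$null_mode, x$D, x$n, x$p_value))
  invisible(x)
}

#' Chi-square goodness of fit of spacings against a reference gene set
#'
#' Compares the spacing distribution of an observed gene set (e.g., ion
#' transport-related genes) with that of a reference set of functionally
#' conserved genes. Bin edges are reference-spacing quantiles, so every bin
#' has equal expected mass under the reference distribution; the statistic
#' is the usual `sum((obs - exp)^2 / exp)` with `df = bins - 1`.
#'
#' The default bin count `max(6, floor(n_observed / 30))` gives df = 15 at
#' n = 490 and df = 5 at n = 80.
#'
#' @param observed Numeric vector of observed spacings (or a `SpacingSet`).
#' @param reference Numeric vector of reference spacings (or `SpacingSet`).
#' @param n_bins Number of bins; default `max(6, floor(n_obs / 30))`.
#' @return List of class `ChiSquareResult`: `chi2`, `df`, `p_value`,
#'   `bin_edges`, `observed`, `expected`.
#' @export
chisq_vs_reference <- function(observed, reference, n_bins = NULL) {
  if (inherits(observed, "SpacingSet")) observed <- observed$spacings
  if (inherits(reference, "SpacingSet")) reference <- reference$spacings
  n <- length(observed)
  if (is.null(n_bins)) n_bins <- max(6, floor(n / 30))
  if (n / n_bins < 5)
    stopf("expected count %.1f per bin < 5; use fewer bins", n / n_bins)
  probs <- seq(0, 1, length.out = n_bins + 1)
  edges <- stats::quantile(reference, probs = probs, type = 7, names = FALSE)
  inner <- edges[-c(1, length(edges))]
  if (any(duplicated(inner)))
    stopf("tied reference quantiles produce empty bins; use fewer bins")
  # open outer bins so observed values outside the reference range count
  cut_edges <- c(-Inf, inner, Inf)
  obs <- as.vector(table(cut(observed, breaks = cut_edges,
                             include.lowest = TRUE)))
  expd <- rep(n / n_bins, n_bins)
  chi2 <- sum((obs - expd)^2 / expd)
  df <- n_bins - 1
  structure(list(chi2 = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 bin_edges = edges, observed = obs, expected = expd),
            class = "ChiSquareResult")
}

#' @export
print.ChiSquareResult <- function(x, ...) {
  cat(sprintf("Chi-square goodness of fit: chi2 = %.1f, DF = %d, P = %.3g\n",
              x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Per-chromosome counts of a labeled gene subset
#'
#' @param bundle A `GenomeBundle`.
#' @param subset_label Label tag.
#' @return Named integer vector, one entry per chromosome (zeros included).
#' @export
per_chromosome_counts <- function(bundle, subset_label) {
  ids <- genes_with_label(bundle, subset_label)
  if (!length(ids)) stopf("no genes carry label '%s'", subset_label)
  g <- bundle$genes[bundle$genes$gene_id %in% ids, , drop = FALSE]
  counts <- table(factor(g$chrom, levels = bundle$chromosomes$name))
  stats::setNames(as.integer(counts), names(counts))
}

#' Centromere-proximal gene counts
#'
#' Counts subset genes whose midpoint lies within `window_bp` of the
#' chromosome's centromere. Chromosomes without a recorded centromere
#' return `NA` (not zero).
#'
#' @param bundle A `GenomeBundle` with `centromere_pos` set where known.
#' @param subset_label Label tag.
#' @param window_bp Half-width of the window around the centromere (bp).
#' @return Named integer vector (NA where centromere position is missing).
#' @export
centromere_proximity <- function(bundle, subset_label, window_bp) {
  ids <- genes_with_label(bundle, subset_label)
  if (!length(ids)) stopf("no genes carry label '%s'", subset_label)
  g <- bundle$genes[bundle$genes$gene_id %in% ids, , drop = FALSE]
  out <- stats::setNames(rep(NA_integer_, nrow(bundle$chromosomes)),
                         bundle$chromosomes$name)
  for (i in seq_len(nrow(bundle$chromosomes))) {
    cen <- bundle$chromosomes$centromere_pos[i]
    if (is.na(cen)) next
    chrom <- bundle$chromosomes$name[i]
    out[chrom] <- sum(g$chrom == chrom &
                        abs(g$midpoint - cen) <= window_bp)
  }
  out
}
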