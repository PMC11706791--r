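test_that("spacings are per-chromosome adjacent differences, pooled", {
  ss <- spacing_set(list(c1 = c(10, 20, 40)))
  expect_equal(ss$spacings, c(10, 20))

  # one gene per chromosome yields no spacings anywhere -> error
  expect_error(spacing_set(list(c1 = 5, c2 = 9, c3 = 2, c4 = 7)),
               "fewer than 2")

  # synthetic placements against a sort-and-diff oracle
  set.seed(41)
  mids <- list(c1 = runif(50, 0, 1e6), c2 = runif(50, 0, 1e6))
  ss2 <- spacing_set(mids)
  oracle <- c(diff(sort(mids$c1)), diff(sort(mids$c2)))
  expect_equal(sort(ss2$spacings), sort(oracle))
  expect_equal(length(ss2$spacings), ss2$n_genes - 2)
})

test_that("gene_spacings pools labeled genes from a bundle", {
  b <- toy_bundle()
  ss <- gene_spacings(b, "ion_transport")  # gA, gB on chr1
  expect_equal(ss$spacings, (21 + 32) / 2 - (1 + 9) / 2)
  expect_error(gene_spacings(b, "nope"), "available")
})

test_that("one-sample KS D matches the brute-force sup at step points", {
  # spacings at exact Uniform(0, max) quantiles: D attains the 1/(n+1) bound
  n <- 9
  mx <- 100
  x <- mx * (1:n) / (n + 1)
  D_quantiles <- copearch:::ks_stat_from_cdf(sort(x) / mx)
  expect_equal(D_quantiles, 1 / (n + 1))

  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    x <- rexp(n, 1 / 50)
    mx <- max(x)
    D <- copearch:::ks_stat_from_cdf(pmin(1, sort(x) / mx))
    expect_equal(D, brute_force_ks_D(x, function(v) min(1, v / mx)))
    # and the full test agrees with stats::ks.test on the same null
    kt <- ks_clustering_test(spacing_set(list(c1 = cumsum(c(0, x)))),
                             "uniform-spacing")
    ref <- suppressWarnings(stats::ks.test(x, "punif", 0, mx))
    expect_equal(kt$D, unname(ref$statistic), tolerance = 1e-12)
    # p approximations differ (finite-n corrected Kolmogorov series vs
    # ks.test's internals); require agreement, not identity
    expect_equal(kt$p_value, ref$p.value, tolerance = 0.05)
  }
})

test_that("position-uniform mode tests midpoints against chromosome spans", {
  set.seed(43)
  mids <- list(Chr1 = runif(40, 0, 1e6))
  ss <- spacing_set(mids, c(Chr1 = 1e6))
  r <- ks_clustering_test(ss, "position-uniform")
  expect_equal(r$D,
               brute_force_ks_D(mids$Chr1 / 1e6, function(v) v))
  expect_gt(r$p_value, 0.01)
})

test_that("small samples are rejected outside montecarlo mode", {
  ss <- spacing_set(list(c1 = c(1, 5, 20, 21)))
  expect_error(ks_clustering_test(ss, "uniform-spacing"), "montecarlo")
})

test_that("chi-square vs reference reproduces hand arithmetic and df heuristic", {
  # all 60 observed land in the first of 6 equal-mass bins
  ref <- seq(1, 1200, length.out = 600)
  obs <- rep(0.5, 60)
  r <- chisq_vs_reference(obs, ref, n_bins = 6)
  expect_equal(r$chi2, 300)
  expect_equal(r$df, 5)
  expect_equal(sum(r$observed), 60)
  expect_equal(sum(r$expected), 60)

  # default bin heuristic: df = 15 at n = 490, df = 5 at n = 80
  set.seed(44)
  big_ref <- rexp(600, 1 / 100)
  expect_equal(chisq_vs_reference(rexp(490, 1 / 100), big_ref)$df, 15)
  expect_equal(chisq_vs_reference(rexp(80, 1 / 100), big_ref)$df, 5)

  expect_error(chisq_vs_reference(rexp(20, 1), big_ref, n_bins = 6),
               "fewer bins")
})

test_that("chi-square is calibrated when observed is drawn from the reference", {
  set.seed(45)
  ref <- rexp(2000, 1 / 80)
  stats <- replicate(200, {
    obs <- sample(ref, 480, replace = TRUE)
    chisq_vs_reference(obs, ref, n_bins = 16)$chi2
  })
  df <- 15
  # median of chi-square(15) is ~14.3; wide tolerance for 200 reps
  expect_lt(abs(median(stats) - df), 3)
  ps <- pchisq(stats, df, lower.tail = FALSE)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("per-chromosome counts match a group-by oracle", {
  b <- toy_bundle()
  counts <- per_chromosome_counts(b, "ion_transport")
  expect_equal(unname(counts), c(2, 0))

  spec <- synthetic_genome_spec(n_chromosomes = 4, chrom_length = 2e5,
                                genes_per_chrom = 25, rng_seed = 5)
  bs <- gen_genome(spec)$bundle
  counts <- per_chromosome_counts(bs, "ion_transport")
  ids <- copearch:::genes_with_label(bs, "ion_transport")
  g <- bs$genes[bs$genes$gene_id %in% ids, ]
  oracle <- table(factor(g$chrom, levels = bs$chromosomes$name))
  expect_equal(unname(counts), as.vector(oracle))
  expect_equal(sum(counts), length(ids))
})

test_that("centromere proximity counts genes in the window, NA when unknown", {
  b <- toy_bundle()  # chr1 centromere at 30; gA mid 5, gB mid 26.5
  expect_equal(unname(centromere_proximity(b, "ion_transport", 5)),
               c(1, NA))
  expect_equal(unname(centromere_proximity(b, "ion_transport", 0)),
               c(0, NA))
  # a gene exactly at the centromere counts for window 0
  b$genes$start[1] <- 29; b$genes$end[1] <- 31
  b$cds <- b$cds[b$cds$gene_id != "gA", ]
  b2 <- genome_bundle(b$chromosomes, b$genes, b$cds, b$sequences)
  expect_equal(unname(centromere_proximity(b2, "ion_transport", 0))[1], 1)
})

test_that("centromere-clustered genomes exceed the uniform proximal null", {
  set.seed(46)
  L <- 1e6; cen <- L / 2; n <- 30; win <- 0.02 * L
  mids <- pmin(pmax(rnorm(n, cen, 0.005 * L), 1), L)
  prox_obs <- sum(abs(mids - cen) <= win)
  null_prox <- replicate(500, sum(abs(runif(n, 0, L) - cen) <= win))
  expect_gte(prox_obs, quantile(null_prox, 0.95))
})

test_that("montecarlo KS mode is seeded and reproducible", {
  set.seed(47)
  ss <- sim_spacing_set(20)
  r1 <- ks_clustering_test(ss, "montecarlo", seed = 7)
  r2 <- ks_clustering_test(ss, "montecarlo", seed = 7)
  expect_identical(r1$D, r2$D)
  expect_identical(r1$p_value, r2$p_value)
})
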