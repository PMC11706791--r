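test_that("depth outliers follow hand-computed type-7 quartile fences", {
  d <- data.frame(gene_id = letters[1:5], depth = c(1, 2, 3, 4, 100))
  r <- depth_outliers(d)
  expect_equal(unique(r$q1), 2)
  expect_equal(unique(r$q3), 4)
  expect_equal(unique(r$iqr), 2)
  expect_equal(r$gene_id[r$outlier_high], "e")

  # equal depths: zero IQR, nothing beyond the fence
  req <- depth_outliers(data.frame(gene_id = letters[1:6],
                                   depth = rep(7, 6)))
  expect_equal(sum(req$outlier_high), 0)

  expect_error(depth_outliers(data.frame(gene_id = letters[1:5],
                                         depth = c(-1, 2, 3, 4, 5))),
               "non-negative")
  expect_error(depth_outliers(data.frame(gene_id = letters[1:3],
                                         depth = 1:3)), "at least 4")
})

test_that("outlier flags are invariant under uniform depth scaling", {
  set.seed(51)
  d <- data.frame(gene_id = sprintf("g%03d", 1:200),
                  depth = rnbinom(200, size = 10, mu = 100))
  f1 <- depth_outliers(d)$outlier_high
  d$depth <- d$depth * 37.5
  f2 <- depth_outliers(d)$outlier_high
  expect_identical(f1, f2)
})

test_that("per-base BED coverage aggregates to gene means", {
  b <- toy_bundle()
  cov <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                    start = c(0, 4, 0), end = c(4, 60, 40),
                    depth = c(10, 20, 5))
  d <- depth_from_bed(cov, b)
  # gA spans 1-9: 4 bases at 10, 5 at 20 -> (40+100)/9
  expect_equal(d$depth[d$gene_id == "gA"], 140 / 9)
  expect_equal(d$depth[d$gene_id == "gB"], 20)
  expect_equal(d$depth[d$gene_id == "gC"], 5)
})

test_that("NG86 counting matches an independent enumeration oracle", {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  # oracle: per-codon synonymous site fraction by direct enumeration
  oracle_sites <- function(cd) {
    ch <- strsplit(cd, "")[[1]]
    s <- 0
    for (pos in 1:3) for (b in bases[bases != ch[pos]]) {
      mut <- ch; mut[pos] <- b
      if (code[[paste(mut, collapse = "")]] == code[[cd]]) s <- s + 1 / 3
    }
    s
  }
  # oracle: pathway-averaged differences by recursive enumeration
  oracle_diffs <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    dpos <- which(ca != cb)
    if (!length(dpos)) return(c(0, 0))
    walk <- function(cur) {
      dp <- which(cur != cb)
      if (!length(dp)) return(list(c(0, 0)))
      out <- list()
      for (p in dp) {
        nxt <- cur; nxt[p] <- cb[p]
        if (code[[paste(nxt, collapse = "")]] == "*") next
        syn <- code[[paste(cur, collapse = "")]] ==
          code[[paste(nxt, collapse = "")]]
        for (tail in walk(nxt))
          out[[length(out) + 1]] <- tail + if (syn) c(1, 0) else c(0, 1)
      }
      out
    }
    res <- walk(ca)
    if (!length(res)) return(NULL)  # all pathways blocked by stops
    Reduce(`+`, res) / length(res)
  }

  sense <- names(code)[code != "*"]
  set.seed(52)
  for (i in 1:40) {
    a <- sample(sense, 1); b <- sample(sense, 1)
    r <- ng86_ks(a, b)
    expect_equal(r$S, (oracle_sites(a) + oracle_sites(b)) / 2)
    od <- oracle_diffs(a, b)
    if (!is.null(od)) {
      expect_equal(r$sd, od[1])
      expect_equal(r$nd, od[2])
    }
    expect_equal(r$S + r$N, 3)
  }

  # single Phe codon pair: one synonymous difference over 1/3 syn site
  r <- ng86_ks("TTT", "TTC")
  expect_equal(r$sd, 1)
  expect_equal(r$S, 1 / 3)
  expect_true(is.infinite(r$Ks))  # ps = 3 saturates the JC correction
})

test_that("NG86 Ks is zero for identical sequences and increases with divergence", {
  s <- paste(rep("ATGGCTAAA", 20), collapse = "")
  r <- ng86_ks(s, s)
  expect_equal(r$Ks, 0)
  expect_equal(r$sd, 0)
  expect_error(ng86_ks("ATG", "ATGAAA"), "length")
  expect_error(ng86_ks("ATGTAAAAA", "ATGTAAAAA"), "stop")

  # monotone in the number of introduced synonymous substitutions
  set.seed(53)
  ks_at <- vapply(c(0, 0.02, 0.05, 0.1), function(t) {
    spec <- synthetic_genome_spec(n_pairs = 30, codons = 300,
                                  target_ks = t, rng_seed = 53)
    pp <- gen_paralogs(spec)$pairs
    mean(vapply(seq_len(nrow(pp)), function(i)
      ng86_ks(pp$seq_a[i], pp$seq_b[i])$Ks, numeric(1)))
  }, numeric(1))
  expect_equal(ks_at[1], 0)
  expect_true(all(diff(ks_at) > 0))
})

test_that("Ks histogram windows and saturation accounting behave", {
  h <- ks_histogram(rep(0, 10))
  expect_equal(unname(h$window_fractions["0-0.04"]), 1)
  expect_equal(h$n_infinite, 0)

  h2 <- ks_histogram(c(0.02, 0.03, 0.5, Inf))
  expect_equal(h2$n_finite, 3)
  expect_equal(h2$n_infinite, 1)
  expect_equal(unname(h2$window_fractions["0-0.04"]), 2 / 3)

  expect_error(ks_histogram(c(Inf, Inf)), "finite")
})

test_that("a young/old Ks mixture is recovered in the recent window", {
  spec <- synthetic_genome_spec(n_pairs = 150, codons = 300,
                                target_ks = c(0.02, 0.5),
                                ks_weights = c(0.6, 0.4), rng_seed = 55)
  gp <- gen_paralogs(spec)
  pp <- gp$pairs
  ks <- vapply(seq_len(nrow(pp)), function(i)
    ng86_ks(pp$seq_a[i], pp$seq_b[i])$Ks, numeric(1))
  h <- ks_histogram(ks)
  # compare against the realized mixing proportion recorded in the truth
  young_frac <- mean(gp$truth$target_ks == 0.02)
  expect_lt(abs(h$window_fractions["0-0.04"] - young_frac), 0.05)
  # bimodal: mass near 0.02 and mass near 0.5, little in between
  mids <- h$breaks[-1] - 0.005
  expect_equal(sum(h$counts[mids > 0.2 & mids < 0.35]), 0)
})
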