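test_that("the CpG-odds transition matrix is stochastic and stationary", {
  for (w in c(0.3, 0.5, 1, 2)) {
    P <- cpg_transition_matrix(w, gc = 0.33)
    expect_equal(unname(rowSums(P)), rep(1, 4))
    pi <- c(A = 0.335, C = 0.165, G = 0.165, T = 0.335)
    expect_equal(unname(as.vector(pi %*% P)), unname(pi))
    expect_equal(unname(P["C", "G"]), w * 0.165)
    expect_true(all(P >= 0))
  }
  expect_error(cpg_transition_matrix(-1), "positive")
})

test_that("generators are bit-reproducible under a fixed seed", {
  spec <- synthetic_genome_spec(n_chromosomes = 2, chrom_length = 1e5,
                                genes_per_chrom = 10, rng_seed = 81)
  g1 <- gen_genome(spec)
  g2 <- gen_genome(spec)
  expect_identical(as.character(g1$bundle$sequences),
                   as.character(g2$bundle$sequences))
  expect_identical(g1$bundle$genes, g2$bundle$genes)
  expect_identical(g1$truth$subsets, g2$truth$subsets)

  d1 <- gen_depths(spec, n = 100)
  d2 <- gen_depths(spec, n = 100)
  expect_identical(d1, d2)

  p1 <- gen_paralogs(synthetic_genome_spec(n_pairs = 5, codons = 50,
                                           rng_seed = 82))
  p2 <- gen_paralogs(synthetic_genome_spec(n_pairs = 5, codons = 50,
                                           rng_seed = 82))
  expect_identical(p1$pairs, p2$pairs)

  r1 <- gen_reads(c(c1 = strrep("ACGT", 500)), coverage = 2,
                  read_length = 50, seed = 83)
  r2 <- gen_reads(c(c1 = strrep("ACGT", 500)), coverage = 2,
                  read_length = 50, seed = 83)
  expect_identical(as.character(r1), as.character(r2))
})

test_that("truth JSON records parameters, placements and subsets", {
  dir <- withr::local_tempdir()
  spec <- synthetic_genome_spec(n_chromosomes = 2, chrom_length = 1e5,
                                genes_per_chrom = 10, rng_seed = 84)
  g <- gen_genome(spec, dir = dir)
  truth <- jsonlite::read_json(g$paths$truth, simplifyVector = TRUE)
  expect_equal(truth$spec$rng_seed, 84)
  expect_equal(sort(unlist(truth$subsets$ion_transport)),
               sort(copearch:::genes_with_label(g$bundle, "ion_transport")))
  expect_equal(unname(lengths(truth$midpoints)), c(10, 10))
})

test_that("gene placement respects feasibility and non-overlap", {
  expect_error(synthetic_genome_spec(chrom_length = 1e4,
                                     genes_per_chrom = 10,
                                     cds_length = 1500),
               "infeasible")
  spec <- synthetic_genome_spec(n_chromosomes = 1, chrom_length = 2e5,
                                genes_per_chrom = 60, cds_length = 1500,
                                rng_seed = 85)
  b <- gen_genome(spec)$bundle
  g <- b$genes[order(b$genes$start), ]
  expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  expect_true(all(g$start >= 1 & g$end <= 2e5))
})

test_that("clustered placement concentrates genes relative to uniform", {
  set.seed(86)
  mu <- sample_gene_midpoints(200, 1e6, "uniform")
  mc <- sample_gene_midpoints(200, 1e6, "clustered", n_clusters = 5,
                              cluster_sd_bp = 2000)
  expect_lt(median(diff(mc)), median(diff(mu)))
  expect_true(all(mc >= 1 & mc <= 1e6))
})

test_that("depth generator leaves no outliers when nothing is duplicated", {
  spec <- synthetic_genome_spec(duplicated_fraction = 0, rng_seed = 87)
  d <- gen_depths(spec, n = 2000)
  expect_length(d$duplicated, 0)
  scr <- depth_outliers(d$depths, k = 3)
  expect_lte(mean(scr$outlier_high), 0.01)
})

test_that("paralogs at target Ks 0 are identical", {
  spec <- synthetic_genome_spec(n_pairs = 10, codons = 100, target_ks = 0,
                                rng_seed = 88)
  pp <- gen_paralogs(spec)$pairs
  expect_identical(pp$seq_a, pp$seq_b)
})

test_that("read generator warns and writes empty output at zero coverage", {
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "empty.fq")
  expect_warning(gen_reads(c(c1 = strrep("ACGT", 100)), coverage = 0,
                           read_length = 50, seed = 89, fastq_path = fq),
                 "zero reads")
  expect_true(file.exists(fq))
  expect_equal(file.size(fq), 0)
})

test_that("reads carry substitution errors at the requested rate", {
  set.seed(90)
  g <- strrep("A", 5000)
  rd <- gen_reads(c(c1 = g), coverage = 4, read_length = 100,
                  error_rate = 0.02, seed = 91)
  ch <- unlist(strsplit(as.character(rd), ""))
  # reads are A-homopolymer or its revcomp (T); errors are other bases
  err <- mean(!ch %in% c("A", "T"))
  expect_gt(err, 0.005)
  expect_lt(err, 0.03)
})

test_that("generator outputs are valid under the package readers", {
  dir <- withr::local_tempdir()
  spec <- synthetic_genome_spec(n_chromosomes = 2, chrom_length = 1e5,
                                genes_per_chrom = 8, rng_seed = 92)
  g <- gen_genome(spec, dir = dir)
  expect_silent(b <- load_genome(g$paths$fasta, g$paths$gff3,
                                 g$paths$labels))
  expect_equal(nrow(b$genes), 16)
  pfa <- file.path(dir, "pairs.fa")
  gen_paralogs(synthetic_genome_spec(n_pairs = 3, codons = 30,
                                     rng_seed = 93), fasta_path = pfa)
  ss <- Biostrings::readDNAStringSet(pfa)
  expect_length(ss, 6)
})
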