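test_that("loading FASTA + GFF3 preserves coordinates and links CDS", {
  dir <- withr::local_tempdir()
  paths <- write_toy_files(dir)
  b <- load_genome(paths$fasta, paths$gff3)
  expect_equal(nrow(b$genes), 3)
  expect_equal(b$genes$start[b$genes$gene_id == "g2"], 11)
  expect_equal(b$genes$end[b$genes$gene_id == "g2"], 20)
  expect_equal(b$genes$strand[b$genes$gene_id == "g2"], "-")
  expect_equal(sum(b$cds$gene_id == "g1"), 2)
  expect_true(all(b$genes$has_cds))
  expect_equal(b$genes$midpoint, (b$genes$start + b$genes$end) / 2)
})

test_that("referential integrity violations are hard errors naming the culprit", {
  dir <- withr::local_tempdir()
  paths <- write_toy_files(dir)
  bad <- readLines(paths$gff3)
  bad <- c(bad, "chrX\ttest\tgene\t1\t5\t.\t+\t.\tID=g9")
  writeLines(bad, paths$gff3)
  expect_error(load_genome(paths$fasta, paths$gff3), "chrX")

  expect_error(genome_bundle(
    data.frame(name = "c1", length = 100),
    data.frame(gene_id = "g1", chrom = "c1", start = 10, end = 20,
               strand = "+"),
    data.frame(gene_id = "g1", transcript_id = "t1", start = 5, end = 20)),
    "g1")
})

test_that("synthetic genome written then re-read is an equal bundle", {
  dir <- withr::local_tempdir()
  spec <- synthetic_genome_spec(n_chromosomes = 2, chrom_length = 2e5,
                                genes_per_chrom = 25, rng_seed = 42)
  g <- gen_genome(spec, dir = dir)
  b2 <- load_genome(g$paths$fasta, g$paths$gff3, g$paths$labels)
  b1 <- g$bundle
  m <- match(b1$genes$gene_id, b2$genes$gene_id)
  expect_equal(b1$genes$start, b2$genes$start[m])
  expect_equal(b1$genes$end, b2$genes$end[m])
  expect_equal(b1$genes$strand, b2$genes$strand[m])
  expect_equal(b1$genes$labels, b2$genes$labels[m])
  expect_identical(as.character(b1$sequences), as.character(b2$sequences))
})

test_that("extract_cds splices, strand-flips, and matches a per-base oracle", {
  b <- genome_bundle(
    data.frame(name = "c1", length = 9),
    data.frame(gene_id = "g1", chrom = "c1", start = 1, end = 9,
               strand = "+"),
    data.frame(gene_id = c("g1", "g1"), transcript_id = "t1",
               start = c(1, 7), end = c(3, 9)),
    c(c1 = "ATGCCCAAA"))
  expect_equal(extract_cds(b, "g1"), "ATGAAA")

  # palindromic minus-strand single segment is its own reverse complement
  bp <- genome_bundle(
    data.frame(name = "c1", length = 6),
    data.frame(gene_id = "g1", chrom = "c1", start = 1, end = 6,
               strand = "-"),
    data.frame(gene_id = "g1", transcript_id = "t1", start = 1, end = 6),
    c(c1 = "ATGCAT"))
  expect_equal(extract_cds(bp, "g1"), "ATGCAT")

  # random synthetic genes against the brute-force splicer
  spec <- synthetic_genome_spec(n_chromosomes = 2, chrom_length = 1e5,
                                genes_per_chrom = 10, cds_length = 300,
                                rng_seed = 7)
  bs <- gen_genome(spec)$bundle
  for (gid in sample(bs$genes$gene_id, 6))
    expect_equal(extract_cds(bs, gid), brute_force_cds(bs, gid))
})

test_that("extract_cds length equals the sum of segment lengths", {
  b <- toy_bundle()
  for (gid in b$genes$gene_id) {
    seg <- b$cds[b$cds$gene_id == gid, ]
    expect_equal(nchar(extract_cds(b, gid)), sum(seg$end - seg$start + 1))
  }
})

test_that("multi-transcript genes use the longest CDS as representative", {
  b <- genome_bundle(
    data.frame(name = "c1", length = 20),
    data.frame(gene_id = "g1", chrom = "c1", start = 1, end = 20,
               strand = "+"),
    data.frame(gene_id = c("g1", "g1", "g1"),
               transcript_id = c("t1", "t2", "t2"),
               start = c(1, 1, 10), end = c(6, 6, 15)),
    c(c1 = "ATGAAACCCGGGTTTACGTA"))
  expect_equal(nchar(extract_cds(b, "g1")), 12)  # t2: 6 + 6
})

test_that("BED output uses 0-based half-open coordinates, sorted", {
  dir <- withr::local_tempdir()
  b <- toy_bundle()
  bed <- file.path(dir, "sub.bed")
  write_gene_bed(b, "ion_transport", bed)
  lines <- read.table(bed, sep = "\t")
  expect_equal(lines$V2, b$genes$start[1:2] - 1)
  expect_equal(lines$V3, b$genes$end[1:2])

  # empty subset writes an empty file and succeeds
  bed2 <- file.path(dir, "hk2.bed")
  b$genes$labels[2] <- "ion_transport"
  expect_error(write_gene_bed(b, "nosuchlabel", bed2), "available")

  # larger synthetic subset: count and sortedness oracle
  spec <- synthetic_genome_spec(n_chromosomes = 3, chrom_length = 2e5,
                                genes_per_chrom = 25,
                                labeled_subsets = c(ion_transport = 0.8),
                                rng_seed = 3)
  bs <- gen_genome(spec)$bundle
  bed3 <- file.path(dir, "big.bed")
  n <- write_gene_bed(bs, "ion_transport", bed3)
  expect_equal(n, length(copearch:::genes_with_label(bs, "ion_transport")))
  tab <- read.table(bed3, sep = "\t", stringsAsFactors = FALSE)
  expect_false(is.unsorted(tab$V1))
  for (ch in unique(tab$V1)) expect_false(is.unsorted(tab$V2[tab$V1 == ch]))
})
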