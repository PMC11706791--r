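# Shared in-code fixtures for the suite. Everything is built at test time;
# no binary data.

# minimal two-chromosome bundle with three genes, built by hand
toy_bundle <- function() {
  chromosomes <- data.frame(name = c("chr1", "chr2"),
                            length = c(60L, 40L),
                            centromere_pos = c(30, NA))
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1L, 21L, 5L), end = c(9L, 32L, 16L),
    strand = c("+", "-", "+"),
    labels = c("ion_transport", "ion_transport;housekeeping", ""))
  cds <- data.frame(
    gene_id = c("gA", "gA", "gB", "gC"),
    transcript_id = c("gA.t1", "gA.t1", "gB.t1", "gC.t1"),
    start = c(1L, 7L, 21L, 5L), end = c(3L, 9L, 32L, 16L))
  seqs <- c(chr1 = paste(rep("ATGCCCAAAT", 6), collapse = ""),
            chr2 = paste(rep("ACGT", 10), collapse = ""))
  genome_bundle(chromosomes, genes, cds, seqs)
}

# write a toy FASTA/GFF3 pair directly (independent of write_genome)
write_toy_files <- function(dir) {
  fasta <- file.path(dir, "toy.fa")
  gff3 <- file.path(dir, "toy.gff3")
  writeLines(c(">chr1", "ATGCCCAAATATGCCCAAAT", ">chr2", "ACGTACGTACGT"),
             fasta)
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1\t9\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t1\t9\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\ttest\tCDS\t1\t3\t.\t+\t0\tID=g1.c1;Parent=g1.t1",
    "chr1\ttest\tCDS\t7\t9\t.\t+\t0\tID=g1.c2;Parent=g1.t1",
    "chr1\ttest\tgene\t11\t20\t.\t-\t.\tID=g2",
    "chr1\ttest\tmRNA\t11\t20\t.\t-\t.\tID=g2.t1;Parent=g2",
    "chr1\ttest\tCDS\t11\t16\t.\t-\t0\tID=g2.c1;Parent=g2.t1",
    "chr2\ttest\tgene\t2\t10\t.\t+\t.\tID=g3",
    "chr2\ttest\tmRNA\t2\t10\t.\t+\t.\tID=g3.t1;Parent=g3",
    "chr2\ttest\tCDS\t2\t10\t.\t+\t0\tID=g3.c1;Parent=g3.t1"),
    gff3)
  list(fasta = fasta, gff3 = gff3)
}

# independent per-base CDS splicer used as an oracle against extract_cds
brute_force_cds <- function(bundle, gene_id) {
  g <- bundle$genes[bundle$genes$gene_id == gene_id, ]
  seg <- bundle$cds[bundle$cds$gene_id == gene_id, ]
  len_by_tx <- tapply(seg$end - seg$start + 1, seg$transcript_id, sum)
  tx <- names(len_by_tx)[order(-len_by_tx, names(len_by_tx))][1]
  seg <- seg[seg$transcript_id == tx, ]
  seg <- seg[order(seg$start), ]
  chrom <- strsplit(as.character(bundle$sequences[[g$chrom]]), "")[[1]]
  out <- character(0)
  for (i in seq_len(nrow(seg)))
    for (p in seg$start[i]:seg$end[i]) out <- c(out, chrom[p])
  s <- paste(out, collapse = "")
  if (g$strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    s <- paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  s
}

# brute-force one-sample KS sup over all ECDF step points
brute_force_ks_D <- function(x, cdf) {
  xs <- sort(x)
  n <- length(xs)
  d <- 0
  for (i in seq_len(n)) {
    Fi <- cdf(xs[i])
    d <- max(d, abs(i / n - Fi), abs((i - 1) / n - Fi))
  }
  d
}

# four-chromosome midpoint sets for clustering studies
sim_spacing_set <- function(n_per_chrom = 20, chrom_length = 5e6,
                            placement = "uniform", n_clusters = 10,
                            cluster_sd_bp = 0.005 * chrom_length) {
  nm <- paste0("Chr", 1:4)
  mids <- stats::setNames(lapply(1:4, function(i)
    sample_gene_midpoints(n_per_chrom, chrom_length, placement,
                          n_clusters, cluster_sd_bp)), nm)
  spacing_set(mids, stats::setNames(rep(chrom_length, 4), nm))
}
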