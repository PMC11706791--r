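#' Specification for a synthetic genome
#'
#' Bundles every generative parameter the simulators use, with defaults
#' emulating the study system at desk scale: a four-chromosome, AT-rich
#' (GC = 33%) genome whose coding sequences carry a tunable CpG depletion,
#' gene placement either uniform or clustered, negative-binomial per-gene
#' read depths with a duplicated high tail, paralog pairs at a known
#' synonymous divergence, and error-free reads at known coverage.
#'
#' @param n_chromosomes Number of chromosomes (default 4, the karyotype of
#'   the motivating copepod genome).
#' @param chrom_length Chromosome length in bp (default 5e6; Mb-scale toy).
#' @param genes_per_chrom Genes per chromosome (default 125).
#' @param placement `"uniform"` or `"clustered"`.
#' @param n_clusters Clusters per chromosome under clustered placement.
#' @param cluster_sd_bp SD of gene midpoints around a cluster centre
#'   (default 0.5% of `chrom_length`).
#' @param cds_length CDS length in nt (fixed per gene; multiple of 3).
#' @param cpg_odds Target CpG_o/e `w` of generated coding sequence (0, 2].
#' @param gc Stationary GC content of the CDS Markov chain (default 0.33).
#' @param labeled_subsets Named fractions of genes per label.
#' @param depth_mean,depth_dispersion Negative-binomial mean and size of
#'   per-gene depths (defaults 9000 and 400, i.e. CV ~ 5%: near-uniform
#'   coverage over single-copy genes in an inbred genome).
#' @param duplicated_fraction,duplication_multiplier Fraction of genes
#'   whose depth is multiplied (duplicated loci; defaults 0.05 and 10).
#' @param n_pairs,codons,target_ks Paralog-pair model (defaults 200 pairs
#'   of 300 codons at Ks 0.05); `target_ks` may be a vector with
#'   `ks_weights` mixing proportions.
#' @param ks_weights Mixing weights for `target_ks` (default equal).
#' @param coverage,read_length,error_rate Read model (defaults 30x, 100 bp,
#'   error-free).
#' @param rng_seed Master seed; all outputs are bit-reproducible given it.
#' @return List of class `SyntheticGenomeSpec`.
#' @export
synthetic_genome_spec <- function(n_chromosomes = 4,
                                  chrom_length = 5e6,
                                  genes_per_chrom = 125,
                                  placement = c("uniform", "clustered"),
                                  n_clusters = 10,
                                  cluster_sd_bp = NULL,
                                  cds_length = 1500,
                                  cpg_odds = 0.5,
                                  gc = 0.33,
                                  labeled_subsets = c(ion_transport = 0.16,
                                                      housekeeping = 0.16),
                                  depth_mean = 9000,
                                  depth_dispersion = 400,
                                  duplicated_fraction = 0.05,
                                  duplication_multiplier = 10,
                                  n_pairs = 200,
                                  codons = 300,
                                  target_ks = 0.05,
                                  ks_weights = NULL,
                                  coverage = 30,
                                  read_length = 100,
                                  error_rate = 0,
                                  rng_seed = 1L) {
  placement <- match.arg(placement)
  if (is.null(cluster_sd_bp)) cluster_sd_bp <- 0.005 * chrom_length
  if (cpg_odds <= 0) stopf("cpg_odds must be positive")
  if (cds_length %% 3 != 0) stopf("cds_length must be a multiple of 3")
  if (genes_per_chrom * cds_length > 0.9 * chrom_length)
    stopf("infeasible gene density: genes x length > 0.9 chromosome")
  structure(as.list(environment()), class = "SyntheticGenomeSpec")
}

#' CpG-odds first-order Markov transition matrix
#'
#' Transition matrix over A/C/G/T whose stationary distribution has the
#' requested GC content and whose C->G transition probability is scaled so
#' that the expected CpG_o/e of emitted sequence equals `w`: row C gets
#' `P(G|C) = w * pi_G` with its remaining mass spread proportionally, and
#' the G column of the other rows is compensated so stationarity of the
#' base composition is preserved exactly.
#'
#' @param w Target CpG_o/e (odds scaling of the CG dinucleotide).
#' @param gc Stationary GC content (default 0.33).
#' @return 4x4 row-stochastic matrix with dimnames A/C/G/T.
#' @export
cpg_transition_matrix <- function(w, gc = 0.33) {
  if (w <= 0) stopf("cpg_odds must be positive")
  a <- (1 - gc) / 2  # pi_A = pi_T
  cg <- gc / 2       # pi_C = pi_G
  pi <- c(A = a, C = cg, G = cg, T = a)
  s <- (1 - w * cg) / (1 - cg)          # row-C scaling of non-G entries
  gC <- cg * (1 - pi["C"] * (w - 1) / (1 - pi["C"]))  # P(G|x), x != C
  P <- matrix(0, 4, 4, dimnames = list(names(pi), names(pi)))
  for (x in names(pi)) {
    if (x == "C") {
      P[x, ] <- pi * s
      P[x, "G"] <- w * cg
    } else {
      P[x, ] <- pi * (1 - pi["C"] * s) / (1 - pi["C"])
      P[x, "G"] <- gC
    }
  }
  if (any(P < 0)) stopf("cpg_odds %g too large for gc %g", w, gc)
  P / rowSums(P)
}

#' Simulate coding sequences from the CpG-odds Markov chain
#'
#' @param n Number of sequences.
#' @param len Length of each sequence (nt).
#' @param w Target CpG_o/e.
#' @param gc Stationary GC content.
#' @param seed Optional integer seed.
#' @return Character vector of `n` sequences.
#' @export
sim_cpg_cds <- function(n, len, w, gc = 0.33, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  P <- cpg_transition_matrix(w, gc)
  pi <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  cum <- t(apply(P, 1, cumsum))
  bases <- c("A", "C", "G", "T")
  mat <- matrix(0L, n, len)
  mat[, 1] <- findInterval(stats::runif(n), cumsum(pi)) + 1L
  for (t in 2:len) {
    u <- stats::runif(n)
    cur <- mat[, t - 1]
    mat[, t] <- 1L + (u > cum[cur, 1]) + (u > cum[cur, 2]) +
      (u > cum[cur, 3])
  }
  apply(matrix(bases[mat], n, len), 1, paste, collapse = "")
}

#' Sample gene midpoints on one chromosome
#'
#' Uniform placement draws midpoints uniformly; clustered placement draws
#' cluster centres uniformly and genes Normal(centre, `cluster_sd_bp`),
#' truncated to the chromosome. Midpoints keep a margin of half a gene
#' length from the chromosome ends.
#'
#' @param n Number of genes.
#' @param chrom_length Chromosome length (bp).
#' @param placement `"uniform"` or `"clustered"`.
#' @param n_clusters,cluster_sd_bp Clustered-placement parameters.
#' @param margin Minimum distance of a midpoint from either end (bp).
#' @return Sorted numeric vector of midpoints.
#' @export
sample_gene_midpoints <- function(n, chrom_length,
                                  placement = c("uniform", "clustered"),
                                  n_clusters = 10, cluster_sd_bp = NULL,
                                  margin = 0) {
  placement <- match.arg(placement)
  if (is.null(cluster_sd_bp)) cluster_sd_bp <- 0.005 * chrom_length
  lo <- margin + 1
  hi <- chrom_length - margin
  draw <- function(m) {
    if (placement == "uniform") {
      stats::runif(m, lo, hi)
    } else {
      centers <- stats::runif(n_clusters, lo, hi)
      x <- stats::rnorm(m, sample(centers, m, replace = TRUE),
                        cluster_sd_bp)
      pmin(pmax(x, lo), hi)
    }
  }
  sort(draw(n))
}

# internal: place n non-overlapping gene spans of length len on a chromosome
place_genes <- function(n, chrom_length, len, placement, n_clusters,
                        cluster_sd_bp, max_iter = 500) {
  margin <- ceiling(len / 2)
  mids <- sample_gene_midpoints(n, chrom_length, placement, n_clusters,
                                cluster_sd_bp, margin)
  for (it in seq_len(max_iter)) {
    starts <- round(mids) - floor(len / 2)
    ord <- order(starts)
    bad_sorted <- which(diff(starts[ord]) < len) + 1L  # overlaps predecessor
    if (!length(bad_sorted)) {
      return(data.frame(start = starts, end = starts + len - 1L))
    }
    idx <- ord[bad_sorted]
    mids[idx] <- sample_gene_midpoints(length(idx), chrom_length, placement,
                                       n_clusters, cluster_sd_bp, margin)
  }
  stopf("could not place %d non-overlapping genes after %d resampling rounds",
        n, max_iter)
}

#' Generate a synthetic genome
#'
#' Emits a multi-chromosome genome whose coding sequences come from the
#' CpG-odds Markov chain, with genes placed uniformly or in clusters, label
#' subsets assigned at random, and (optionally) FASTA/GFF3/labels/terms
#' files plus a truth JSON recording every parameter and placement.
#'
#' The intergenic background is i.i.d. sequence at the same GC content.
#' Minus-strand genes carry the reverse complement of their CDS on the
#' chromosome, so [extract_cds()] recovers the simulated sequence exactly.
#'
#' @param spec A [synthetic_genome_spec()].
#' @param dir Output directory; `NULL` (default) skips file output.
#' @return List: `bundle` (a `GenomeBundle`), `truth` (list), and — when
#'   `dir` is given — `paths`.
#' @export
gen_genome <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "SyntheticGenomeSpec"))
  set.seed(spec$rng_seed)
  bases <- c("A", "C", "G", "T")
  pbg <- c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2, (1 - spec$gc) / 2)
  chrom_names <- sprintf("Chr%d", seq_len(spec$n_chromosomes))

  genes <- list(); cds <- list(); seqs <- character(spec$n_chromosomes)
  truth_mid <- list()
  n_total <- spec$n_chromosomes * spec$genes_per_chrom
  all_cds <- sim_cpg_cds(n_total, spec$cds_length, spec$cpg_odds, spec$gc)
  gidx <- 0L
  for (ci in seq_len(spec$n_chromosomes)) {
    span <- place_genes(spec$genes_per_chrom, spec$chrom_length,
                        spec$cds_length, spec$placement, spec$n_clusters,
                        spec$cluster_sd_bp)
    span <- span[order(span$start), , drop = FALSE]
    bg <- sample(bases, spec$chrom_length, replace = TRUE, prob = pbg)
    strand <- sample(c("+", "-"), spec$genes_per_chrom, replace = TRUE)
    ids <- sprintf("g%05d", gidx + seq_len(spec$genes_per_chrom))
    for (j in seq_len(spec$genes_per_chrom)) {
      s <- all_cds[gidx + j]
      if (strand[j] == "-") s <- revcomp_chr(s)
      bg[span$start[j]:span$end[j]] <- strsplit(s, "")[[1]]
    }
    seqs[ci] <- paste(bg, collapse = "")
    genes[[ci]] <- data.frame(gene_id = ids, chrom = chrom_names[ci],
                              start = span$start, end = span$end,
                              strand = strand, stringsAsFactors = FALSE)
    cds[[ci]] <- data.frame(gene_id = ids,
                            transcript_id = paste0(ids, ".t1"),
                            start = span$start, end = span$end,
                            stringsAsFactors = FALSE)
    truth_mid[[chrom_names[ci]]] <- (span$start + span$end) / 2
    gidx <- gidx + spec$genes_per_chrom
  }
  genes <- do.call(rbind, genes)
  cds <- do.call(rbind, cds)

  # disjoint random label subsets
  pool <- genes$gene_id
  labels <- stats::setNames(rep("", nrow(genes)), genes$gene_id)
  subset_ids <- list()
  for (lab in names(spec$labeled_subsets)) {
    n_lab <- round(spec$labeled_subsets[[lab]] * nrow(genes))
    pick <- sample(pool, min(n_lab, length(pool)))
    labels[pick] <- lab
    subset_ids[[lab]] <- sort(pick)
    pool <- setdiff(pool, pick)
  }
  genes$labels <- unname(labels)

  chromosomes <- data.frame(name = chrom_names,
                            length = spec$chrom_length,
                            centromere_pos = spec$chrom_length / 2)
  bundle <- genome_bundle(chromosomes, genes, cds,
                          stats::setNames(seqs, chrom_names))
  truth <- list(spec = unclass(spec)[!vapply(unclass(spec), is.null,
                                             logical(1))],
                midpoints = truth_mid, subsets = subset_ids)
  out <- list(bundle = bundle, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(fasta = file.path(dir, "genome.fa"),
                  gff3 = file.path(dir, "genes.gff3"),
                  labels = file.path(dir, "labels.tsv"),
                  centromeres = file.path(dir, "centromeres.tsv"),
                  truth = file.path(dir, "truth_genome.json"))
    write_genome(bundle, paths$fasta, paths$gff3, paths$labels)
    utils::write.table(chromosomes[, c("name", "centromere_pos")],
                       paths$centromeres, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}

#' Generate per-gene read depths with a duplicated high tail
#'
#' Depths are negative-binomial; a `duplicated_fraction` of genes has its
#' depth multiplied by `duplication_multiplier`, emulating collapsed
#' duplicated loci. The truth lists the duplicated gene ids.
#'
#' @param spec A [synthetic_genome_spec()] (depth model fields used).
#' @param gene_ids Gene identifiers; defaults to `g00001...` up to the
#'   spec's total gene count.
#' @param n Number of genes; overrides the spec's total when given.
#' @param path Optional TSV output path (`gene_id <tab> depth`); a truth
#'   JSON is written next to it.
#' @return List: `depths` (data.frame gene_id, depth), `duplicated`
#'   (character vector of true duplicated gene ids).
#' @export
gen_depths <- function(spec, gene_ids = NULL, n = NULL, path = NULL) {
  stopifnot(inherits(spec, "SyntheticGenomeSpec"))
  set.seed(derive_seed(spec$rng_seed, 2L))
  if (is.null(n))
    n <- if (!is.null(gene_ids)) length(gene_ids) else
      spec$n_chromosomes * spec$genes_per_chrom
  if (is.null(gene_ids)) gene_ids <- sprintf("g%05d", seq_len(n))
  depth <- stats::rnbinom(n, size = spec$depth_dispersion,
                          mu = spec$depth_mean)
  n_dup <- round(spec$duplicated_fraction * n)
  dup <- if (n_dup > 0) sample(gene_ids, n_dup) else character(0)
  depth[gene_ids %in% dup] <- depth[gene_ids %in% dup] *
    spec$duplication_multiplier
  df <- data.frame(gene_id = gene_ids, depth = depth,
                   stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(list(duplicated = sort(dup)),
                         paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(depths = df, duplicated = sort(dup))
}

# internal: synonymous single-nt neighbours of every sense codon
syn_neighbours <- function() {
  if (!is.null(.ng86_cache$syn_nb)) return(.ng86_cache$syn_nb)
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  nb <- lapply(names(code)[code != "*"], function(cd) {
    ch <- strsplit(cd, "")[[1]]
    out <- character(0)
    for (pos in 1:3) for (b in setdiff(bases, ch[pos])) {
      mut <- ch; mut[pos] <- b
      mutc <- paste(mut, collapse = "")
      if (code[[mutc]] == code[[cd]]) out <- c(out, mutc)
    }
    out
  })
  names(nb) <- names(code)[code != "*"]
  .ng86_cache$syn_nb <- nb
  nb
}

#' Generate paralog pairs at known synonymous divergence
#'
#' Each pair descends from a random ancestral codon sequence; a Poisson
#' number of synonymous single-nucleotide substitutions (expected
#' `target_Ks * S`, with `S` the NG86 synonymous site count of the
#' ancestor) is applied, each change drawn uniformly from the synonymous
#' neighbourhoods of the current sequence and assigned to one of the two
#' copies at random. `target_ks` may be a mixture (with `ks_weights`).
#'
#' @param spec A [synthetic_genome_spec()] (paralog model fields used).
#' @param fasta_path Optional output FASTA of the pairs (`pairK_a/b`); a
#'   truth JSON is written next to it.
#' @return List: `pairs` (data.frame `id_a, id_b, seq_a, seq_b,
#'   target_ks`), `truth`.
#' @export
gen_paralogs <- function(spec, fasta_path = NULL) {
  stopifnot(inherits(spec, "SyntheticGenomeSpec"))
  set.seed(derive_seed(spec$rng_seed, 3L))
  tab <- ng86_tables()
  nb <- syn_neighbours()
  sense <- tab$sense
  w <- spec$ks_weights
  ks_pool <- spec$target_ks
  if (is.null(w)) w <- rep(1 / length(ks_pool), length(ks_pool))
  ks_assign <- sample(ks_pool, spec$n_pairs, replace = TRUE, prob = w)

  one_pair <- function(target) {
    anc <- sample(sense, spec$codons, replace = TRUE)
    S <- sum(tab$syn_sites[anc])
    nsub <- stats::rpois(1, target * S)
    copies <- list(a = anc, b = anc)
    if (nsub > 0) for (i in seq_len(nsub)) {
      which_copy <- sample(c("a", "b"), 1)
      seqc <- copies[[which_copy]]
      cand <- which(lengths(nb[seqc]) > 0)
      pos <- sample(cand, 1)
      opts <- nb[[seqc[pos]]]
      seqc[pos] <- opts[sample.int(length(opts), 1)]
      copies[[which_copy]] <- seqc
    }
    c(paste(copies$a, collapse = ""), paste(copies$b, collapse = ""))
  }
  mat <- vapply(ks_assign, one_pair, character(2))
  pairs <- data.frame(id_a = sprintf("pair%03d_a", seq_len(spec$n_pairs)),
                      id_b = sprintf("pair%03d_b", seq_len(spec$n_pairs)),
                      seq_a = mat[1, ], seq_b = mat[2, ],
                      target_ks = ks_assign, stringsAsFactors = FALSE)
  truth <- list(target_ks = ks_assign, n_pairs = spec$n_pairs,
                codons = spec$codons)
  if (!is.null(fasta_path)) {
    ss <- Biostrings::DNAStringSet(c(rbind(pairs$seq_a, pairs$seq_b)))
    names(ss) <- c(rbind(pairs$id_a, pairs$id_b))
    Biostrings::writeXStringSet(ss, fasta_path)
    jsonlite::write_json(truth, paste0(fasta_path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(pairs = pairs, truth = truth)
}

#' Generate sequencing reads from a genome
#'
#' Uniform start positions on both strands, optional uniform substitution
#' errors, fixed read length. Zero coverage produces an empty output with a
#' warning.
#'
#' @param genome A `GenomeBundle`, named character vector / DNAStringSet of
#'   chromosome sequences, or FASTA path.
#' @param coverage Target mean coverage.
#' @param read_length Read length (bp).
#' @param error_rate Per-base substitution error probability.
#' @param seed Optional integer seed.
#' @param fastq_path Optional FASTQ output path.
#' @return [Biostrings::DNAStringSet] of reads (invisibly when writing).
#' @export
gen_reads <- function(genome, coverage = 30, read_length = 100,
                      error_rate = 0, seed = NULL, fastq_path = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(genome, "GenomeBundle")) genome <- genome$sequences
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  genome <- toupper(genome)
  bases <- c("A", "C", "G", "T")
  reads <- character(0)
  for (chrom in names(genome)) {
    L <- nchar(genome[[chrom]])
    if (L < read_length) next
    n_reads <- floor(coverage * L / read_length)
    if (n_reads < 1) next
    starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
    r <- substring(genome[[chrom]], starts, starts + read_length - 1L)
    flip <- stats::runif(n_reads) < 0.5
    if (any(flip))
      r[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(r[flip])))
    reads <- c(reads, r)
  }
  if (!length(reads)) {
    warning("zero reads generated (coverage too low or genome too short)")
    rs <- Biostrings::DNAStringSet(character(0))
    if (!is.null(fastq_path)) file.create(fastq_path)
    return(rs)
  }
  if (error_rate > 0) {
    m <- do.call(rbind, strsplit(reads, ""))
    hit <- which(matrix(stats::runif(length(m)) < error_rate, nrow(m)))
    if (length(hit)) {
      # substitute with one of the three other bases
      m[hit] <- vapply(m[hit], function(b)
        sample(setdiff(bases, b), 1), character(1))
      reads <- apply(m, 1, paste, collapse = "")
    }
  }
  rs <- Biostrings::DNAStringSet(reads)
  names(rs) <- sprintf("read%07d", seq_along(reads))
  if (!is.null(fastq_path)) {
    quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(rs)))
    Biostrings::writeXStringSet(rs, fastq_path, format = "fastq",
                                qualities = quals)
    return(invisible(rs))
  }
  rs
}
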