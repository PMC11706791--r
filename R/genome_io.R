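#' Construct a genome bundle
#'
#' A `GenomeBundle` is the in-memory unit every analysis consumes: the
#' chromosome table (name, length, optional centromere position), the gene
#' table (coordinates, strand, labels, annotation terms), the CDS segment
#' table (per transcript) and the chromosome sequences.
#'
#' Coordinates are stored 1-based inclusive (the GFF3 dialect); conversion
#' to BED's 0-based half-open happens only at the output boundary.
#'
#' @param chromosomes data.frame with columns `name`, `length` and
#'   optionally `centromere_pos` (bp, `NA` when unknown).
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` and optionally `labels` and `terms` (`;`-separated tags).
#' @param cds data.frame with columns `gene_id`, `transcript_id`, `start`,
#'   `end`; empty data.frame allowed.
#' @param sequences Named [Biostrings::DNAStringSet] (or named character
#'   vector) of chromosome sequences; may be `NULL` for position-only work.
#' @return An object of class `GenomeBundle`.
#' @export
genome_bundle <- function(chromosomes, genes, cds = NULL, sequences = NULL) {
  chromosomes <- as.data.frame(chromosomes)
  genes <- as.data.frame(genes)
  if (is.null(cds))
    cds <- data.frame(gene_id = character(), transcript_id = character(),
                      start = integer(), end = integer())
  cds <- as.data.frame(cds)
  if (!is.null(sequences) && !methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  if (is.null(chromosomes$centromere_pos))
    chromosomes$centromere_pos <- NA_real_
  if (is.null(genes$labels)) genes$labels <- ""
  if (is.null(genes$terms)) genes$terms <- ""
  genes$labels[is.na(genes$labels)] <- ""
  genes$terms[is.na(genes$terms)] <- ""
  genes$midpoint <- (genes$start + genes$end) / 2
  genes$has_cds <- genes$gene_id %in% cds$gene_id

  if (any(chromosomes$length <= 0))
    stopf("chromosome lengths must be positive")
  bad_cen <- !is.na(chromosomes$centromere_pos) &
    (chromosomes$centromere_pos <= 0 |
       chromosomes$centromere_pos > chromosomes$length)
  if (any(bad_cen))
    stopf("centromere position outside chromosome: %s",
          paste(chromosomes$name[bad_cen], collapse = ", "))
  unknown <- setdiff(genes$chrom, chromosomes$name)
  if (length(unknown))
    stopf("gene(s) reference unknown chromosome(s): %s",
          paste(unique(unknown), collapse = ", "))
  if (any(genes$start > genes$end))
    stopf("gene start > end for: %s",
          paste(genes$gene_id[genes$start > genes$end], collapse = ", "))
  clen <- stats::setNames(chromosomes$length, chromosomes$name)
  over <- genes$end > clen[genes$chrom]
  if (any(over))
    stopf("gene(s) extend past chromosome end: %s",
          paste(genes$gene_id[over], collapse = ", "))
  if (nrow(cds)) {
    gi <- match(cds$gene_id, genes$gene_id)
    if (anyNA(gi))
      stopf("CDS segment(s) reference unknown gene(s): %s",
            paste(unique(cds$gene_id[is.na(gi)]), collapse = ", "))
    outside <- cds$start < genes$start[gi] | cds$end > genes$end[gi]
    if (any(outside))
      stopf("CDS outside gene span for gene(s): %s",
            paste(unique(cds$gene_id[outside]), collapse = ", "))
    # segments of one transcript must not overlap
    by_tx <- split(cds[, c("start", "end")], cds$transcript_id)
    for (tx in names(by_tx)) {
      seg <- by_tx[[tx]][order(by_tx[[tx]]$start), , drop = FALSE]
      if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)]))
        stopf("overlapping CDS segments in transcript %s", tx)
    }
  }
  if (!is.null(sequences)) {
    missing_seq <- setdiff(chromosomes$name, names(sequences))
    if (length(missing_seq))
      stopf("no sequence for chromosome(s): %s",
            paste(missing_seq, collapse = ", "))
  }
  structure(list(chromosomes = chromosomes, genes = genes, cds = cds,
                 sequences = sequences),
            class = "GenomeBundle")
}

#' @export
print.GenomeBundle <- function(x, ...) {
  cat(sprintf("GenomeBundle: %d chromosome(s) (%.2f Mb), %d gene(s), %d CDS segment(s)\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6,
              nrow(x$genes), nrow(x$cds)))
  invisible(x)
}

#' Load a genome from FASTA + GFF3 (+ optional labels / centromeres)
#'
#' Builds a [genome_bundle()] from the standard formats. Gene, mRNA and CDS
#' features are linked through GFF3 `ID`/`Parent` attributes; genes without
#' any CDS are kept but flagged (`has_cds = FALSE`). Soft-masked (lowercase)
#' sequence is uppercased on load.
#'
#' @param fasta_path FASTA of chromosome sequences.
#' @param gff3_path GFF3 annotation with gene/mRNA/CDS features.
#' @param labels_path Optional TSV `gene_id <tab> label` (one row per tag;
#'   repeated gene_ids accumulate tags).
#' @param centromeres_path Optional TSV `chrom <tab> position_bp`.
#' @return A `GenomeBundle`.
#' @export
load_genome <- function(fasta_path, gff3_path, labels_path = NULL,
                        centromeres_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))

  gr <- rtracklayer::import(gff3_path)
  type <- as.character(gr$type)
  id <- as.character(gr$ID)
  parent <- vapply(gr$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))

  is_gene <- type == "gene"
  is_tx <- type %in% c("mRNA", "transcript")
  is_cds <- type == "CDS"

  genes <- data.frame(
    gene_id = id[is_gene],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene],
    stringsAsFactors = FALSE)
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"

  tx2gene <- stats::setNames(parent[is_tx], id[is_tx])
  cds_tx <- parent[is_cds]
  # CDS may parent a gene directly (no mRNA level)
  cds_gene <- ifelse(cds_tx %in% names(tx2gene), tx2gene[cds_tx], cds_tx)
  cds <- data.frame(
    gene_id = unname(cds_gene),
    transcript_id = unname(cds_tx),
    start = GenomicRanges::start(gr)[is_cds],
    end = GenomicRanges::end(gr)[is_cds],
    stringsAsFactors = FALSE)

  chromosomes <- data.frame(name = names(seqs),
                            length = Biostrings::width(seqs),
                            centromere_pos = NA_real_,
                            stringsAsFactors = FALSE)
  if (!is.null(centromeres_path)) {
    cen <- utils::read.table(centromeres_path, sep = "\t", header = FALSE,
                             col.names = c("chrom", "pos"),
                             stringsAsFactors = FALSE)
    chromosomes$centromere_pos <-
      cen$pos[match(chromosomes$name, cen$chrom)]
  }

  if (!is.null(labels_path)) {
    lab <- utils::read.table(labels_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    names(lab)[1:2] <- c("gene_id", "label")
    agg <- tapply(lab$label, lab$gene_id,
                  function(v) paste(sort(unique(v)), collapse = ";"))
    genes$labels <- as.character(agg[genes$gene_id])
    genes$labels[is.na(genes$labels)] <- ""
  }

  genome_bundle(chromosomes, genes, cds, seqs)
}

# internal: gene_ids of genes carrying a label (tags are ;-separated)
genes_with_label <- function(bundle, label) {
  tags <- strsplit(bundle$genes$labels, ";", fixed = TRUE)
  hit <- vapply(tags, function(t) label %in% t, logical(1))
  bundle$genes$gene_id[hit]
}

# internal: all labels present in a bundle
available_labels <- function(bundle) {
  sort(unique(unlist(strsplit(bundle$genes$labels, ";", fixed = TRUE))))
}

# internal: representative transcript (longest total CDS) per gene
representative_tx <- function(bundle, gene_id) {
  seg <- bundle$cds[bundle$cds$gene_id == gene_id, , drop = FALSE]
  if (!nrow(seg)) return(NULL)
  len_by_tx <- tapply(seg$end - seg$start + 1, seg$transcript_id, sum)
  best <- names(len_by_tx)[order(-len_by_tx, names(len_by_tx))][1]
  seg[seg$transcript_id == best, , drop = FALSE]
}

#' Extract the representative coding sequence of a gene
#'
#' CDS segments of the longest transcript are concatenated in genomic order
#' and reverse-complemented for minus-strand genes, yielding the
#' 5'->3' coding sequence. Ambiguity characters are not tolerated inside
#' coding sequence.
#'
#' @param bundle A `GenomeBundle` with sequences.
#' @param gene_id Gene identifier.
#' @return Uppercase coding sequence as a single character string.
#' @export
extract_cds <- function(bundle, gene_id) {
  if (is.null(bundle$sequences))
    stopf("bundle carries no sequences")
  g <- bundle$genes[bundle$genes$gene_id == gene_id, , drop = FALSE]
  if (!nrow(g)) stopf("unknown gene: %s", gene_id)
  seg <- representative_tx(bundle, gene_id)
  if (is.null(seg)) stopf("gene %s has no CDS", gene_id)
  seg <- seg[order(seg$start), , drop = FALSE]
  chrom_seq <- as.character(bundle$sequences[[g$chrom]])
  parts <- substring(chrom_seq, seg$start, seg$end)
  s <- paste(parts, collapse = "")
  if (grepl("[^ACGT]", s))
    stopf("non-ACGT character in CDS of gene %s", gene_id)
  if (g$strand == "-") s <- revcomp_chr(s)
  s
}

#' Write a labeled gene subset as BED6
#'
#' One line per gene carrying `subset_label`, 0-based half-open, sorted by
#' chromosome then start. Score column is 0.
#'
#' @param bundle A `GenomeBundle`.
#' @param subset_label Label tag selecting the subset.
#' @param path Output path.
#' @return Invisibly, the number of records written.
#' @export
write_gene_bed <- function(bundle, subset_label, path) {
  ids <- genes_with_label(bundle, subset_label)
  if (!length(ids) && !subset_label %in% available_labels(bundle))
    stopf("unknown label '%s'; available: %s", subset_label,
          paste(available_labels(bundle), collapse = ", "))
  g <- bundle$genes[bundle$genes$gene_id %in% ids, , drop = FALSE]
  g <- g[order(g$chrom, g$start), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   g$chrom, g$start - 1L, g$end, g$gene_id, g$strand)
  writeLines(lines, path)
  invisible(length(lines))
}

#' Write a genome bundle to FASTA + GFF3 (+ labels TSV)
#'
#' Inverse of [load_genome()]; used by the synthetic generator and by
#' round-trip tests. Each gene is written as gene/mRNA/CDS records with
#' `ID`/`Parent` attributes.
#'
#' @param bundle A `GenomeBundle` with sequences.
#' @param fasta_path,gff3_path,labels_path Output paths; `labels_path`
#'   may be `NULL` to skip labels.
#' @return Invisibly, `NULL`.
#' @export
write_genome <- function(bundle, fasta_path, gff3_path, labels_path = NULL) {
  if (is.null(bundle$sequences)) stopf("bundle carries no sequences")
  Biostrings::writeXStringSet(bundle$sequences, fasta_path)
  con <- file(gff3_path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(bundle$chromosomes)))
    writeLines(sprintf("##sequence-region %s 1 %d",
                       bundle$chromosomes$name[i],
                       bundle$chromosomes$length[i]), con)
  g <- bundle$genes[order(bundle$genes$chrom, bundle$genes$start), ,
                    drop = FALSE]
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    writeLines(sprintf("%s\tcopearch\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom[i], g$start[i], g$end[i], g$strand[i], gid),
               con)
    seg <- bundle$cds[bundle$cds$gene_id == gid, , drop = FALSE]
    for (tx in unique(seg$transcript_id)) {
      txseg <- seg[seg$transcript_id == tx, , drop = FALSE]
      writeLines(sprintf("%s\tcopearch\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                         g$chrom[i], min(txseg$start), max(txseg$end),
                         g$strand[i], tx, gid), con)
      txseg <- txseg[order(txseg$start), , drop = FALSE]
      for (j in seq_len(nrow(txseg)))
        writeLines(sprintf("%s\tcopearch\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
                           g$chrom[i], txseg$start[j], txseg$end[j],
                           g$strand[i], tx, j, tx), con)
    }
  }
  if (!is.null(labels_path)) {
    tags <- strsplit(bundle$genes$labels, ";", fixed = TRUE)
    n <- lengths(tags)
    df <- data.frame(gene_id = rep(bundle$genes$gene_id, n),
                     label = unlist(tags))
    df <- df[df$label != "", , drop = FALSE]
    utils::write.table(df, labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(NULL)
}
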