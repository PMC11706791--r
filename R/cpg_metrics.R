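#' Per-gene CpG observed/expected ratio
#'
#' The gene-body methylation signature: in lineages with historical CpG
#' methylation, deamination of 5-methylcytosine converts CpG to TpG over
#' evolutionary time, so coding sequence shows fewer CpG dinucleotides than
#' expected from its C and G content. The statistic is
#' `CpG_o/e = f_CpG / (f_C * f_G)` with `f_C = n_C / L`, `f_G = n_G / L`
#' and `f_CpG = n_CpG / (L - 1)` (overlapping dinucleotide windows).
#'
#' Positions with non-ACGT characters are excluded from both numerator and
#' denominators, with lengths adjusted: `L` counts ACGT positions and the
#' dinucleotide denominator counts adjacent pairs of valid positions.
#' When the sequence contains no C or no G the ratio is undefined and the
#' record is flagged (`defined = FALSE`).
#'
#' @param seq Character scalar, the coding sequence (uppercased internally).
#' @param gene_id Optional identifier carried through to the record.
#' @param dinuc_denominator `"L-1"` (default) or `"L"`; which length the
#'   dinucleotide frequency is divided by.
#' @return One-row data.frame: `gene_id, L, n_C, n_G, n_CpG, f_C, f_G,
#'   f_CpG, cpg_oe, defined`.
#' @export
compute_cpg_oe <- function(seq, gene_id = NA_character_,
                           dinuc_denominator = c("L-1", "L")) {
  dinuc_denominator <- match.arg(dinuc_denominator)
  stopifnot(is.character(seq), length(seq) == 1L)
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (length(ch) < 2L) stopf("sequence must have length >= 2")
  valid <- ch %in% c("A", "C", "G", "T")
  L <- sum(valid)
  n_C <- sum(ch == "C")
  n_G <- sum(ch == "G")
  pair_valid <- valid[-length(ch)] & valid[-1L]
  n_win <- sum(pair_valid)
  n_CpG <- sum(ch[-length(ch)] == "C" & ch[-1L] == "G")
  denom_win <- if (dinuc_denominator == "L-1") n_win else L
  f_C <- if (L > 0) n_C / L else NA_real_
  f_G <- if (L > 0) n_G / L else NA_real_
  f_CpG <- if (denom_win > 0) n_CpG / denom_win else NA_real_
  defined <- isTRUE(L > 0 && denom_win > 0 && f_C * f_G > 0)
  cpg_oe <- if (defined) f_CpG / (f_C * f_G) else NA_real_
  data.frame(gene_id = gene_id, L = L, n_C = n_C, n_G = n_G, n_CpG = n_CpG,
             f_C = f_C, f_G = f_G, f_CpG = f_CpG, cpg_oe = cpg_oe,
             defined = defined, stringsAsFactors = FALSE)
}

#' CpG_o/e records for every coding gene of a bundle
#'
#' @param bundle A `GenomeBundle` with sequences.
#' @param dinuc_denominator Passed to [compute_cpg_oe()].
#' @return data.frame of per-gene records (genes without CDS are skipped).
#' @export
cpg_table <- function(bundle, dinuc_denominator = "L-1") {
  ids <- bundle$genes$gene_id[bundle$genes$has_cds]
  recs <- lapply(ids, function(g)
    compute_cpg_oe(extract_cds(bundle, g), gene_id = g,
                   dinuc_denominator = dinuc_denominator))
  do.call(rbind, recs)
}

#' Genome-wide summary of CpG_o/e records
#'
#' Undefined records are excluded (with a warning), matching the convention
#' that genes lacking C or G carry no information about CpG depletion.
#' Modality of the distribution is reported descriptively as the number of
#' local maxima of a Gaussian kernel density estimate with the default
#' bandwidth rule.
#'
#' @param records data.frame from [cpg_table()] / [compute_cpg_oe()].
#' @param threshold Depletion threshold for `fraction_below` (default 1).
#' @return List: `n_genes`, `mean`, `sd`, `min`, `max`, `fraction_below`,
#'   `pct_below` (one decimal, half away from zero), `n_modes`, `threshold`.
#' @export
summarize_cpg <- function(records, threshold = 1.0) {
  def <- records[records$defined & !is.na(records$cpg_oe), , drop = FALSE]
  if (!nrow(def)) stopf("all CpG records are undefined")
  n_undef <- nrow(records) - nrow(def)
  if (n_undef > 0)
    warning(sprintf("%d undefined CpG record(s) excluded from summary",
                    n_undef))
  x <- def$cpg_oe
  n_modes <- if (length(x) >= 10) {
    d <- stats::density(x, bw = "nrd0")
    y <- d$y
    sum(diff(sign(diff(y))) == -2)
  } else NA_integer_
  below <- sum(x < threshold)
  list(n_genes = length(x),
       mean = mean(x), sd = stats::sd(x), min = min(x), max = max(x),
       fraction_below = below / length(x),
       pct_below = percent_of(below, length(x)),
       n_modes = n_modes, threshold = threshold)
}

#' Lowest- and highest-CpG_o/e tail gene sets
#'
#' Both sets have size `floor(q * n)` over the defined records; ties in
#' `cpg_oe` break by lexicographic `gene_id` so the sets are deterministic.
#'
#' @param records data.frame of CpG records.
#' @param q Tail fraction in (0, 0.5); default 0.05 (the top/bottom 5%).
#' @return List with `low` and `high` character vectors of gene ids and
#'   `size`, the common set size.
#' @export
cpg_tail_sets <- function(records, q = 0.05) {
  stopifnot(q > 0, q < 0.5)
  def <- records[records$defined & !is.na(records$cpg_oe), , drop = FALSE]
  n <- nrow(def)
  size <- floor(q * n)
  if (size < 1) stopf("tail size floor(q*n) = 0; need more records")
  low_ord <- order(def$cpg_oe, def$gene_id)
  high_ord <- order(-def$cpg_oe, def$gene_id)
  list(low = def$gene_id[low_ord[seq_len(size)]],
       high = def$gene_id[high_ord[seq_len(size)]],
       size = size)
}
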