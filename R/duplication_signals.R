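#' Read-depth IQR outlier screen for duplicated genes
#'
#' Flags genes whose mean read depth exceeds `Q3 + k * IQR` of the cohort —
#' an exceptionally high mapped depth is the expected signature of a
#' collapsed or recently duplicated locus. Quartiles use linear
#' interpolation (quantile type 7). Low-side deviations (`< Q1 - k*IQR`)
#' are reported with a separate flag but are not "outliers" in the
#' duplication sense.
#'
#' @param depth_table data.frame with columns `gene_id` and `depth`
#'   (mean per-gene read depth, any consistent unit, >= 0).
#' @param k Fence multiplier (default 1.5).
#' @param qtype Quantile type passed to [stats::quantile()] (default 7).
#' @return data.frame: `gene_id, depth, q1, q3, iqr, outlier_high,
#'   low_flag`.
#' @export
depth_outliers <- function(depth_table, k = 1.5, qtype = 7) {
  d <- depth_table$depth
  if (length(d) < 4) stopf("need at least 4 genes for quartiles")
  if (any(is.na(d)) || any(d < 0)) stopf("depths must be non-negative")
  q <- stats::quantile(d, c(0.25, 0.75), type = qtype, names = FALSE)
  iqr <- q[2] - q[1]
  data.frame(gene_id = depth_table$gene_id, depth = d,
             q1 = q[1], q3 = q[2], iqr = iqr,
             outlier_high = d > q[2] + k * iqr,
             low_flag = d < q[1] - k * iqr,
             stringsAsFactors = FALSE)
}

#' Mean per-gene depth from a per-base coverage BED
#'
#' Aggregates a BED-like per-base coverage table (chrom, start, end, depth;
#' 0-based half-open intervals) to the mean depth over each gene span.
#' Positions not covered by any interval count as depth 0.
#'
#' @param coverage data.frame or path to a headerless TSV with columns
#'   chrom, start, end, depth.
#' @param bundle A `GenomeBundle`.
#' @return data.frame `gene_id, depth` usable with [depth_outliers()].
#' @export
depth_from_bed <- function(coverage, bundle) {
  if (is.character(coverage))
    coverage <- utils::read.table(coverage, sep = "\t", header = FALSE,
                                  col.names = c("chrom", "start", "end",
                                                "depth"))
  g <- bundle$genes
  out <- numeric(nrow(g))
  for (chrom in unique(g$chrom)) {
    cv <- coverage[coverage$chrom == chrom, , drop = FALSE]
    gi <- which(g$chrom == chrom)
    if (!nrow(cv)) next
    cov_ir <- IRanges::IRanges(cv$start + 1L, cv$end)  # to 1-based
    gene_ir <- IRanges::IRanges(g$start[gi], g$end[gi])
    hits <- IRanges::findOverlaps(gene_ir, cov_ir)
    ov <- IRanges::pintersect(gene_ir[S4Vectors::queryHits(hits)],
                              cov_ir[S4Vectors::subjectHits(hits)])
    wsum <- tapply(IRanges::width(ov) * cv$depth[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits), sum)
    out[gi[as.integer(names(wsum))]] <- as.numeric(wsum)
  }
  data.frame(gene_id = g$gene_id,
             depth = out / (g$end - g$start + 1),
             stringsAsFactors = FALSE)
}

# ---- NG86 synonymous divergence ------------------------------------------

# internal environment caching the NG86 lookup tables
.ng86_cache <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(.ng86_cache$tab)) return(.ng86_cache$tab)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  bases <- c("A", "C", "G", "T")
  aa <- unname(code)

  # per-codon synonymous site count: at each position, the fraction of the
  # three single-nucleotide changes that preserve the amino acid; changes
  # to stop codons count as nonsynonymous, so S + N = 3 per codon
  syn_sites <- stats::setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    if (code[[cd]] == "*") { syn_sites[cd] <- NA_real_; next }
    s <- 0
    ch <- strsplit(cd, "")[[1]]
    for (pos in 1:3) for (b in setdiff(bases, ch[pos])) {
      mut <- ch; mut[pos] <- b
      mutc <- paste(mut, collapse = "")
      if (code[[mutc]] == code[[cd]]) s <- s + 1 / 3
    }
    syn_sites[cd] <- s
  }

  # pairwise expected synonymous / nonsynonymous differences, averaged over
  # all minimal mutational pathways; pathways passing through a stop codon
  # are discarded (unless every pathway is blocked)
  path_counts <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    dpos <- which(ca != cb)
    d <- length(dpos)
    if (d == 0) return(c(0, 0))
    perms <- if (d == 1) list(dpos) else
      if (d == 2) list(dpos, rev(dpos)) else
        lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2),
                    c(3,2,1)), function(o) dpos[o])
    score_path <- function(ord, allow_stops) {
      cur <- ca; sd <- 0; nd <- 0
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- cb[pos]
        a1 <- code[[paste(cur, collapse = "")]]
        a2 <- code[[paste(nxt, collapse = "")]]
        if (!allow_stops && (a1 == "*" || a2 == "*")) return(NULL)
        if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    res <- Filter(Negate(is.null), lapply(perms, score_path,
                                          allow_stops = FALSE))
    if (!length(res))
      res <- lapply(perms, score_path, allow_stops = TRUE)
    Reduce(`+`, res) / length(res)
  }

  sense <- codons[aa != "*"]
  nsc <- length(sense)
  sd_mat <- matrix(0, nsc, nsc, dimnames = list(sense, sense))
  nd_mat <- sd_mat
  for (i in seq_len(nsc)) for (j in seq_len(nsc)) {
    if (i == j) next
    pc <- path_counts(sense[i], sense[j])
    sd_mat[i, j] <- pc[1]; nd_mat[i, j] <- pc[2]
  }
  .ng86_cache$tab <- list(syn_sites = syn_sites, sd = sd_mat, nd = nd_mat,
                          sense = sense, code = code)
  .ng86_cache$tab
}

# internal: split an in-frame CDS into codons, dropping one trailing stop
split_codons <- function(s, label) {
  s <- toupper(s)
  if (nchar(s) %% 3 != 0) stopf("%s length is not a multiple of 3", label)
  if (grepl("[^ACGT]", s)) stopf("non-ACGT character in %s", label)
  cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  code <- Biostrings::GENETIC_CODE
  is_stop <- code[cods] == "*"
  if (any(is_stop)) {
    if (sum(is_stop) == 1 && which(is_stop) == length(cods))
      cods <- cods[-length(cods)]
    else stopf("internal stop codon in %s", label)
  }
  cods
}

#' NG86 synonymous divergence between two aligned coding sequences
#'
#' Nei-Gojobori (1986) counting: per-codon synonymous site fractions from
#' the universal genetic code, observed differences averaged over all
#' minimal mutational pathways for multi-hit codons, and a Jukes-Cantor
#' correction `Ks = -(3/4) * log(1 - (4/3) * ps)` for multiple
#' substitutions per site. Site counts are averaged over the two
#' sequences. A trailing stop codon (present in both) is dropped.
#'
#' @param cds_a,cds_b Aligned in-frame coding sequences of equal length.
#' @param id_a,id_b Optional identifiers carried into the result.
#' @return List of class `KsPair`: `S`, `N` (site counts), `sd`, `nd`
#'   (difference counts), `ps`, `pn`, `Ks`, `Ka` (`Inf` when the
#'   proportion reaches the correction's domain edge, 3/4).
#' @export
ng86_ks <- function(cds_a, cds_b, id_a = "a", id_b = "b") {
  if (nchar(cds_a) != nchar(cds_b)) stopf("sequences differ in length")
  ca <- split_codons(cds_a, id_a)
  cb <- split_codons(cds_b, id_b)
  if (length(ca) != length(cb))
    stopf("sequences differ in length after stop trimming")
  tab <- ng86_tables()
  Sa <- sum(tab$syn_sites[ca]); Sb <- sum(tab$syn_sites[cb])
  S <- (Sa + Sb) / 2
  N <- 3 * length(ca) - S
  idx_a <- match(ca, tab$sense); idx_b <- match(cb, tab$sense)
  sd <- sum(tab$sd[cbind(idx_a, idx_b)])
  nd <- sum(tab$nd[cbind(idx_a, idx_b)])
  ps <- sd / S
  pn <- nd / N
  jc <- function(p) if (p >= 3 / 4) Inf else -(3 / 4) * log(1 - (4 / 3) * p)
  structure(list(id_a = id_a, id_b = id_b, S = S, N = N, sd = sd, nd = nd,
                 ps = ps, pn = pn, Ks = jc(ps), Ka = jc(pn)),
            class = "KsPair")
}

#' @export
print.KsPair <- function(x, ...) {
  cat(sprintf("KsPair %s / %s: S = %.1f, N = %.1f, sd = %.2f, nd = %.2f, Ks = %.4f\n",
              x$id_a, x$id_b, x$S, x$N, x$sd, x$nd, x$Ks))
  invisible(x)
}

#' Ks histogram and recent-duplication window fractions
#'
#' Bins finite Ks values of paralog pairs (the "Ks plot" used to detect
#' waves of gene duplication and ancient WGD) and reports the fraction of
#' pairs falling inside configurable Ks windows (endpoints inclusive).
#' Infinite/saturated pairs are excluded and counted separately.
#'
#' @param ks_values Numeric Ks values (may contain `Inf`), or a list of
#'   `KsPair` objects.
#' @param bin_width Histogram bin width (default 0.01).
#' @param windows List of `c(lo, hi)` Ks windows; defaults to the
#'   recent-duplication windows `(0, 0.04)` and `(0.00002, 0.09)`.
#' @return List: `breaks`, `counts`, `n_finite`, `n_infinite`,
#'   `window_fractions` (named by "lo-hi").
#' @export
ks_histogram <- function(ks_values, bin_width = 0.01,
                         windows = list(c(0, 0.04), c(0.00002, 0.09))) {
  if (is.list(ks_values) && length(ks_values) &&
      inherits(ks_values[[1]], "KsPair"))
    ks_values <- vapply(ks_values, function(p) p$Ks, numeric(1))
  finite <- ks_values[is.finite(ks_values)]
  n_inf <- sum(!is.finite(ks_values))
  if (!length(finite)) stopf("no finite Ks values")
  breaks <- seq(0, max(finite) + bin_width, by = bin_width)
  counts <- as.vector(table(cut(finite, breaks = breaks,
                                include.lowest = TRUE, right = FALSE)))
  wf <- vapply(windows, function(w)
    mean(finite >= w[1] & finite <= w[2]), numeric(1))
  names(wf) <- vapply(windows, function(w)
    sprintf("%g-%g", w[1], w[2]), character(1))
  list(breaks = breaks, counts = counts, n_finite = length(finite),
       n_infinite = n_inf, window_fractions = wf)
}
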