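#' Hypergeometric term enrichment
#'
#' Flat (no ontology graph) enrichment of annotation terms in a study set
#' against a population, the computation behind over-representation of,
#' e.g., ion-transport terms among low-CpG_o/e genes. For each term with at
#' least one study hit the upper-tail hypergeometric probability
#' `P(X >= k | N, K, n)` is computed exactly by log-factorial summation,
#' then corrected across terms (Benjamini-Hochberg by default).
#'
#' @param study_genes Character vector, the study set (must be a subset of
#'   the population).
#' @param population_genes Character vector, the background.
#' @param term_map data.frame with columns `gene_id` and `term` (one row
#'   per gene-term assignment).
#' @param adjust Multiple-testing method, `"BH"` (default) or
#'   `"bonferroni"`.
#' @return data.frame sorted by p: `term, k, n, K, N, p_value, q_value`.
#' @export
enrich_terms <- function(study_genes, population_genes, term_map,
                         adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  study_genes <- unique(study_genes)
  population_genes <- unique(population_genes)
  stray <- setdiff(study_genes, population_genes)
  if (length(stray))
    stopf("study gene(s) not in population: %s",
          paste(utils::head(stray, 10), collapse = ", "))
  term_map <- term_map[term_map$gene_id %in% population_genes, , drop = FALSE]
  N <- length(population_genes)
  n <- length(study_genes)
  terms <- split(term_map$gene_id, term_map$term)
  rows <- lapply(names(terms), function(tm) {
    members <- unique(terms[[tm]])
    K <- length(members)
    k <- length(intersect(members, study_genes))
    if (k == 0) return(NULL)
    data.frame(term = tm, k = k, n = n, K = K, N = N,
               p_value = hypergeom_upper_p(k, N, K, n),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      q_value = numeric()))
  res$q_value <- stats::p.adjust(res$p_value, method = adjust)
  res[order(res$p_value, res$term), , drop = FALSE]
}

#' Exact upper-tail hypergeometric probability
#'
#' `P(X >= k)` for X hypergeometric with population `N`, `K` marked, draw
#' size `n`, by direct summation of exactly computed terms on the log
#' scale.
#'
#' @param k Observed hits in the study set.
#' @param N Population size.
#' @param K Marked genes in the population.
#' @param n Study-set size.
#' @return Probability in [0, 1].
#' @export
hypergeom_upper_p <- function(k, N, K, n) {
  stopifnot(k >= 0, K <= N, n <= N, k <= min(n, K))
  i <- k:min(n, K)
  lg <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(1, sum(exp(lg)))
}

#' Share of results matching a pattern set
#'
#' Reports what fraction of a term list (e.g., significantly enriched
#' terms) matches a set of identifiers or keyword tags — the computation
#' behind statements like "61 of 209 enriched terms relate to ion
#' transport".
#'
#' @param terms Character vector of term identifiers/descriptions.
#' @param pattern_set Character vector of exact identifiers, or (with
#'   `fixed = FALSE`) regular expressions matched against each term.
#' @param fixed If `TRUE` (default) membership is exact; else regex match.
#' @return List: `matching`, `total`, `percentage` (one decimal, rounded
#'   half away from zero).
#' @export
share_matching <- function(terms, pattern_set, fixed = TRUE) {
  total <- length(terms)
  if (total == 0) stopf("empty term list")
  hit <- if (fixed) {
    terms %in% pattern_set
  } else {
    Reduce(`|`, lapply(pattern_set, function(p) grepl(p, terms)))
  }
  matching <- sum(hit)
  list(matching = matching, total = total,
       percentage = percent_of(matching, total))
}
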