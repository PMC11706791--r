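#' Run the full genome-architecture analysis pipeline
#'
#' Orchestrates the stages in dependency order: load (or simulate) the
#' genome, per-gene CpG_o/e and tail sets, optional term enrichment of the
#' low tail, spatial clustering tests of a labeled subset, the read-depth
#' duplication screen, and the Ks plot. Optional stages whose inputs are
#' missing are skipped with a warning; the report is fully determined by
#' inputs, config and seed.
#'
#' @param config List with entries (all optional unless noted):
#' \describe{
#'   \item{fasta, gff3, labels, centromeres}{input paths (required unless
#'     `spec` is given)}
#'   \item{spec}{a [synthetic_genome_spec()]; simulated in place of files}
#'   \item{stages}{character subset of `c("cpg", "enrichment",
#'     "clustering", "depth", "ks")`; default all}
#'   \item{subset_label}{gene subset for the clustering stage
#'     (default `"ion_transport"`)}
#'   \item{reference_label}{`NULL` (default) uses the highest-CpG_o/e genes,
#'     matched in count, as the functionally conserved reference}
#'   \item{term_map}{data.frame gene_id/term for enrichment}
#'   \item{depth_table}{data.frame gene_id/depth or TSV path}
#'   \item{paralog_pairs}{data.frame as from [gen_paralogs()]}
#'   \item{null_mode, centromere_window, tail_q, cpg_threshold, seed}{
#'     stage parameters}
#' }
#' @param outdir Optional directory for per-stage TSV/JSON outputs.
#' @return List of class `RunReport`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stages <- config$stages
  if (is.null(stages))
    stages <- c("cpg", "enrichment", "clustering", "depth", "ks")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  report <- list(params = list(stages = stages, seed = seed),
                 stages = list())

  bundle <- NULL
  if (!is.null(config$spec)) {
    bundle <- gen_genome(config$spec)$bundle
  } else if (length(stages)) {
    if (is.null(config$fasta) || is.null(config$gff3))
      stopf("config must name 'fasta' and 'gff3' inputs (or a 'spec')")
    bundle <- load_genome(config$fasta, config$gff3, config$labels,
                          config$centromeres)
  }

  records <- NULL
  if ("cpg" %in% stages) {
    records <- cpg_table(bundle)
    threshold <- if (is.null(config$cpg_threshold)) 1.0 else
      config$cpg_threshold
    smry <- suppressWarnings(summarize_cpg(records, threshold))
    tail_q <- if (is.null(config$tail_q)) 0.05 else config$tail_q
    tails <- cpg_tail_sets(records, tail_q)
    report$stages$cpg <- list(summary = smry, tail_size = tails$size)
    report$params$tail_q <- tail_q
    if (!is.null(outdir))
      utils::write.table(records, file.path(outdir, "cpg_records.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  } else tails <- NULL

  if ("enrichment" %in% stages) {
    if (is.null(config$term_map) || is.null(tails)) {
      warning("enrichment stage skipped: no term_map (or no cpg stage)")
    } else {
      enr <- enrich_terms(tails$low, records$gene_id, config$term_map)
      alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
      report$stages$enrichment <-
        list(n_terms_tested = nrow(enr),
             n_significant = sum(enr$q_value < alpha),
             top_terms = utils::head(enr$term, 5))
      if (!is.null(outdir))
        utils::write.table(enr, file.path(outdir, "enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("clustering" %in% stages) {
    subset_label <- if (is.null(config$subset_label)) "ion_transport" else
      config$subset_label
    null_mode <- if (is.null(config$null_mode)) "montecarlo" else
      config$null_mode
    sset <- gene_spacings(bundle, subset_label)
    kst <- ks_clustering_test(sset, null_mode = null_mode, seed = seed)
    counts <- per_chromosome_counts(bundle, subset_label)
    # reference = highest-CpG_o/e genes matched in count (functionally
    # conserved housekeeping-like set), unless a reference label is given
    chisq <- NULL
    if (!is.null(config$reference_label)) {
      ref_set <- gene_spacings(bundle, config$reference_label)
      chisq <- try(chisq_vs_reference(sset, ref_set), silent = TRUE)
    } else if (!is.null(records)) {
      n_sub <- sum(counts)
      def <- records[records$defined, , drop = FALSE]
      top_ids <- def$gene_id[order(-def$cpg_oe,
                                   def$gene_id)][seq_len(min(n_sub,
                                                             nrow(def)))]
      g <- bundle$genes[bundle$genes$gene_id %in% top_ids, , drop = FALSE]
      ref_set <- spacing_set(split(g$midpoint, g$chrom))
      chisq <- try(chisq_vs_reference(sset, ref_set), silent = TRUE)
    }
    if (inherits(chisq, "try-error")) chisq <- NULL
    window <- if (is.null(config$centromere_window)) 1e6 else
      config$centromere_window
    prox <- centromere_proximity(bundle, subset_label, window)
    report$stages$clustering <-
      list(subset = subset_label, ks = unclass(kst),
           chisq = if (!is.null(chisq))
             unclass(chisq)[c("chi2", "df", "p_value")],
           per_chromosome = as.list(counts),
           centromere_proximal = as.list(prox),
           centromere_window = window)
  }

  if ("depth" %in% stages) {
    dt <- config$depth_table
    if (is.character(dt) && length(dt) == 1 && file.exists(dt))
      dt <- utils::read.table(dt, sep = "\t", header = FALSE,
                              col.names = c("gene_id", "depth"))
    if (is.null(dt)) {
      warning("depth stage skipped: no depth_table")
    } else {
      scr <- depth_outliers(dt)
      report$stages$depth <- list(n_genes = nrow(scr),
                                  n_outlier_high = sum(scr$outlier_high),
                                  pct_outlier_high =
                                    percent_of(sum(scr$outlier_high),
                                               nrow(scr)))
      if (!is.null(outdir))
        utils::write.table(scr, file.path(outdir, "depth_outliers.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("ks" %in% stages) {
    pp <- config$paralog_pairs
    if (is.null(pp)) {
      warning("ks stage skipped: no paralog_pairs")
    } else {
      ks_vals <- vapply(seq_len(nrow(pp)), function(i)
        ng86_ks(pp$seq_a[i], pp$seq_b[i], pp$id_a[i], pp$id_b[i])$Ks,
        numeric(1))
      h <- ks_histogram(ks_vals)
      report$stages$ks <- list(n_pairs = length(ks_vals),
                               mean_ks = mean(ks_vals[is.finite(ks_vals)]),
                               n_infinite = h$n_infinite,
                               window_fractions = as.list(h$window_fractions))
    }
  }

  class(report) <- "RunReport"
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(outdir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' Validate the structure of a run report
#'
#' Checks a `RunReport` (or its JSON-roundtripped list form) against the
#' schema shipped in `inst/schema/run_report_schema.json`: required
#' top-level fields, stage names, and required per-stage fields.
#'
#' @param report A `RunReport` or a list parsed from its JSON.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_run_report <- function(report) {
  schema <- jsonlite::read_json(system.file("schema",
                                            "run_report_schema.json",
                                            package = "copearch"))
  for (f in unlist(schema$required))
    if (is.null(report[[f]])) stopf("report missing required field '%s'", f)
  allowed <- unlist(schema$stage_names)
  extra <- setdiff(names(report$stages), allowed)
  if (length(extra))
    stopf("unknown stage(s) in report: %s", paste(extra, collapse = ", "))
  for (st in names(report$stages)) {
    req <- unlist(schema$stage_required[[st]])
    miss <- setdiff(req, names(report$stages[[st]]))
    if (length(miss))
      stopf("stage '%s' missing field(s): %s", st,
            paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}
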