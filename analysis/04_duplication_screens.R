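#!/usr/bin/env Rscript
# Stage 4: gene-duplication screens.
#
# (a) IQR outlier screen on per-gene read depth, scored against the truth
#     from the generator; (b) NG86 Ks plot of the paralog pairs with the
#     recent-duplication window fractions.

suppressPackageStartupMessages(library(copearch))

depths <- read.table("results/simulated/depths.tsv", sep = "\t",
                     col.names = c("gene_id", "depth"))
truth <- jsonlite::read_json("results/simulated/depths.tsv.truth.json",
                             simplifyVector = TRUE)

scr <- depth_outliers(depths)
flagged <- scr$gene_id[scr$outlier_high]
sens <- mean(truth$duplicated %in% flagged)
fdr <- if (length(flagged)) mean(!flagged %in% truth$duplicated) else 0
message(sprintf("depth screen: %d/%d flagged (%.1f%%); sensitivity %.2f, FDR %.2f",
                length(flagged), nrow(scr),
                100 * length(flagged) / nrow(scr), sens, fdr))
write.table(scr, "results/depth_outliers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

pfa <- Biostrings::readDNAStringSet("results/simulated/paralogs.fa")
ids <- names(pfa)
a <- grep("_a$", ids)
ks_vals <- vapply(a, function(i)
  ng86_ks(as.character(pfa[[i]]), as.character(pfa[[i + 1]]))$Ks,
  numeric(1))
h <- ks_histogram(ks_vals)
message(sprintf("Ks plot: %d pairs, mean Ks %.4f, %d saturated",
                h$n_finite, mean(ks_vals[is.finite(ks_vals)]),
                h$n_infinite))
for (w in names(h$window_fractions))
  message(sprintf("  fraction in Ks window %s: %.3f", w,
                  h$window_fractions[w]))

jsonlite::write_json(list(n_flagged = length(flagged),
                          sensitivity = sens, fdr = fdr,
                          mean_ks = mean(ks_vals[is.finite(ks_vals)]),
                          window_fractions = as.list(h$window_fractions)),
                     "results/duplication.json", auto_unbox = TRUE,
                     digits = NA)
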