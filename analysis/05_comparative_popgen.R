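#!/usr/bin/env Rscript
# Stage 5: order-level comparative statistics and the small calculators.
#
# Kruskal-Wallis and pairwise Wilcoxon tests on chromosome number and
# genome size across copepod orders (on the package's synthetic trait
# table -- the published supplementary data are not redistributed here),
# a Pearson correlation of genome size vs repeat proportion, and the
# effective-population-size calculation from Watterson's theta.

suppressPackageStartupMessages(library(copearch))

traits <- read.table(system.file("extdata", "synthetic_copepod_traits.tsv",
                                 package = "copearch"),
                     header = TRUE, sep = "\t")

for (metric in c("chromosome_2n", "genome_size_mb")) {
  tab <- data.frame(group = traits$order, value = traits[[metric]])
  kw <- kruskal_wallis(tab)
  message(sprintf("%s: H = %.2f, DF = %d, P = %.3g", metric, kw$H, kw$df,
                  kw$p_value))
  med <- group_medians(tab)
  message("  medians: ",
          paste(sprintf("%s=%.0f", names(med), med), collapse = ", "))
  pw <- pairwise_wilcoxon(tab)
  write.table(round(pw, 4), sprintf("results/pairwise_wilcoxon_%s.tsv",
                                    metric),
              sep = "\t", quote = FALSE)
}

# genome size vs repeat content, four synthetic genome-scale points
four <- data.frame(genome_mb = c(529, 580, 950, 350),
                   repeat_pct = c(46.1, 52.0, 61.5, 35.0))
r <- pearson_r(four$genome_mb, four$repeat_pct)
message(sprintf("genome size vs repeat proportion: Pearson r = %.3f", r))

ne <- effective_pop_size(theta_w = 0.0131, mu = 3.46e-9)
message(sprintf("Ne = theta/(4 mu) = %.0f (~%.0g)", ne$ne, ne$ne_magnitude))

jsonlite::write_json(list(pearson_r = r, ne = ne),
                     "results/comparative.json", auto_unbox = TRUE,
                     digits = NA)
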