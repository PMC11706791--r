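#!/usr/bin/env Rscript
# Stage 6: k-mer based genome-size estimation.
#
# Counts canonical 21-mers in the simulated reads (30x over a 250-kb
# genome segment; see stage 1) and estimates the segment size from the
# coverage peak.

suppressPackageStartupMessages(library(copearch))

h <- count_kmers("results/simulated/reads.fq", k = 21)
est <- estimate_genome_size(h)

G <- 250000
message(sprintf("k-mer instances: %.3g; coverage peak at %.2f (cutoff %d)",
                h$total_kmers, est$peak, est$error_cutoff))
message(sprintf("estimated size %.0f bp vs true %.0f bp (%.2f%% error)",
                est$est_size, G, 100 * abs(est$est_size - G) / G))

jsonlite::write_json(list(k = h$k, est_size = est$est_size,
                          true_size = G, peak = est$peak,
                          error_cutoff = est$error_cutoff),
                     "results/kmer_size.json", auto_unbox = TRUE,
                     digits = NA)
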