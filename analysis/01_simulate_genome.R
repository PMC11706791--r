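#!/usr/bin/env Rscript
# Stage 1: simulate the study inputs.
#
# Builds a four-chromosome synthetic genome with CpG-depleted coding
# sequence (target CpG_o/e = 0.5, GC = 33%), labeled ion-transport and
# housekeeping subsets, per-gene read depths with a duplicated high tail,
# paralog pairs at Ks = 0.05, and 30x error-free reads. Everything later
# stages consume lives under results/simulated/.

suppressPackageStartupMessages(library(copearch))

outdir <- "results/simulated"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

spec <- synthetic_genome_spec(rng_seed = 20260921)
g <- gen_genome(spec, dir = outdir)
message(sprintf("genome: %d chromosomes x %.1f Mb, %d genes",
                spec$n_chromosomes, spec$chrom_length / 1e6,
                nrow(g$bundle$genes)))

dep <- gen_depths(spec, gene_ids = g$bundle$genes$gene_id,
                  path = file.path(outdir, "depths.tsv"))
message(sprintf("depths: %d genes, %d truly duplicated",
                nrow(dep$depths), length(dep$duplicated)))

par <- gen_paralogs(spec, fasta_path = file.path(outdir, "paralogs.fa"))
message(sprintf("paralogs: %d pairs of %d codons at target Ks %.2f",
                spec$n_pairs, spec$codons, spec$target_ks))

# reads for the k-mer stage: a 250-kb segment of Chr1 keeps the exact
# (in-memory) k-mer counter at desk scale (~7.5e6 k-mer instances at 30x)
seg <- substr(as.character(g$bundle$sequences[["Chr1"]]), 1, 250000)
gen_reads(c(Chr1_segment = seg), coverage = spec$coverage,
          read_length = spec$read_length, error_rate = spec$error_rate,
          seed = spec$rng_seed,
          fastq_path = file.path(outdir, "reads.fq"))
message("reads written: ", file.path(outdir, "reads.fq"))
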