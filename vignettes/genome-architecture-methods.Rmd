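---
title: "Methods: genome-architecture statistics for a calanoid copepod genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-architecture statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copearch)
```

# Scope

`copearch` implements the statistical layer of a genome-architecture study
of the calanoid copepod *Eurytemora carolleeae* (Atlantic clade of the
*E. affinis* species complex): an AT-rich (GC ≈ 33%), ~529-Mb genome on
four chromosomes in which ion-transport gene families are expanded,
carry strong signatures of historical gene-body methylation, and sit in
chromosomal clusters. The package provides five analyses over a common
gene-table representation, plus a synthetic-genome generator that supplies
statistically controlled inputs so that every analysis can be calibrated
and tested without the deposited data:

1. per-gene CpG~o/e~ and its genome-wide distribution (methylation signature);
2. chromosomal clustering tests for labeled gene sets (KS and chi-square);
3. gene-duplication screens (read-depth IQR outliers; NG86 Ks plot);
4. order-level comparative statistics and small population-genetic calculators;
5. k-mer histogram genome-size estimation.

Assembly, gene prediction, repeat annotation, orthology and phylogenetics
are out of scope; the package consumes their standard outputs
(FASTA, GFF3, TSV label/term/depth tables, FASTA/FASTQ reads).

# The CpG~o/e~ statistic

DNA methylation in animals is concentrated at CpG dinucleotides.
Methylated cytosines deaminate to thymine at an elevated rate, so lineages
with sustained gene-body methylation progressively lose CpG sites from
transcribed sequence. The per-gene statistic is

$$\mathrm{CpG_{o/e}} = \frac{f_{CpG}}{f_C\, f_G},\qquad
  f_C = \frac{n_C}{L},\; f_G = \frac{n_G}{L},\;
  f_{CpG} = \frac{n_{CpG}}{L-1},$$

computed on the representative coding sequence of each gene (the longest
transcript's CDS, spliced and strand-corrected). Values near 1 indicate no
depletion; values near 0.5, as in this copepod, indicate strong historical
methylation.

Numerical conventions, fixed and configurable where the choice is not
forced:

* **Denominators.** Mononucleotide frequencies use $L$, the dinucleotide
  frequency uses $L-1$ (the number of overlapping windows). An
  all-over-$L$ variant is available (`dinuc_denominator = "L"`); for
  $L = 1500$ the two differ by < 0.1%.
* **Ambiguity characters.** Positions that are not A/C/G/T are excluded
  from numerator and denominators, with lengths adjusted. Coding sequence
  extracted from a genome must be pure ACGT; `N` is legal only in
  intergenic sequence.
* **Undefined ratios.** A sequence with no C or no G has an undefined
  ratio; such records are flagged and excluded from summaries (not
  zero-filled), with a warning.
* **Tail sets.** The low/high 5% sets have size $\lfloor q\,n\rfloor$
  over the defined records; ties in CpG~o/e~ break by lexicographic gene
  id so the sets are reproducible.
* **Modality.** The "unimodal distribution" claim is reported
  descriptively as the number of local maxima of a Gaussian kernel
  density estimate with the default bandwidth rule; no formal dip test is
  performed.
* **Percentages** are reported to one decimal, rounding halves away from
  zero — the convention needed so that 53/80 prints as 66.3%.

# Term enrichment

Enrichment of annotation terms in a study set (e.g. the 5% lowest-CpG~o/e~
genes) against a population uses the exact upper-tail hypergeometric
probability $P(X \ge k)$, computed by log-factorial summation, with
Benjamini–Hochberg correction across terms (Bonferroni available). Terms
are opaque identifiers: there is no ontology-graph propagation, matching
the flat enrichment style of common annotation tools. Only enrichment
(upper tail) is tested; the significance threshold is exposed as
`alpha` with default 0.05.

# Clustering of gene sets along chromosomes

The unit of analysis is the **adjacent-gene spacing**: differences between
midpoints of consecutive subset genes along a chromosome, pooled across
chromosomes. Gene position is the integer midpoint of the gene span —
strand-symmetric and robust to annotation differences at gene ends.
Flank-to-telomere distances are excluded; tied midpoints produce zero
spacings that are kept. Pooling across chromosomes (rather than testing
per chromosome) is the package's documented choice.

`ks_clustering_test()` offers three null modes:

* **`uniform-spacing`** (literal): one-sample KS of the pooled spacings
  against Uniform(0, max spacing). This is the reading that reproduces
  very large D values on strongly clustered sets, but it is *not* a
  calibrated test of placement: even uniformly placed genes have
  right-skewed (approximately exponential) spacings, so this mode rejects
  its null for essentially any large gene set. The analysis scripts
  demonstrate this on uniform placements. It is provided for
  comparability, not inference.
* **`position-uniform`**: one-sample KS of midpoint/chromosome-length
  against Uniform(0,1); a calibrated test of *positions*, but insensitive
  to small-scale aggregation.
* **`montecarlo`** (default in the pipeline): the observed spacings are
  compared against spacings pooled from 1000 uniform placements with
  matched per-chromosome gene counts; the p-value is Monte-Carlo — the
  observed two-sample D is ranked among the Ds of 199 fresh null
  placements against the same pool, so the test is exactly calibrated by
  exchangeability. Null placements are drawn via the Dirichlet
  representation of uniform order-statistic gaps (normalized i.i.d.
  exponentials), which needs no sorting.

One-sample p-values use the asymptotic Kolmogorov series with the standard
finite-$n$ correction $\lambda = (\sqrt n + 0.12 + 0.11/\sqrt n)D$. The KS
statistic itself is computed as the exact supremum over ECDF step points
and is verified against a brute-force enumeration in the tests.

The **chi-square comparison** against a functionally conserved reference
set (the highest-CpG~o/e~ genes, matched in count, standing in for
housekeeping genes) bins the observed spacings at reference-spacing
quantiles, so each bin has equal expected mass $n/\text{bins}$. The
default bin count is $\max(6, \lfloor n/30\rfloor)$, which yields 16 bins
(df = 15) for a 490-gene set and 6 bins (df = 5) for an 80-gene set —
the degrees of freedom reported for the motivating data. Bins with
expected counts below 5 are refused with advice to use fewer bins.

**Centromere proximity** counts subset genes within a window (default
1 Mb in the pipeline) of user-supplied centromere positions; chromosomes
without a known centromere report `NA`, never zero.

# Duplication screens

**Read depth.** Genes whose mean read depth exceeds $Q_3 + k\,\mathrm{IQR}$
(quartiles by linear interpolation, type 7; $k = 1.5$ by default) are
flagged as putative duplicated/collapsed loci. Low-side deviations are
flagged separately but are not "outliers" in the duplication sense. The
depth unit (reads overlapping vs mean per-base coverage) is accepted as
given; a per-base BED coverage aggregator (`depth_from_bed()`) converts
interval coverage to per-gene means when needed. The flags are invariant
under uniform rescaling of all depths.

**Synonymous divergence.** Paralog age is estimated with Nei–Gojobori
(1986) counting: per-codon synonymous site fractions from the universal
code (mutations to stop codons count as nonsynonymous, so $S + N$ equals
the sequence length in sites), observed differences averaged over all
minimal mutational pathways for multi-hit codons (pathways through stop
codons are discarded unless all are blocked), and a Jukes–Cantor
correction $K_s = -\tfrac34\ln(1 - \tfrac43 p_s)$. This is a deliberate,
documented method choice: maximum-likelihood codon models (F3×4) give
nearly identical values in the low-divergence regime
($K_s \lesssim 0.1$), which is exactly the regime of recent-duplication
claims; saturated pairs ($p_s \ge 3/4$) are flagged infinite and excluded
from histograms with a separate count. The Ks-plot windows default to the
recent-duplication intervals (0–0.04 and 2×10⁻⁵–0.09), endpoints
inclusive.

# Comparative statistics and calculators

Order-level trait comparisons use the tie-corrected Kruskal–Wallis test
(chi-square approximation, adequate at the group sizes involved) and
pairwise two-sided rank-sum tests. The motivating study labels its
pairwise tests "Wilcoxon signed rank", but the order groups are unpaired
species sets, so the rank-sum (Mann–Whitney) reading is used — exact
p-values for small tie-free samples, tie- and continuity-corrected normal
approximation otherwise, BH-adjusted across pairs. Group medians average
the central pair for even counts. Trait values (haploid vs diploid
chromosome counts, genome sizes in Mb) are taken as tabulated.

The effective-population-size calculator applies the neutral identity
$N_e = \theta_W / (4\mu)$; with $\theta_W = 0.0131$ and
$\mu = 3.46\times10^{-9}$ it returns 946,532, reported alongside its
one-significant-figure and nearest-power-of-ten roundings (9×10⁵ and
10⁶).

# k-mer genome-size estimation

Reads are decomposed into canonical k-mers (lexicographic minimum of the
word and its reverse complement; `k` must be odd to avoid self-reverse-
complementary words), encoded as base-4 integers — exact in doubles for
`k ≤ 26` — and counted exactly in memory. This is a deliberately plain
counter for desk-scale inputs (≤ ~10⁷ k-mer instances); cluster-scale
data belong in dedicated counters, whose histograms can be fed directly
into the estimator.

The estimator separates the error tail from the coverage peak at the
first local minimum of the 3-point moving average of the histogram, finds
the modal multiplicity above that cutoff, refines it by 3-point parabolic
interpolation **plus half a bin** — the vertex of a Poisson($\lambda$)
coverage histogram sits near $\lambda - \tfrac12$, while the denominator
of the size estimate wants the mean coverage $\lambda$ — and returns

$$\widehat G = \frac{\sum_{m \ge \text{cutoff}} m\,c(m)}{\text{peak}}.$$

With error-free 30× reads of a 100-kb genome the estimate is within ~2%,
and it shifts by well under 1% when coverage doubles. A histogram with no
local minimum/maximum structure (insufficient coverage separation) is an
error, with advice to increase coverage. The full GenomeScope-style
mixture model (heterozygosity, repeat fraction) is intentionally not
reimplemented.

# The synthetic-genome generator

The generator emulates the statistical structure the analyses assume, at
toy scale, with a truth JSON sufficient to score any recovery test.
Default conditions (a `synthetic_genome_spec()`): 4 chromosomes × 5 Mb,
125 genes per chromosome, 1500-nt single-segment CDS, GC = 33%, target
CpG~o/e~ 0.5 (the genome-wide mean of the motivating genome), uniform
placement, 16% `ion_transport` and 16% `housekeeping` labels (80 genes
each at the default scale, the size of the key ion-transport set),
centromeres at chromosome midpoints.

* **CpG-depleted coding sequence.** A first-order Markov chain whose
  stationary base composition is exactly the requested GC and whose
  C→G transition is scaled to $w\,\pi_G$, with the G column of the other
  rows compensated so stationarity is preserved *exactly*. Consequently
  the expected CpG~o/e~ of emitted sequence equals $w$, and the
  generator–estimator loop closes to within ±0.05 at 500 genes × 1500 nt
  — a clean parameter-recovery test. The biological motivation is
  deamination-driven CpG loss; the chain is a statistical emulation, not
  a mutational model.
* **Placement.** Uniform midpoints, or `n_clusters` uniform centres with
  Normal(centre, `cluster_sd_bp`) genes truncated to the chromosome;
  spans are made non-overlapping by resampling colliding genes (gene
  density above 90% of the chromosome is refused). Gene lengths are fixed
  per spec to keep feasibility checks simple.
* **Depths.** Negative binomial with mean 9000 (the depth scale reported
  for the motivating annotation) and size 400, i.e. CV ≈ 5% — near-
  uniform short-read coverage over single-copy genes of an inbred
  genome. A `duplicated_fraction` (5%) of genes is multiplied by
  `duplication_multiplier` (10×). Under these conditions the IQR screen
  recovers the duplicated set with sensitivity ≥ 0.9 and FDR ≤ 0.1.
  Real depth tables are far more dispersed (gene-family effects,
  mappability); the screen itself is distribution-free, but the
  sensitivity/FDR figures quoted here are properties of these conditions,
  not guarantees on real data.
* **Paralogs.** Each pair descends from a random sense-codon ancestor; a
  Poisson($K_s^{target}\times S$) number of synonymous single-nucleotide
  changes (drawn from the synonymous neighbourhoods of the current
  codons) is distributed over the two copies. Because every change is
  synonymous and NG86 counts it as one synonymous difference, the mean
  estimated Ks recovers the target (±0.01 at 200 pairs × 300 codons);
  multi-hit codons are handled by the pathway averaging in the estimator.
* **Reads.** Uniform start positions, both strands, fixed length,
  optional uniform substitution errors, Phred "I" qualities.

All randomness flows from `rng_seed`; sub-streams (depths, paralogs) use
fixed offsets, so every output is bit-reproducible.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: introns and multi-exon structure (optional
only), repeats and mappability artefacts, GC heterogeneity along
chromosomes, ontology-structured term maps, indels and quality-dependent
sequencing error, linkage between label, expression and position. The
calibration and power results for the clustering test are exact for the
placement models simulated; real gene sets violate uniformity in ways
beyond simple clustering (telomere/centromere composition biases), which
is why the Monte-Carlo null matches per-chromosome counts rather than a
single genome-wide intensity.

# Problem sizes and reproducibility

The test suite and the acceptance script size their simulations for
desk-scale runs: 500 replicates for the KS size study, 200 for power,
500 genes × 1500 nt for CpG closure, 200 pairs × 300 codons for Ks
recovery, 2000 genes for the depth screen, and a 100-kb genome at 30×
for the k-mer stage. The analysis drivers under `analysis/` run the same
pipeline at the default 500-gene genome scale and write their tables
under `results/`.

# Known limitations

* The literal `uniform-spacing` KS mode is reported for comparability
  with very large published D values but is anti-conservative by
  construction; inference should use the Monte-Carlo mode.
* NG86 + Jukes–Cantor underestimates Ks relative to ML codon models as
  divergence grows; conclusions should be restricted to the low-Ks
  regime.
* The k-mer counter is exact and in-memory; it is not a tool for
  cluster-scale read sets.
* The hypergeometric engine treats terms independently; genes annotated
  to many correlated terms inflate the number of tests, which BH handles
  only in the independent/PRDS sense.
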