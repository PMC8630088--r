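---
title: "Models and methods behind epigain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epigain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epigain)
```

# Scope

`epigain` analyses spontaneous epiallele formation — the ectopic gain of
non-CG DNA methylation at genes — in *Arabidopsis thaliana* methylomes,
with a focus on epigenetic recombinant inbred lines (epiRILs) derived from
a cross between wild type and a hypomethylated *ddm1* parent. The package
covers six analysis layers (per-cytosine calling and methylation levels,
gene-state classification, haplotype reconstruction, ectopic-gain calling,
methylation-QTL interval mapping, Hi-C contact enrichment) plus a
synthetic-data generator that emits every input with known ground truth.
Read processing, region-level HMM segmentation, Hi-C matrix construction
and contact-significance modelling, and ChIP-seq peak calling are
deliberately out of scope: the package consumes their outputs (per-cytosine
count tables, BED intervals, significant-contact BEDPE).

# Per-cytosine methylation calling

Bisulfite sequencing leaves a fraction of unmethylated cytosines
unconverted; that fraction is estimated from the chloroplast genome, which
is fully unmethylated, as total methylated reads over total reads on the
control contig (`estimate_nonconversion()`). Each cytosine with at least
`min_cov = 3` reads is then tested with a one-sided binomial test,
$p = P(X \ge m \mid n, \; p_{nc})$ for $m$ methylated of $n$ total reads at
non-conversion rate $p_{nc}$. The p-values are Benjamini–Hochberg adjusted
across all tested sites and a site is called methylated at $q < 0.05$.
Whether the original analyses applied an FDR correction at the site level
is not documented; we adopt it for explicit false-positive control and
expose `fdr` as a knob. The package-level test suite checks that on a fully
unmethylated contig the methylated-call fraction stays below the nominal
FDR.

Weighted methylation levels are always computed as
$\sum m_i / \sum n_i$ over the covered cytosines of a region — never as a
mean of per-site ratios — so deeply covered sites carry proportionally more
weight. An interval without covered sites has a *missing* level, which is
distinct from zero everywhere downstream.

Sequence contexts are derived from the trinucleotide on the cytosine's
strand: CG when the second base is G, CHG when the third base is G, CHH
otherwise. CWA (W = A/T), the CMT2-preferred subcontext, is implemented as
the filter `tri_context %in% c("CAA", "CTA")` within CHH, and
"non-CWA CHH" as its complement.

# Gene methylation-state classification

Genes are classified from the CDS of their primary transcript. Per context
$c$, the genome-wide background rate $p_{0,c}$ is the fraction of called
CDS sites that are methylated (each site counted once even under
overlapping annotations). Per gene, with $n_c$ called sites and $k_c$
methylated calls, the binomial upper tail $P(X \ge k_c \mid n_c, p_{0,c})$
is BH-adjusted per context across all genes. The rules, each requiring at
least 20 covered sites in the deciding context:

* **teM (mCHH)** — $q_{CHH} < 0.05$ (CG and CHG unconstrained, as both
  accompany mCHH);
* **teM (mCHG)** — $q_{CHG} < 0.05$ and $q_{CHH} \ge 0.05$ (CG
  unconstrained, as mCG commonly accompanies mCHG);
* **gbM** — $q_{CG} < 0.05$ with both non-CG contexts non-significant;
* **UM** — all three contexts non-significant, at least 20 covered CHH
  sites, and at most 2 symmetric methylated CG dyads (both strands of a CG
  pair called methylated) — the extra filter that removes genes with
  residual CG methylation from the unmethylated set;
* anything else is **unclassified**.

Two choices were genuinely open. The "higher number of methylated
cytosines" tail is implemented inclusively as $P(X \ge k)$, which is the
standard convention and conservative at $k = 0$. When several rules fire
simultaneously the precedence is teM-mCHH > teM-mCHG > gbM > UM,
mirroring the observation that significant mCG does not disqualify a
teM gene; the coverage floor for UM is read as 20 *covered* CHH sites.
The q-value universe is per context across genes, matching the
per-context thresholds in the rules.

# Haplotype reconstruction and the hypomethylation index

EpiRILs segregate methylation states, not sequence variants, so
ultra-stable differentially methylated regions (DMRs) act as physical
markers. A marker's state in a line is its weighted methylation level over
all contexts pooled (the DMRs separate methylated from unmethylated
regions; a CG-only level is available via the `context` argument),
thresholded at 0.5: below 0.5 the line carries the unmethylated *ddm1*
allele (U = 1), otherwise the methylated wild-type allele (M = 0). The
hypomethylation index $h$ is the mean of these indicators over non-missing
markers — a proxy for the fraction of the genome inherited from the
hypomethylated parent.

Parent-of-origin segments are drawn between markers: concordant
neighbouring markers extend their parent across the gap, discordant ones
break at the midpoint between their interval edges, and spans beyond the
terminal markers or adjacent to an uncalled marker stay unknown. Genes are
assigned the parent of the segment containing their midpoint — cheap,
deterministic, and adequate because genes spanning a breakpoint are rare
at realistic marker densities.

met1-derived chromosome segments are located by walking each chromosome
left to right, packing the exons of gbM genes into consecutive bins of
exactly 10 exons (a final short bin merges into its predecessor — one
reading of "continuous bins with at least 10 exons"; the original
bin-advance rule is not documented) and flagging bins whose exonic mCG is
reduced by more than 25% relative to the control parent; adjacent flagged
bins merge into maximal intervals.

# Ectopic gain calling and its correlates

A gene gains ectopic methylation in context CHG, CWA or non-CWA CHH when,
over the cytosines of its full span (introns included — browser-level gains
are gene-wide) covered by at least 3 reads in both the line and the
control parent, the mean per-site level difference is at least +0.10 with
at least 3 such sites. The "average 10% higher" could also be read as a
difference of weighted levels; the per-site mean is used because it
weights sites equally regardless of depth, and the site floor guards the
small-sample regime either way.

Per line, the gain matrix also yields the three QTL phenotypes: the count
of gaining genes, the mean genic level, and the genome-wide weighted level
in the gain context. Enrichment of gains by gene class uses a one-sided
Fisher exact test (odds ratio > 1) over the analysed gene universe, and a
per-gene Pearson correlation between the line-wise level change and $h$
(within a parental stratum) is flagged at $|r| > 0.35$; undefined
correlations (fewer than 3 lines, zero variance) are never flagged.

# Methylation-QTL interval mapping

The linkage map is built from the binary marker genotypes: markers whose
one-sided Fisher association with an already-accepted marker on another
chromosome is significant at $10^{-4}$ are rejected (cross-chromosome
correlation cannot reflect genuine linkage; the greedy in-order rule keeps
the first copy of a duplicated marker), and map distances come from
adjacent-marker recombination fractions with the selfed-RIL correction
$r = R / (2(1-R))$ and the Haldane function $d = -50 \ln(1 - 2r)$.
Adjacent fractions are capped at 0.49 before conversion so distances stay
finite.

Scanning uses Haley–Knott regression of the phenotype on the conditional
probability of the *ddm1* allele, evaluated on a 1-cM grid augmented with
the marker positions. Conditional probabilities interpolate the nearest
informative flanking markers through the selfed-RIL transition function
and are normalised over the two genotype paths, so a typed marker returns
its observed state and the midpoint between discordant flanks returns
exactly 0.5. The LOD is $(n/2)\log_{10}(RSS_0/RSS_1)$, capped at 50 when
the residual sum of squares vanishes. Haley–Knott was preferred over an
EM mixture because the phenotypes are continuous with near-normal
residuals in simulation and the difference is negligible at these effect
sizes.

Significance uses a genome-wide permutation threshold (the $1-\alpha$
quantile of the maximum LOD over phenotype permutations, seeded and
deterministic), with the fixed LOD-3 convention available as an option.
Peaks are local maxima above the threshold separated by a 1.5-LOD valley,
with 1.5-LOD support intervals; a peak within 1 Mb of its gene on the same
chromosome is cis, otherwise trans (the original cis window is not
documented; 1 Mb is configurable), and the compartment label comes from
membership in a user-supplied heterochromatin BED — pericentromere
coordinates are an input, not a computation.

# Contact analysis

From a precomputed significant-contact list (2-kb bins in the data the
package emulates), a contact links a gene to an H3K9me2 region when one
anchor overlaps a peak by at least 1 bp and the other overlaps the gene;
multi-peak anchors still count once per contact per gene. Distances are
nearest-edge gaps between the gene and any contacted peak on the same
chromosome (the original distance metric is not documented; edge-to-edge
is the most conservative choice), and inter-chromosomal contacts
contribute to counts but not distances. Class enrichment mirrors the gain
enrichment; group comparisons use two-sided Wilcoxon rank-sum tests with
no multiplicity adjustment, exact for tie-free comparisons with
$\min(n_1, n_2) \le 8$ and normal-approximated with tie correction
otherwise. The contact-significance model itself (Fit-Hi-C) is not
re-implemented: the defined computation starts from its output.

# The synthetic experiment

`simulate_epiril_experiment()` generates a desk-scale caricature of the
study design with full ground truth. Its defaults are the package's fixed
study conditions:

* **Genome** — five 2-Mb chromosomes, a central pericentromeric
  heterochromatin block covering 20% of each, 600 genes (250 gbM, 100 teM,
  250 UM) placed without overlap on the euchromatic arms with log-normal
  lengths (median ~2 kb, matching the *A. thaliana* average; gbM genes
  drawn ~1.4× longer, echoing their observed length bias).
* **Methylation rates** — wild-type per-context rates gbM 0.8/0.02/0.02,
  teM 0.9/0.7/0.15, UM 0.005 everywhere, heterochromatic intergenic
  0.9/0.7/0.2 (CG/CHG/CHH). These are simulation knobs chosen to make
  class recovery non-trivial but achievable at 20× depth, not empirical
  claims. The *ddm1* parent attenuates heterochromatic (marker and
  intergenic) rates by ×0.1; genic rates are left untouched, as *ddm1*
  hypomethylation is overwhelmingly heterochromatic.
* **Markers** — 100 intergenic DMR intervals of 500 bp, quasi-evenly
  spaced. Marker cytosines are CG/CHG-dominated (2:1), reflecting the
  methylated-region character of ultra-stable DMRs; this keeps the
  expected wild-type marker level (~0.83) well clear of the 0.5 threshold
  at 20× depth.
* **Population** — 150 lines; per chromosome, crossovers are Poisson with
  mean 2 along the realized inbred mosaic and the leftmost parent is fair,
  giving 50/50 expected parental contribution.
* **Reads** — per site, `total ~ Poisson(depth = 20)` and
  `mc ~ Binomial(total, rate(1 - nc) + (1 - rate) nc)` with non-conversion
  `nc = 0.005`; a fully unmethylated chloroplast-like contig is always
  emitted.
* **Gains** — per line, a gbM gene gains with probability
  `plogis(-2.5 + 2.5 h + 2 g_QTL)` where `g_QTL` is the line's allele at a
  designated pericentromeric marker (a logistic form keeps probabilities
  bounded; the emulated association is monotone, not of a stated
  functional form). UM genes gain at 2% of that probability. A gain raises
  the gene's CHG and CWA site rates by +0.25.
* **Contacts** — H3K9me2 peaks are the 2-kb bins tiling heterochromatin;
  each gene draws `Poisson(1 × 2^flag)` significant contacts to random
  peaks.

What the generator does *not* emulate: real sequence content (cytosines
are placed, not read from a genome), read-level errors beyond
non-conversion, partial methylation polymorphism within a line, marker
imputation, and the long-range dependence structure of real Hi-C maps.
Passing the recovery tests therefore demonstrates that the pipeline's
logic and statistics behave as specified under the assumed generative
model — not that the thresholds are optimal for any particular real
dataset.

# Numerical and degenerate-input conventions

* Coordinates are 1-based closed internally (`GenomicRanges`); BED/BEDPE
  0-based half-open is converted only at the I/O boundary.
* Body-window remainders go to the last window; genes shorter than 20 bp
  yield all-missing body windows with a warning.
* A weighted level over zero covered sites is missing, never 0; marker
  states with missing levels are `NA` and excluded from $h$.
* Fisher odds ratios are `Inf` when `bc = 0`; an all-zero table is an
  error.
* The LOD cap is 50; monomorphic grid positions score 0; constant
  phenotypes give a zero curve with a warning.
* Permutation thresholds are deterministic given their seed;
  `alpha = 1` degenerates to the minimum permuted maximum.

# Problem sizes used by the test suite

The shipped tests run the generator at its default scale (600 genes,
150 lines, 20×) for the recovery checks, with 50 replicates at 200
permutations for QTL power and 20 replicates for contact power; oracle
equivalences (binomial tail, Fisher, rank-sum, BH) are exhaustive at small
sizes and sampled up to margins of 30. These sizes were chosen so the
whole suite exercises every claim in minutes on a laptop.

# Known limitations

* The marker-state threshold is hard (0.5); heterozygous-like intermediate
  levels caused by a crossover inside a marker interval are called to one
  side, which the simulation shows happens for roughly 1 marker in 10,000
  line-marker calls at the default spacing.
* Map construction assumes markers are pre-assigned to chromosomes by
  physical position; it orders but does not re-group them.
* `find_met1_derived_regions` uses greedy fixed-count exon bins; other
  readings of "at least 10 exons per bin" would shift bin boundaries by at
  most one bin.
* The gain caller compares each line to a single shared control; replicate
  controls, if available, must be pooled upstream.
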