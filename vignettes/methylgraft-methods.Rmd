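---
title: "Models and methods behind methylgraft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methylgraft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylgraft)
```

methylgraft analyses whole-genome bisulfite sequencing (WGBS) methylomes
in a control-versus-treatment design, as arises for instance when
profiling the haemocyte methylome of a pearl oyster before and at time
points after allotransplantation. This vignette is the package's own
account of its models: the quantities it computes, the assumptions they
rest on, the tunables that matter, what the synthetic-data generator does
and does not emulate, and the design choices that were genuinely open.

## Methylation levels

The unit record is a per-cytosine call: chromosome, 1-based position,
strand, sequence context and the counts of reads supporting methylation
($N_m$) and non-methylation ($N_{nm}$). Context is the two bases 3' of
the cytosine *on its own strand*: CG if the next base is G, CHG if the
base after next is G, CHH otherwise (H = A, C or T). On the minus strand
the downstream bases are the reverse complement of the plus-strand bases
to the left of the site, which is why `classify_context()` is checked
against a literal double-strand scan in the tests.

The methylation level of any region is the *weighted* level

$$R_m = \frac{N_m^{all}}{N_m^{all} + N_{nm}^{all}},$$

i.e. reads are pooled across sites before the ratio is taken. This makes
the level exactly additive: re-pooling the counts of any partition of an
interval reproduces the whole-interval value, a property the test suite
asserts on a thousand random partitions. A mean of per-site fractions
would not have this property and would over-weight shallow sites.

Two conventions matter downstream. Each stranded cytosine is its own
site — complementary CG pairs are *not* collapsed into one symmetric CpG,
because the level is defined per reference cytosine. And intervals are
0-based half-open internally (matching BED), while call positions are
1-based (matching the per-cytosine table convention); conversion happens
only at the interval boundary.

A site counts as "methylated" for composition summaries
(`context_proportions()`) when it has at least one methylated read at
coverage of at least 4. No binomial test is applied; the rule is
deliberately simple and pluggable via `site_rule`.

## Gene-feature profiles

`partition_genes()` decomposes each transcript into upstream 2 kb, first
exon, first intron, internal exons/introns, last exon and downstream
2 kb, in transcription order, plus two derived spans: the promoter
(identical to upstream 2 kb — the analysis needs a promoter definition
and the upstream flank is the natural one; the length is configurable)
and the gene body (TSS to transcript end). Single-exon genes contribute
only a first exon so the exon classes stay disjoint. `feature_profile()`
pools counts over *all* intervals carrying a label genome-wide —
weighted pooling again, not a mean of per-gene means — and
`normalize_track()` converts one feature's trajectory across time points
into fractions of its total, which is how multi-time-point profiles are
made comparable across features with very different absolute levels.

`kmer_preference()` tabulates the pooled level of every observed 7-mer
with the cytosine at position 4 (three bases of flank either side, read
on the site's strand). Sites whose flanks leave the contig or contain N
are excluded and tallied, so the per-7-mer site counts plus exclusions
always partition the input. "Methylation percentage" per 7-mer is the
weighted level by default; the fraction-of-sites-methylated reading is
available via `measure = "site_fraction"`, since either interpretation
is defensible.

The per-site comparison score between two groups is the degree of
difference $\log_2(R_{m1}) / \log_2(R_{m2})$, with an exact zero in
either argument replaced by 0.001 before the logs. The formula is
implemented literally as this ratio of logs. Its one degenerate input,
$R_{m2} = 1$ (denominator zero), yields a flagged infinite score rather
than an error.

## DMR calling

Differentially methylated regions are found by a windowed two-group
scan. The genome is tiled into non-overlapping windows (1 kb by default;
the width is a free parameter of the method, and a half-window sliding
mode exists but is off by default because non-overlapping tiles keep
neighbour merging well defined). Per window and context, counts are
pooled per group and the window is a putative DMR when all of the
following hold:

* at least 5 covered cytosines of that context *in each group* (the
  site filter is applied per group, the stricter of the two readings);
* fold change $\max(R_{m1}, R_{m2}) / \max(\min(R_{m1}, R_{m2}),
  \text{floor}) \ge 2$, the floor (default 0.05) acting as a
  pseudo-level that keeps the ratio defined;
* two-sided Fisher exact $P < 0.05$ on the pooled
  $2 \times 2$ read-count table (groups × methylated/unmethylated);
* neither group hypomethylated: both levels at or above the floor. This
  is the literal reading of the rule; `hypo_rule = "either"` gives the
  laxer alternative.

The Fisher P is the point-probability two-sided sum with a relative
tolerance of $10^{-7}$ on the "no more probable than observed"
comparison; it is validated against exhaustive enumeration of all
135,751 tables with total count up to 40 at $10^{-10}$. No
multiple-testing correction is applied, mirroring the raw threshold of
the windowed procedure; a BH-adjusted column is available in the
enrichment output where it is conventional.

Neighbouring passing windows are then *iteratively merged*: two
neighbours (same chromosome, context and direction, gap at most
`max_gap` = one window by default, nothing called between them) are
interdependent when the whole span from the start of the upstream one to
the end of the downstream one — with counts re-pooled from the raw calls,
gap sites included — itself passes the fold, P and floor tests. Merging
is strictly left-to-right, restarts after every merge, and stops at a
fixed point, so final DMR sets are pairwise non-mergeable and the
operation is idempotent (both asserted on random scenarios). Merging
opposite-direction neighbours is refused: a hyper- and a hypomethylated
region are not one continuous event. Direction is the sign of
$R_{m2} - R_{m1}$.

A gene is a gene-body DMG when at least one DMR overlaps its TSS-to-end
span by one base or more, and a promoter DMG for overlap with the 2 kb
upstream of the TSS; a DMR spanning the TSS makes the gene both.
Enrichment of a DMG set against gene–term annotations is the
hypergeometric upper tail $P(X \ge k)$ over a universe that defaults to
all annotated genes (the background is configurable because the right
universe is study-specific); gene-body and promoter sets are tested
separately.

## BSP clone analysis

Bisulfite-sequencing-PCR clones are compared to their reference amplicon
by global pairwise alignment with bisulfite-aware scoring: a clone T
aligned to a reference C is scored as a match (+1), since it is the
expected conversion product, with mismatch −1 and a linear gap penalty of
−2 per base — end-to-end alignment is appropriate because BSP amplicons
are short and primer-delimited. The asymmetry matters: a clone C against
a reference T is still a mismatch. Only the top (primer-defined) strand
is modelled; the reverse complement of a clone is tried automatically
when the direct orientation aligns below 50% bisulfite-aware identity,
and clones under 80% identity in both orientations are rejected outright.

At each reference CpG cytosine the aligned clone base gives the call
(C methylated, T unmethylated, gap or other missing). The conversion
rate is estimated from the non-CpG reference cytosine columns — these
should essentially all read T — and a clone passes QC at 95% or better.
The QC is on by default but the threshold is a parameter, since some
studies keep all clones. The clone × CpG matrix, its per-position
methylated fractions and the text/ggplot lollipop renderings all derive
from QC-passing clones only, with rows ordered by clone id for
determinism.

## The synthetic methylome generator

The generator exists so that every downstream stage can be validated
against known ground truth without any sequencing download. Its defaults
describe the study conditions the package is tested under:

* 2 chromosomes × 500 kb at GC 0.35 (an AT-rich invertebrate genome),
  40 four-exon genes, 20 CpG islands, 25 repeat segments;
* mosaic CG methylation: 0.7 in gene bodies and repeats, 0.3 in
  intergenic background, 0.05 in promoters and CpG islands — so
  promoters and islands are the hypomethylated compartments and gene
  bodies/repeats the methylated ones, the pattern expected of a mollusc
  methylome;
* non-CG methylation at background level: CHG $8 \times 10^{-4}$, CHH
  $6 \times 10^{-4}$. These values are deliberately far below the CG
  levels. Invertebrate non-CG methylation is essentially absent, and
  with Poisson 30× coverage and the one-methylated-read site rule, the
  probability that a site shows a spurious methylated read grows roughly
  as $30 p$ — CHH sites outnumber CG sites about four to one in an
  AT-rich genome, so even $p = 0.01$ would flood the methylated-site
  pool with CHH calls and push the mCG share far below anything
  observed in WGBS of molluscs. At the defaults the simulated
  composition lands at roughly 92% mCG / 1.8% mCHG / 6.2% mCHH,
  inside the observed bands for this kind of methylome;
* 30× mean Poisson coverage (not fixed coverage, so the ≥5-site and
  coverage filters are genuinely exercised by dropped and shallow
  sites), with methylated read counts Binomial(coverage, level);
* 20 planted CG DMRs of 1 kb, control level 0.3 versus treatment 0.7.
  Planted DMRs start at multiples of their own width, i.e. aligned to
  the default analysis grid. This is intentional: a 1 kb region
  straddling two 1 kb tiles contributes at most a diluted signal to
  each, and for about half of random placements *neither* tile can reach
  the twofold filter even with perfect data — a phase artefact of every
  tile-based caller, not a property of the statistics the benchmark is
  meant to measure. Grid-aligned planting measures the caller; users
  can pass arbitrary `planted_dmrs` (including misaligned ones) to
  study the phase effect itself.

Every draw derives from the single config seed through fixed offsets,
so genomes are byte-identical across runs and each group's counts come
from an independent, reproducible stream. A multi-group time course with
global de- and re-methylation can be emulated through `group_effects`
multipliers on the CG baselines.

What the generator does **not** emulate: read-level artefacts (mapping
bias, incomplete bisulfite conversion in the WGBS calls, strand
coverage asymmetry), linkage between neighbouring sites (each site
draws independently), sequence-driven methylation preference (the 7-mer
table on simulated data is flat up to noise), or realistic gene/repeat
architecture. Passing the planted-DMR benchmark therefore shows that
the windowing, testing and merging machinery is correct under the
stated noise model — it does not certify performance on real
methylomes, where coverage and level heterogeneity are richer.

## Numerical choices and degenerate inputs

* Zero-coverage regions carry an `NA` level and are excluded from
  eligibility rather than treated as zero.
* The Fisher comparison tolerance ($10^{-7}$, relative) guards against
  float noise when two tables have near-equal probabilities; the
  enumeration sweep bounds the resulting error below $10^{-10}$.
* An all-zero trajectory normalizes to all zeros with an `all_zero`
  flag instead of dividing by zero.
* Degree-of-difference with a level of exactly 1 in the denominator is
  flagged infinite, not raised.
* Merging ties are impossible by construction: candidates are examined
  strictly left to right and the pass restarts after every merge.
* BED/bedGraph output is written sorted by (chromosome, start) so all
  artefacts are byte-deterministic.

## Problem sizes used in validation

The shipped validation uses the generator defaults (1 Mb genome, two
groups, ≈350k cytosine calls per group), three independent seeds for
the stochastic checks (context composition, null calibration), 100–1000
replicates for the property checks, the full enumeration sweep for the
Fisher test, and 200 random amplicons plus a 500-clone experiment for
BSP. These sizes keep a complete run in a few minutes while leaving the
statistical assertions comfortably powered.

## Known limitations

* The windowed scan has no smoothing across windows; a DMR weaker than
  the twofold/`alpha` filters in every individual window is only
  recoverable through merging if at least two windows pass on their own.
* The promoter is a fixed-length flank; no TSS-annotation-quality
  adjustment is attempted.
* The enrichment model treats genes as exchangeable (no gene-length or
  coverage bias correction).
* BSP alignment assumes clones of roughly amplicon length; severely
  truncated clones fail the identity gate rather than being locally
  aligned.
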