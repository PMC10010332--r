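---
title: "Methods: interlesion tumor and immune heterogeneity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interlesion tumor and immune heterogeneity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionscope)
```

This vignette documents the models and procedures the package implements,
the parameters that matter, the numerical conventions adopted where a choice
had to be made, and what the synthetic-data generators do and do not
emulate.

## Somatic variant filtering

A candidate somatic call carries strand-resolved tumor read counts
(`tumor_alt_fwd/rev`, `tumor_ref_fwd/rev`), germline counts (`normal_alt`,
`normal_total`) and a population-database membership flag. A call is
excluded when **any** enabled criterion fires:

| criterion | rule | default |
|---|---|---|
| `total_reads` | tumor total reads < `min_total_reads` | 20 |
| `low_vaf` | tumor VAF < `min_vaf` | 0.05 |
| `germline_support` | `normal_alt` > `max_germline_alt_reads` | 2 (absent in mouse preset) |
| `single_strand` | alternate reads on one strand only | on |
| `population_db` | database membership flag set | human only |

Conventions worth stating explicitly:

* All inequalities are strict as printed: exactly 20 reads, VAF exactly
  0.05, or exactly 2 germline mutant reads are **retained**.
* The strand criterion looks at the alternate-supporting reads only — the
  mutation being present on one strand — not at total strand coverage. A
  call with zero alternate reads on both strands also fails it (the
  mutation is not on both strands), alongside the VAF criterion.
* Every criterion is evaluated for every call (no short-circuiting), so the
  per-criterion tallies are independent of evaluation order and sum to a
  recount of the recorded failure labels.
* Population-database membership is consumed as a precomputed boolean
  column; the package does not query external variant databases, which
  keeps filtering self-contained and testable.
* Multi-allelic rows must be pre-split; the reader rejects them.

Whether upstream callers' outputs were unioned or intersected before
filtering is an upstream decision; the filter processes whatever candidate
set it is given.

## Copy-number log-R ratio

The LRR pipeline has four steps.

1. **Site selection.** SNP sites are kept when the matched normal's VAF
   indicates a clean genotype: homozygous at VAF ≤ 0.05 or ≥ 0.95,
   heterozygous at 0.4–0.6 (both bands inclusive). Intermediate VAFs are
   excluded as mapping artefacts or contamination.
2. **GC adjustment.** Within each sample independently, sites are binned by
   local GC fraction (1 % bins) and each depth is scaled by
   (global median depth) / (bin median depth). Median scaling was chosen
   over a loess fit for robustness to copy-number outliers and for exact
   reproducibility; a GC-unbiased track is left unchanged up to bin
   granularity. The GC fraction is computed over a 101-bp window centred on
   the site (50 bp flanking each side); the width is configurable.
3. **Per-site LRR.** `LRR_i = log2((t_i/T)/(n_i/N))`, where `t_i`, `n_i`
   are the adjusted tumor and normal depths and `T`, `N` their sums over
   evaluated sites. Sum normalisation makes the track invariant to
   rescaling either library; the normaliser can be switched to the median.
   Sites with zero adjusted depth in either sample are dropped and counted,
   never propagated as infinities.
4. **Windowed representative LRR.** The median over a closed 1-Mb window
   centred at each site, computed per chromosome (windows never span
   chromosomes) and reported only where at least `min_sites = 10` sites
   fall in the window — single-site medians are noise. The median of an
   even count is the mean of the two central values.

Tumor purity and ploidy are deliberately not modelled; expected LRR
magnitudes in the tests assume purity 1, so a heterozygous deletion sits
near `log2(0.5/M)` where `M` is the genome-wide mean relative tumor depth
(slightly below 1 when a deletion occupies part of the genome — the
library-size renormalisation shifts the baseline). Segmentation,
purity/ploidy inference and allele-specific copy number are out of scope.

## Neoantigen enumeration and overlap

For a nonsynonymous substitution at protein position `p` in a protein of
length `L`, every 9-mer window of the mutated sequence covering `p` is a
candidate: starts `max(1, p − 8)` through `min(p, L − 8)` — nine windows at
interior positions, one at a terminus. Binding is consumed from a
NetMHCpan-style table (peptide, allele, %Rank); strong binders are those
with %Rank ≤ 0.5. The threshold is **inclusive** (the Methods convention
for strong binders) and configurable, since one also sees the strict form
"< 0.5" in informal use. Duplicate (peptide, allele) pairs keep the minimal
rank.

For interlesion comparisons a neoantigen is identified by its
(peptide, MHC allele) pair rather than by its source mutation, because
distinct mutations can yield identical peptides; counts deduplicated by
source mutation are emitted alongside. Peptides missing from the binding
table are excluded from counts and listed in a coverage report. A
deterministic hash-based stub binding table ships for end-to-end testing;
its pseudo-ranks carry no biology. Only single-residue substitutions are
supported — frameshift- and fusion-derived peptides are out of scope, as is
any binding model of our own.

## Single-cell TCR clonotypes

**QC.** Cells with mitochondrial content above 10 % or with fewer than 200
or more than 4,000 detected genes are removed (dying cells, empty droplets,
doublets). The exclusions are strict, so boundary cells are retained.

**Resolution.** Clonotype identity is the TRB (V gene, J gene, CDR3
nucleotide) triple: cells without a β contig are dropped while α-less cells
are kept, so β defines identity and the best-supported α is annotation.
Within a cell, UMIs are pooled over identical triples; when a runner-up
candidate has **more than half** the top candidate's UMIs the cell is
ambiguous. Exactly half is retained; an exact tie at the top rank is
ambiguous (the conservative extension of the more-than-half rule).
Candidate order is made deterministic by breaking UMI ties
lexicographically.

**Evenness.** Pielou's `J = H′/ln S` with natural-log Shannon entropy over
clones with positive counts; `S ≥ 2` is required since `ln S = 0`
otherwise.

**Dominance.** The published grouping into lesion-dominant and equivalent
clonotypes states no numeric rule, so it is parameterised here: clonotype
frequencies are compared between lesions and a clonotype is A-dominant when
`freq_A ≥ ratio_threshold × freq_B` (default ratio 2), symmetric for B;
clonotypes seen in only one lesion are dominant there when they have at
least `min_cells = 2` cells; clonotypes below `min_cells` everywhere are
excluded. The rule is antisymmetric under lesion swap. The threshold is a
reported parameter, not a recovered ground truth.

**Exhaustion and enrichment.** A clonotype is flagged exhausted when more
than half its cells (configurable) sit in the exhausted-CD8 cluster. The
2×2 table of dominant class × exhausted flag (equivalent clonotypes
excluded) is tested with an exact two-sided Fisher test: conditioning on
margins, the p-value sums hypergeometric probabilities of all tables no
more probable than the observed one, computed in log space with a relative
tie tolerance of 1e-7. On the printed two-lesion table (9 exhausted of 33
dominant in one lesion vs 4 of 50 in the other) this gives an odds ratio of
4.3125 and p = 0.029; note an exact two-sided test on those counts does not
reach 0.01, so significance statements at that level would have to come
from an asymptotic test.

**Cluster annotation.** Manual marker-based annotation is replaced by an
explicit, testable surrogate: a gene is "high" in a cluster when its mean
expression exceeds the across-cluster median; a cluster gets the first rule
label whose required markers are all high and excluded markers all low
(e.g. CD8A + PDCD1 + HAVCR2 → exhausted CD8; CD4 + FOXP3 → Treg; CD4 +
GZMA without CD8A → cytotoxic CD4). More specific rules precede generic
activation rules. Clustering itself (normalisation, integration, PCA/UMAP)
is consumed, not computed.

## Mixed-response classification and survival

Per-lesion percent change from baseline is evaluated at every scan within
the first 183 days (six months, inclusive). The per-lesion
regression/progression thresholds are not printed anywhere, so the
RECIST-style −30 % / +20 % pair is adopted per lesion and exposed as
configuration. A new lesion is progression regardless of size. A lesion
that regresses and later progresses within the window counts toward both
flags (responses are dynamic), and is categorised progressing.

Patient groups follow the three-group taxonomy: **nonmixed responder** (all
lesions regressing, no new lesions), **mixed responder** (at least one
regressing lesion together with a progressing or new lesion), **nonmixed
nonresponder** (progression without regression anywhere). Patients whose
evaluable lesions are all stable — or regressing in part with the rest
stable — fall outside the printed taxonomy; they are labelled
`stable_unclassified` and excluded from group comparisons rather than
forced into a bin.

The simplified RECIST surrogate works on total burden (sum of measured
lesion diameters): CR at zero burden, PR at ≤ −30 % from baseline, PD at
≥ +20 % from the nadir or a new lesion, SD otherwise; node-size rules,
target-lesion selection and confirmation scans are not modelled. Printed
percentages use half-up rounding to one decimal (70/503 → 13.9 %,
13/70 → 18.6 %), since banker's rounding would change some printed values.

Survival uses the product-limit estimator (median = earliest time S(t) ≤
0.5) and the k-group log-rank test with hypergeometric covariance,
`(O − E)' V⁻¹ (O − E)` over k−1 groups on k−1 degrees of freedom. Both are
cross-checked against the survival package in the test suite but
implemented independently. Cox modelling is out of scope.

## Synthetic-data generators

All generators are deterministic given `sim_config(seed = ...)` and emit a
truth table the tests consume — no test reads ground truth from generated
observables.

* `sim_lesion_pair_mutations()`: trunk mutations shared by both lesions,
  private mutations in one (defaults 50/25/15, a trunk-heavy architecture
  typical of adjacent metastases), read counts at ~100× with
  Binomial(0.5) strand split, and 5 planted decoys per exclusion criterion
  per lesion, each violating its target criterion by construction.
* `sim_depth_tracks()`: 6,000 sites over two chromosomes, Beta-distributed
  GC centred near 0.45, a multiplicative GC depth effect
  (`1 + 0.8·(gc − 0.5)` by default) shared by tumor and normal, Poisson
  depths at 100×, tumor scaled by copy_number/2 inside planted segments
  (purity 1), and normal VAFs drawn from a homozygous/heterozygous/
  intermediate mixture so site selection is exercised.
* `sim_clonotype_tables()`: truncated power-law clone frequencies
  (exponent 1.2 — a skewed repertoire; 0 gives uniform), planted
  interlesion dominance (default frequency multiplier 4, safely beyond the
  2× classification threshold; `dominance_ratio = 1` disables planting),
  exhausted-cluster membership with a planted odds ratio (default 4)
  between dominant classes, and planted 5 % rates of ambiguous, β-less and
  QC-failing cells.
* `sim_cohort()`: 503 patients across four cancer types by default, planted
  group labels (multinomial, or exact counts via `exact_group_counts` for
  worked-arithmetic checks), per-lesion trajectory templates whose margins
  exceed the classification thresholds (regressions of 40–70 %,
  progressions of 30–80 %, optional new lesions), exponential survival
  with group-specific means ordered responder > mixed > nonresponder and
  independent exponential censoring.

What the generators do **not** emulate: sequencing error and mapping
artefacts beyond the planted decoys, subclonal copy-number mixtures or
impure tumors, repertoire overlap structure beyond the planted
dominance/exhaustion pattern, correlated lesion trajectories, or
non-exponential survival. Passing the recovery tests therefore shows the
algorithms implement their stated rules — not that the rules themselves are
optimal on real, noisier data.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at sizes chosen to make
sampling error negligible relative to the tolerances being asserted: 6,000
SNP sites for LRR tracks (≥ 5,000 windowed sites after selection), 1,000
random calls for the filter oracle, 503-patient cohorts, repertoires of 150
clonotypes × 1,500 cells per lesion, and exhaustive Fisher enumeration over
all 2×2 tables with total ≤ 40; stochastic recovery properties use 25–40 seeded replicates. Key conventions: even-count medians average
the central pair; Fisher ties use a 1e-7 relative tolerance; log-rank
degenerate inputs (identical groups) return a statistic of exactly 0;
evenness is scale-invariant by construction and `J = 1` only for uniform
vectors.

## Known limitations

* The LRR formula's normalisation (sum vs median) is a convention; both are
  offered, and absolute LRR levels depend on it when large aberrations
  occupy much of the genome.
* The dominance rule and the exhausted-clonotype flag are parameterised
  surrogates for published groupings whose exact rules are not stated.
* The response classifier's per-lesion thresholds are RECIST-inspired
  defaults, not recovered values; sensitivity to them should be assessed on
  real cohorts.
* Single-residue substitutions only; no binding prediction, no clustering,
  no segmentation, no Cox models — those stages are consumed from, or left
  to, the established external tools.
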