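# lesionscope

Tools for analysing **interlesion heterogeneity** in cancer patients treated
with PD-1 blockade: why two metastatic lesions of the same patient can carry
different tumor subclones, different neoantigen repertoires and different
tumor-infiltrating T-cell clones — and why patients whose lesions respond
discordantly ("mixed responders") do worse than uniform responders.

The package implements, as tested reusable functions on plain data frames:

* **Somatic variant consensus filtering** — candidate tumor/normal calls are
  excluded when any criterion fires: total reads < 20, tumor VAF < 0.05,
  germline mutant reads > 2, mutant support on a single strand, or presence
  in a population database of normal genomes (human preset; the mouse
  cell-line preset drops the germline and database criteria). All failing
  criteria are recorded per call, with per-criterion tallies.
* **Tumor/normal log-R-ratio (LRR) copy number** — SNP sites that are
  homozygous (normal VAF ≤ 0.05 or ≥ 0.95) or heterozygous (0.4–0.6) in the
  matched normal are selected; depths are GC-adjusted by median scaling in
  1 % GC bins; the per-site signal is
  `LRR_i = log2( (t_i / T) / (n_i / N) )` with `t_i`, `n_i` the adjusted
  tumor and normal depths and `T`, `N` their totals; the representative LRR
  is the median over a 1-Mb moving window centred at each site.
* **Neoantigen candidates and interlesion overlap** — every 9-mer window of
  a mutated protein covering the substituted residue is enumerated,
  MHC-I binding tables are filtered at the strong-binder threshold
  (%Rank ≤ 0.5), and mutations/neoantigens are partitioned into
  lesion-private and shared sets (Venn counts by peptide–allele pair and by
  source mutation).
* **Single-cell TCR clonotypes** — cell QC (mitochondrial fraction ≤ 10 %,
  200–4,000 detected genes), β-chain-defined clonotype resolution (cells
  without a TCRβ contig are dropped; a runner-up clonotype with more than
  half the top clonotype's UMIs marks the cell ambiguous), Pielou evenness
  `J = H′ / ln S`, interlesion dominance classification by frequency ratio,
  and exhausted-clonotype enrichment via an exact two-sided Fisher test
  (log-space hypergeometric).
* **Mixed-response classification and survival** — per-lesion percent change
  from baseline over the first six months (183 days) classifies patients as
  nonmixed responders (all lesions regressing), mixed responders
  (simultaneous regression and progression, or regression plus a new
  lesion), or nonmixed nonresponders; PFS/OS are compared with an in-house
  Kaplan–Meier estimator and k-group log-rank test.
* **Seeded synthetic-data generators** for every input above, each emitting
  a ground-truth table for parameter-recovery tests.

## Worked example

```r
library(lesionscope)

# Paired-lesion mutations with planted filter-violating decoys
sim <- sim_lesion_pair_mutations(sim_config(seed = 42))
report <- apply_somatic_filters(sim$lesion_a, filter_criteria("human"))
print(report)
#> Somatic filter report (human preset)
#>   retained: 75  rejected: 25
#>   failures per criterion:
#>     total_reads       5
#>     low_vaf           5
#>     germline_support  5
#>     single_strand     5
#>     population_db     5

rb <- apply_somatic_filters(sim$lesion_b, filter_criteria("human"))
venn_partition(report$retained$pos, rb$retained$pos)
#> Venn partition: only A = 25 | shared = 50 | only B = 15
```

The 25 rejected calls are exactly the planted decoys (5 per criterion); the
Venn partition recovers the generator's 25 lesion-A-private, 50 trunk and 15
lesion-B-private mutations.

```r
# A 503-patient cohort with 70 planted mixed responders,
# 13 of whom received local therapy
cohort <- sim_cohort(sim_config(seed = 42,
  exact_group_counts = c(nonmixed_responder = 180, mixed_responder = 70,
                         nonmixed_nonresponder = 253),
  exact_local_therapy_count = 13))
cs <- cohort_summary(cohort$lesions, cohort$patients)
cs$pooled
#> $n: 503   $mixed: 70   $mixed_pct: 13.9
#> $mixed_local_therapy: 13   $mixed_local_therapy_pct: 18.6

sv <- compare_survival(cs$classified, "pfs")
#> log-rank chi-square = 135.6 on 2 df, p = 3.57e-30
```

Classification recovers all 503 planted group labels; 70/503 mixed
responders print as 13.9 % and 13/70 locally treated mixed responders as
18.6 %. The log-rank test separates the three groups' progression-free
survival, whose generating hazards are ordered responder < mixed <
nonresponder.

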