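# mslinc

Discovery and subtype classification of molecular subtype-specific
lincRNAs (MS-lincRNAs) in tumor transcriptomes.

Most novel long intergenic noncoding RNAs (lincRNAs) found in tumor
RNA-seq are never tied to a clinically meaningful grouping. `mslinc`
implements, as a single tested R pipeline, the analysis needed to do
that for breast cancer's five molecular subtypes (luminal A, luminal B
HER2−, luminal B HER2+, HER2-enriched, triple negative):

1. **Discovery** — candidate transcripts from an assembled catalog are
   accepted as novel lincRNAs when they lie ≥ 2 kb from every known
   gene, have mature length ≥ 200 nt, and are called noncoding by
   *both* of two coding-potential scorers (a Fickett TESTCODE + ORF
   logistic, and a hexamer log-likelihood-ratio + ORF logistic):
   accept ⟺ gap ≥ 2000 ∧ L ≥ 200 ∧ (p_A < τ ∧ p_B < τ).
2. **Expression** — FPKM low-expression filtering, Welch tests on
   log2(FPKM+1) with BH adjustment for every subtype-vs-control
   comparison, and assignment of expression classes (down in all tumors
   / up in all tumors / luminal-specific).
3. **Methylation** — Pearson correlation (t-transform p) between
   promoter CpG beta values (500–2000 bp from the strand-aware TSS) and
   expression, at P < 0.01.
4. **Coexpression network** — cis pairs (≤ 100 kb) and trans pairs
   (> 1 Mb or different chromosomes); edges require r > 0.6 at
   P < 10⁻⁵, plus PPI support for coding–coding pairs; modules by
   deterministic greedy cohesiveness w_in/(w_in + w_bound); gene-set
   enrichment by hypergeometric test.
5. **Linctype panel** — staged correlation-based feature selection
   (CFS merit k·r̄_cf / √(k + k(k−1)·r̄_ff) with symmetrical-uncertainty
   correlations, best-first search): two-class stage, six-class stage
   nested in it, per-subtype one-vs-rest stage, plus expression
   extremes; the union with provenance is the marker panel.
6. **Evaluation** — row-centered hierarchical clustering, PCA, k-means
   (k-means++ seeding, 50 restarts), Kaplan–Meier curves and log-rank
   tests over recovered clusters.

A synthetic-data generator (`simulate_study()`) emulates the study
design — 33 samples in 11 groups (5 tumor subtypes, matched adjacent,
normal; 3 each) — and plants every signal the pipeline should recover:
true lincRNAs and decoys violating each filter, subtype markers at +3
log2, methylation-repressed promoters, latent-correlated cis pairs,
PPI-constrained coding pairs, and cluster-specific survival hazards.
All ground truth is recorded, so the whole pipeline is testable offline.

## Worked example

```r
library(mslinc)

design <- simulation_design(seed = 1)
design
#> simulation_design: 33 samples in 11 groups; seed 1
#>   features: 60 coding, 20 known noncoding, 50 novel lincRNA, 35 decoys

result <- run_linctype_pipeline(design)

# every decoy is rejected by the filter that its construction violates
head(result$discovery$audit[result$discovery$audit$verdict == "rejected", ], 4)
#>   transcript_id  gap_bp mature_len p_A p_B  verdict reason
#> 1          DC01 3397199       1750   1   1 rejected coding
#> 2          DC02 3342488       1711   1   1 rejected coding
#> 3          DC03 3549044        942   1   1 rejected coding
#> 4          DC04 3502889       1126   1   1 rejected coding

result$panel
#> linctype_panel: 74 markers
#>   stage sizes: two_class=10, six_class=10, subtype_specific=92,
#>   extreme_low=6, extreme_high=3

result$survival
#> $chisq
#> [1] 69.41959
#> $df
#> [1] 4
#> $p
#> [1] 3.009643e-14
```

Reading the output: all 50 planted lincRNAs are accepted and all 35
decoys rejected for their planted reason (the coding-like decoys DC*
are intergenic and long, so only the coding-potential consensus stops
them — both scorer probabilities are 1). The panel of 74 markers
includes every planted subtype marker tagged with its subtype. On the
200-sample validation cohort the panel's k-means clusters reproduce the
subtypes exactly, and the log-rank test across those clusters detects
the planted hazard differences (χ² = 69.4 on 4 df, p ≈ 3×10⁻¹⁴).

Individual stages are exported (`filter_novel_lincrnas()`,
`differential_expression()`, `significant_meth_regulators()`,
`build_edges()`, `detect_modules()`, `select_linctype()`,
`kmeans_cluster()`, `km_estimate()`, `logrank_test()`, ...) and accept
plain matrices/data frames or the standard file formats (GTF via
`parse_gtf()`/`write_gtf()`, FASTA, TSV, BED, GMT). See
`vignette("mslinc-methods")` for the models, parameter defaults and
their rationale.

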