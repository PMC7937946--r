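# endoseq

Blood-transcriptome endotype discovery for small-to-medium vessel
vasculitis, as a tested, reusable R pipeline.

Phenotypically similar vasculitides (GPA, MPA, PAN, unclassifiable
presentations) can be driven by different immune processes. Given a gene ×
sample RNA-seq count matrix from whole blood, `endoseq` discovers
transcriptional *endotypes* — disease subtypes defined by the underlying
biology — and characterizes them:

1. **Preprocess** — globin-gene removal, median-of-ratios size factors
   (anchored to geometric mean 1), method-of-moments NB dispersion, the
   closed-form variance-stabilizing transformation
   `g(x) = (2/√α)·asinh(√(αx))`, and parametric empirical-Bayes batch
   adjustment for sequencing date.
2. **Cluster** — average-linkage hierarchical clustering of samples on
   Euclidean distances of vst values; a k-cut into two major endotypes (A,
   B) plus "other"; labels oriented so A is the cluster with higher
   neutrophil-degranulation anchor expression (S100A8, S100A9, ...).
3. **Differential expression** — per-gene NB Wald test of A vs B
   (`log2FC = log2(μ_A/μ_B)`, delta-method SE with Var = μ + αμ²,
   Benjamini–Hochberg FDR), with gene lists at the ±1.5-fold, FDR ≤ 0.05
   thresholds.
4. **Minimal signature** — the filter chain (significant DE; |FC| ≥ 2
   between cluster means; lowest-50% within-cluster variance in both
   clusters; mean normalized count ≥ 100) ranked by a signal-to-noise
   divergence score, returning ≤ 20 genes, plus re-clustering validation of
   the signature on independent cohorts.
5. **Gene-set statistics** — hypergeometric over-representation analysis,
   Fisher's exact overlap of gene lists (cross-product OR, probability-mass
   two-sided p), a self-contained rotation test of a set-level moderated-z
   statistic, and a competitive test with an inter-gene-correlation VIF
   adjustment.
6. **Markers & clinic** — T-cell marker expression ratios (TBX21:GATA3 and
   friends) with Wilcoxon rank-sum comparisons, and per-endotype clinical
   summaries (n, sex, ANCA status, mean activity score).

A synthetic-data module (`simulate_cohort()`) generates NB count matrices
with planted endotypes, batch effects, a globin block, marker genes and
enriched gene sets — plus the ground truth, so every stage is testable
end-to-end with no external data. The package also ships the clinical
characteristics of the motivating discovery cohorts (30 pediatric, 11 adult
patients) as plain-text fixtures.

## Worked example

```r
library(endoseq)

sim  <- simulate_cohort(sim_config(), seed = 1)   # 2000 genes, 13/14/3 samples
prep <- preprocess_counts(sim$counts, sim$samples)
endotypes <- cluster_samples(prep$vst) |>
  assign_endotypes(n_clusters = 3, vst = prep$vst) |>
  label_endotypes(prep$vst)
table(endotypes$label)
#>     A     B other
#>    13    14     3

de <- nb_wald_de(prep$counts, prep$sf, endotypes, prep$dispersion)
glance(de)
#> # A tibble: 1 × 5
#>   n_genes   n_a   n_b n_up_in_a n_up_in_b
#>     <int> <int> <int>     <int>     <int>
#> 1    2000    13    14        98        92

sig <- select_signature(prep$vst, prep$counts, endotypes, de, sf = prep$sf)
head(tidy(sig), 3)
#> # A tibble: 3 × 7
#>   gene   direction score passed_de passed_fc2 passed_var50 passed_count100
#>   <chr>      <int> <dbl> <lgl>     <lgl>      <lgl>        <lgl>
#> 1 G01601         1  9.04 TRUE      TRUE       TRUE         TRUE
#> 2 G01293        -1  7.47 TRUE      TRUE       TRUE         TRUE
#> 3 G01176         1  7.25 TRUE      TRUE       TRUE         TRUE

roast_test(prep$vst, endotypes, sig$gene, B = 999, seed = 1)
#> Rotation gene-set test: 20 genes, observed mean z = 8.307, p = 0.001 (B = 999)

marker_ratios(prep$vst, endotypes)
#> Marker expression ratios (A vs B, Wilcoxon rank-sum)
#>         pair  median_a  median_b     p_value
#>  TBX21:GATA3 1.2746073 0.9891181 0.001480579
#>   FOXP3:CD3E 1.0690592 1.0447360 0.789550875
#>   GATA3:CD3E 0.9546555 1.0508259 0.068799988
```

Reading the output: the clustering recovers the planted 13/14/3 structure;
190 genes pass the ±1.5-fold / FDR ≤ 0.05 thresholds (the generator plants
~200); the 20-gene signature separates the endotypes with a rotation-test p
at its attainable minimum (1/(B+1)); and the Th1:Th2 marker ratio
(TBX21:GATA3) is higher in endotype A, as planted. The per-endotype clinical
summary of the packaged discovery-cohort table reproduces its printed
characteristics:

```r
clinical_summary(load_clinical_fixture("pediatric_cohort1"))[, 1:8]
#> # A tibble: 3 × 8
#>   endotype     n female  male anca_pr3 anca_mpo anca_neg mean_activity
#>   <chr>    <int>  <int> <int>    <int>    <int>    <int>         <int>
#> 1 A           13      9     4        9        4        0            21
#> 2 B           14      9     5        5        6        3            14
#> 3 other        3      2     1        1        2        0            21
```

`run_pipeline(pipeline_config(seed = 1), outdir = "run/")` executes all
stages and writes every table plus `report.json` / `run_info.json` (config
hash, seed) to the run directory. A thin command-line wrapper lives at
`inst/cli/endoseq.R`.

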