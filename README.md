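# permatyper

Analysis toolkit for **paired gut-microbiome intervention studies** — cohorts
sampled before and after a dietary (or other) intervention. It is aimed at
microbiome researchers who need, in one tested package:

* **Enterotyping** — distance-based community typing of genus-level profiles:
  Jensen–Shannon distance, PAM (k-medoids) clustering, cluster count chosen by
  the Calinski–Harabasz index.
* **Permatyping** — a bootstrap stability refinement of enterotypes: samples
  whose cluster assignment is unstable across re-clustered bootstrap resamples
  are set aside as *unclassified*, shrinking each enterotype to its reliable
  core.
* **Responder discovery** — per-subject before/after dissimilarity under the
  generalized UniFrac metric, clustered (PAM + average silhouette width) to
  split the cohort into *responders* (large community shift) and
  *non-responders*, plus a baseline-microbiota classifier benchmarked by
  repeated train/test splits and ROC AUC.
* **PERMANOVA + power design** — distance-based multivariate ANOVA with free
  or paired (within-subject swap) permutation schemes, the bias-adjusted
  effect size ω², and a simulation framework that answers "how many subjects
  do I need?" before the study is run.
* **Compositional and diversity statistics** — CLR transform with paired
  Wilcoxon signed-rank tests and Benjamini–Hochberg adjustment, Shannon and
  Chao1 diversity, rarefaction, Bacteroidetes:Firmicutes ratios, and
  co-occurrence "cooperatives" (connected components of a taxon graph).
* **A synthetic paired-cohort generator** with full recorded ground truth, so
  every stage of the pipeline is testable without any sequencing data.

## The statistics in brief

For samples with pairwise dissimilarities `d_ij` and a k-group labelling, the
PERMANOVA decomposition is

    SST = Σ_{i<j} d_ij² / n,      SSW = Σ_g Σ_{i<j ∈ g} d_ij² / n_g,
    pseudo-F = (SSB/(k−1)) / (SSW/(n−k)),   R² = SSB/SST,
    ω² = (SSB − (k−1)·SSW/(n−k)) / (SST + SSW/(n−k))

with significance from label permutations (paired designs swap each subject's
before/after labels independently — the 2^subjects scheme). Power analysis
simulates two-group cohorts in a latent Euclidean space, affinely mapped to a
target dissimilarity mean/sd, with the group offset bisected until the
realized ω² matches the target effect size.

The generalized UniFrac distance between samples A and B over tree branches i
with lengths `b_i` and subtree abundances `p_Ai`, `p_Bi` is

    d(A,B) = Σ_i b_i (p_Ai+p_Bi)^α |p_Ai−p_Bi|/(p_Ai+p_Bi)
             ────────────────────────────────────────────
                     Σ_i b_i (p_Ai+p_Bi)^α

with α = 0.5 by default (α = 1 recovers the weighted-UniFrac normalization).

## Worked example

```r
library(permatyper)

co <- generate_cohort(cohort_config(n_subjects = 120, seed = 1))
rel_before <- to_relative(co$table_before)

enterotype(rel_before)
#> typing_result: k = 3, sizes = 43/41/36, cost = 37.21

permatype(rel_before, n_bootstrap = 100, threshold = 0.8, seed = 2)
#> permatype_result: k = 3, core sizes = 38/39/35, unclassified = 8/120 (threshold 0.80)

full <- to_relative(abundance_table(
  rbind(co$table_before$values, co$table_after$values),
  lineage = co$table_before$lineage, mode = "counts"))
dis <- paired_dissimilarity(full, co$design, tree = co$tree)
rr <- cluster_response(dis)
rr$group_stats
#>           group  n      mean         sd
#> 1 non_responder 81 0.1971271 0.03130756
#> 2     responder 39 0.3193372 0.03932431

bf <- bf_ratio(rel_before)
mean(bf[co$truth$responder]); mean(bf[!co$truth$responder])
#> responders 0.23 vs non-responders 0.09 at baseline

simulate_power(power_config(0.52, 0.06, 0.006, n_subjects = 70,
                            n_reps = 200, n_permutations = 200, seed = 3))
#> power = 0.815 (MC se 0.027) at n_subjects = 70, omega2 = 0.006
```

Reading the output: the generator planted three community types (recovered as
k = 3), a bimodal per-subject shift (recovered as two response groups whose
mean paired dissimilarities, 0.197 and 0.319, sit at the planted 0.19/0.30
modes), and a higher baseline Bacteroidetes:Firmicutes ratio among responders
(0.23 vs 0.09). The permatype step leaves 8 of 120 samples unclassified —
predominantly the planted mixed-type profiles. The power estimate says a
70-subject paired design detects an ω² = 0.006 community shift with roughly
80% power at α = 0.05.

A single-seed end-to-end run:

```r
report <- run_pipeline(run_config(synthetic = TRUE, seed = 1,
                                  out_dir = "run1"))
report$summary$k_enterotype        # 3
```

A command-line front end covering the same stages ships in
`inst/cli/permatyper` (subcommands `synth cohort`, `typing fit`,
`typing permatype`, `response run`, `power estimate`, `power size`,
`pipeline run`).

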