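# nmfsubtypes

Transcriptomic subtype discovery and prognostic modeling for bulk RNA-seq
tumor cohorts, packaged as a reusable, fully tested pipeline:

1. **Normalization and gene selection** — median-of-ratios size factors;
   top-variance genes with a median filter and mitochondrial exclusion.
2. **Consensus NMF subtyping** — Brunet multiplicative updates for the
   generalized Kullback–Leibler divergence, V ≈ WH with W, H ≥ 0; many
   random restarts per candidate rank k; a sample × sample consensus
   matrix (fraction of runs in which two samples co-cluster); rank chosen
   by the cophenetic coefficient of the consensus.
3. **Subtype-specific genes** — the entropy-based basis-specificity score
   S_i = 1 + (1/log₂k) Σ_q p(i,q) log₂ p(i,q), with
   p(i,q) = W_iq / Σ_q W_iq; S_i = 0 for a uniform profile and 1 for a
   gene loading on a single program.
4. **Minimal nearest-centroid signature** (ClaNC-style) — genes owned by
   the class maximizing the class-vs-rest t-statistic, top N per class
   (k·N genes total), classification by nearest centroid; N selected by
   repeated stratified 70/30 cross-validation.
5. **Lineage-mixing scores** — per-sample shares of LUAD/LUSC/NET marker
   expression, S_type = Σ expr(type markers) / Σ expr(all markers), and
   the mix-lineage score S_mix = 1 − max(S).
6. **Prognostic risk models** — Cox proportional hazards (Efron ties)
   over nine covariate sets A–I, with the expression subtype encoded as
   the Euclidean distances of each sample to the k subtype centroids;
   Harrell's c-index in training and held-out cohorts;
   likelihood-ratio tests for adding the subtype distances; Kaplan–Meier
   curves and follow-up-horizon truncation.

Cohorts of this kind are usually controlled-access, so the package
includes a first-class synthetic-data generator (negative-binomial counts
with planted subtype programs, mitochondrial and lineage-marker genes,
subtype-linked proportional-hazards survival with independent censoring,
stage–subtype association, driver flags and grade) that makes every stage
testable end to end. See the methods vignette
(`vignettes/subtype-discovery-methods.Rmd`) for the model, parameter
defaults and design rationale.

## Worked example

```r
library(nmfsubtypes)

ds   <- generate_dataset(synthetic_config(samples_per_subtype = 30, n_genes = 1000,
                                          n_signature_genes_per_subtype = 100, seed = 7))
expr <- normalize_counts(ds$counts)            # median-of-ratios
sel  <- select_genes(expr, n_top = 1000)       # median > 1, non-mito, top variance

cons <- lapply(2:4, function(k)
  consensus_over_runs(sel, rank = k, n_runs = 20, base_seed = 100 * k))
select_rank(cons)
#> rank_selection: chosen rank 3
#>  rank cophenetic silhouette_consensus silhouette_coef silhouette_basis
#>     2  0.9987644            0.8029661       0.9190560       0.39333115
#>     3  1.0000000            1.0000000       0.9101999      -0.02322930
#>     4  0.9996427            0.9303622       0.7583361      -0.03683567
```

The rank-3 consensus is perfectly stable (cophenetic = 1) while ranks 2
and 4 are slightly less so; rank 3 is selected, matching the three
planted subtypes. The best run's argmax-H labels recover the planted
grouping exactly (the cluster indices are arbitrary):

```r
assign <- assign_clusters(cons[[2]]$best_fit)
table(assign$labels, ds$true_labels)
#>      1  2  3
#>   1  0 30  0
#>   2 30  0  0
#>   3  0  0 30
```

A 60-gene signature (N = 20 per class) distills the subtypes; repeated
70/30 cross-validation estimates its error:

```r
sig <- build_signature(sel, assign$labels, n_per_class = 20)
cv  <- cross_validate_signature(sel, assign$labels, N_range = c(5, 10, 20),
                                repeats = 20, seed = 1)
cv$per_N_errors
#>    N train_error test_error     test_se
#> 1  5  0.01428571 0.05555556 0.012165679
#> 2 10  0.01349206 0.03148148 0.008183072
#> 3 20  0.01428571 0.04814815 0.013461588
```

so at N = 20 about 1% of training and 5% of held-out samples are
misclassified. The lineage-mixing score singles out the planted
lineage-chaotic subtype (configured cross-lineage fractions
0.05 / 0.15 / 0.5):

```r
sc <- lineage_score(expr, ds$lineage_sets)
round(tapply(sc$mix, ds$true_labels, mean), 3)
#>     1     2     3
#> 0.063 0.183 0.562
```

and the centroid-distance Cox model outperforms stage alone (hazard in
the generator depends on subtype only; stage is prognostic purely via its
association with subtype):

```r
cohort <- list(expr = sel, survival = ds$survival)
reg <- run_model_registry(cohort, cohort, sig, models = c("A", "C", "F"))
reg[c("model_id", "description", "cindex_train", "lrt_p")]
#>  model_id        description cindex_train        lrt_p
#>         A              stage    0.5949625 5.221452e-05
#>         C expression subtype    0.6670839 7.974233e-06
#>         F    subtype + stage    0.6814768           NA
```

(`lrt_p` for model A is the likelihood-ratio test for adding the subtype
distances to the stage model; for model C it is the test against the null
model.)

The whole workflow, with TSV/JSON artifacts and a checksummed manifest,
also runs as one call — `run_pipeline(default_pipeline_config())` — or
from a shell via the thin CLI in `inst/scripts/nmfsubtypes-cli.R`
(`simulate | normalize | subtype | signature | lineage | risk | all`).

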