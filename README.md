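# mirhubnet

Identify disease-subtype-related miRNAs from **two** miRNA–miRNA
interaction networks built on miRNA–mRNA dual expression profiles of the
same samples — one network from miRNA expression, one from a
reconstructed *target activity* dataset — and intersect their
topological hubs. Designed for two-class tumour-subtype cohorts (the
motivating case: basal-like vs luminal-A breast cancer) and for anyone
who wants a fully reproducible, synthetic-data-testable implementation
of MI-network hub analysis.

## Method in brief

1. **Differential filter** — permutation SAM statistic
   `d_i = (x̄_iA − x̄_iB)/(s_i + s0)` with a pooled permutation null;
   working set at `P < 0.05`, `FDR < 0.1`; subtype *trend* labels at
   `P < 0.001`, `FDR < 0.05`.
2. **Mutual information networks** — Kraskov–Stögbauer–Grassberger
   kNN estimator (algorithm 1, `k = 3`, nats):
   `Î(X;Y) = ψ(k) + ψ(N) − ⟨ψ(n_x+1) + ψ(n_y+1)⟩`,
   a permutation-null MI floor, then ARACNE data-processing-inequality
   pruning: edge (i,j) of a triple is removed when
   `MI(i;j) < MI(j;k) − ε` **and** `MI(i;j) < MI(i;k) − ε`, `ε = 0.05`.
3. **Activity layer** — each miRNA's activity profile is the first
   principal component (sample scores) of its target genes' centred
   mRNA expression; the second network is built on these profiles.
4. **Hubs** — degree ≥ threshold (default 15) in **both** networks,
   with a Poisson degree null (`P(X ≥ t)`, `λ` = average degree)
   exposed for threshold advice; the common-hub report averages
   degree/betweenness/closeness across the two networks.
5. **Validation** — stratified 5-fold CV with naive Bayes / kNN (k=3) /
   RBF-SVM / random forest (5000 trees); random-set correlation test;
   permutation global test `Q = Σ_j (x_jᵀy)²/m`; K-means (k=2) +
   log-rank survival comparison.

A synthetic dual-profiling generator plants hub modules, class shifts,
miRNA→target coupling and survival structure with a full ground-truth
record, so the entire pipeline runs and is tested without any external
data. See the methods vignette
(`vignettes/dual-network-mirna-discovery.Rmd`) for every model
assumption, parameter default, and design decision.

## Worked example

Simulate a dual-profiling cohort of 30 + 82 samples whose subtype
signal sits on four planted hub modules (shift the module factor, so
hubs and their partners are subtype related, as in the motivating
cohort), then run the whole pipeline:

```r
library(mirhubnet)

cfg <- synthetic_config(n_class_a = 30, n_class_b = 82, n_mirna = 60,
                        n_hubs = 4, module_size = 4, rho = 0.9,
                        de_fraction = 0.1, n_genes = 400, seed = 7)
sim <- generate_dual_dataset(cfg)
shift <- sample_labels(sim$mirna) == "luminal_A"
for (h in sim$truth$hub_ids) {
  sim$mirna[h, shift] <- sim$mirna[h, shift] + 1.5
  for (m in sim$truth$module_members[[h]])
    sim$mirna[m, shift] <- sim$mirna[m, shift] + cfg$rho * 1.5
}

res <- run_pipeline(sim$mirna, sim$mrna, sim$targets,
                    survival = sim$survival, seed = 7,
                    degree_threshold = 2)
res
#> pipeline_result (seed 7)
#>   selected differential miRNAs: 25
#>   expression network: 20 edges | activity network: 29 edges
#>   common hubs (degree >= 2): 6
#>   global test: Q = 735.969, p = 0.0001
#>   log-rank: chisq = 0.261, p = 0.6097
```

Reading the output: 25 of 60 miRNAs pass the relaxed differential
filter; the MI networks on their expression and activity profiles keep
20 and 29 edges after the null floor and DPI pruning; 6 miRNAs are hubs
in both networks. The global test confirms the hub set's joint
expression pattern separates the two subtypes (p = 1e-4, the resolution
of 10,000 permutations), and the log-rank p ≈ 0.61 correctly reports no
survival difference — the generator's default hazard ratio is 1.

```r
head(res$hub_report$common_hubs)
#>     mirna avg_degree avg_betweenness avg_closeness         trend
#> 1 miR-032        4.0        33.50000     0.6451613 class_b_trend
#> 2 miR-030        3.5         4.25000     0.6578947 class_b_trend
#> 3 miR-055        3.0        15.83333     0.6916667 class_b_trend
#> 4 miR-031        3.0        13.50000     0.5069444 class_b_trend
#> 5 miR-043        2.0        28.00000     0.3673401 class_b_trend
#> 6 miR-014        2.0        22.50000     0.3400673 class_b_trend

sim$truth$hub_ids
#> [1] "miR-002" "miR-030" "miR-031" "miR-032"
```

Three of the four planted hubs top the common-hub report, each labelled
with the planted subtype trend. The classifier battery shows the 6-hub
panel carries almost all of the 25-feature set's discriminative power:

```r
subset(res$classification, matrix_kind == "expression")
#>   matrix_kind  feature_set    classifier n_features  accuracy
#> 1  expression  common_hubs   naive_bayes          6 0.9454545
#> 2  expression  common_hubs           knn          6 0.9458498
#> 3  expression  common_hubs       svm_rbf          6 0.9545455
#> 4  expression  common_hubs random_forest          6 0.9371542
#> 5  expression differential   naive_bayes         25 0.9818182
#> 6  expression differential           knn         25 0.9818182
#> 7  expression differential       svm_rbf         25 0.9909091
#> 8  expression differential random_forest         25 0.9909091
```

Per-stage functions (`permutation_test`, `build_network`,
`activity_scores`, `node_centralities`, `network_summary`,
`common_hub_report`, `crossval_accuracy`, `global_test`,
`survival_compare`, …) are exported individually; a thin CLI over them
with `simulate / diffexpr / network / activity / topology / hubs /
evaluate / run-all` subcommands ships at `inst/scripts/mirhubnet.R`.

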