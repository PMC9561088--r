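# enmecotype

An R workflow for proposing candidate **livestock ecotypes** from
village-level occurrence records and gridded environmental layers, using
presence-background ecological niche modelling. It was built for the
setting where indigenous populations (here, village chicken populations
sampled across 16 districts of a topographically diverse region) are still
managed as one undifferentiated group, and habitat characterization is the
first, cheapest evidence for splitting them into management units.

The pipeline runs the complete protocol:

1. **Occurrence expansion** — each sampled village becomes 10 presence
   points (the GPS point plus 9 random points in a 1.2 km² square).
2. **Variable screening** — Spearman rank correlations (threshold 0.6)
   with expert-priority pruning, PCA inspection, and an iterative
   maxent-based selection that drops low-contribution (< 5%) and
   collinear variables per beta multiplier, keeping the minimum-AICc set.
3. **Maximum-entropy niche models** — fitted from scratch: the model over
   background cells $x$ is $\mathrm{raw}(x) = e^{\lambda\cdot f(x)}/Z$,
   with feature classes L/Q/P/H/T/C and per-feature L1 bounds
   $\beta_j = \mathrm{BM}\cdot c_{\mathrm{class}}(m)\, s_j/\sqrt{m}$,
   minimized by cyclic coordinate descent with soft-thresholding. Feature
   class and beta multiplier are chosen by small-sample-corrected AIC over
   a candidate grid (the default grid has 192 combinations).
4. **Evaluation** — rank-based AUC on a 75/25 split with regionalised
   ten-fold cross-validation, jackknife gains, percent contribution,
   permutation importance, response curves.
5. **Ecotype delineation** — pairwise Pearson correlation and Hellinger
   niche overlap (I) between per-district suitability maps; hierarchical
   clustering of the Euclidean distances between similarity-matrix rows
   under four linkages; linkage chosen by agglomerative coefficient; tree
   cut into ecotypes, with cross-metric disagreements flagged.

A **synthetic landscape generator** (correlated Gaussian-field layers,
planted Gaussian ecotype niches, and the matching 16-district / 32-village
/ 320-point design) makes every stage runnable and testable offline.

## Worked example

```r
library(enmecotype)

sc  <- synthetic_scenario(seed = 1)          # landscape + planted truth
cfg <- run_config(sc$stack, sc$design$table, seed = 1,
                  out_dir = "run1", k_override = 4)
rep <- run_pipeline(cfg)

rep$screening$selected
#> [1] "bio13" "bio5"  "bio8"
c(rep$tuning$fc_set, rep$tuning$bm)
#> [1] "LQP" "2"
range(unlist(rep$districts$auc_train))
#> [1] 0.8629395 0.9936890
unlist(rep$clustering$overlap_I$ac)
#> single complete  average     ward
#>  0.725    0.817    0.787    0.892
rep$clustering$overlap_I$chosen_linkage
#> [1] "ward"
```

The screening recovered exactly the three layers that generate the planted
suitability (the five decoy layers are dropped); AICc picked a
linear-quadratic-product model at beta multiplier 2; each district's model
separates its habitat from the background (training AUC 0.86–0.99); and
Ward linkage — the strongest agglomerative coefficient under both
similarity metrics — cuts into four ecotypes that match the planted
partition exactly (adjusted Rand index 1 under both metrics, no
cross-metric disagreements). `run1/` holds the stage artefacts: occurrence
and similarity CSVs, tuning grid, jackknife table, Newick dendrograms,
per-district and per-ecotype suitability maps, and `report.json`, which is
byte-identical across reruns with the same configuration and seed.

The same run can be executed stage by stage as a narrated analysis:

```sh
SEED=1 Rscript analysis/01_simulate.R        # landscape, villages, truth
SEED=1 Rscript analysis/02_screen.R          # expansion + screening
SEED=1 Rscript analysis/03_tune_fit.R        # AICc tuning + district models
SEED=1 Rscript analysis/04_evaluate.R        # AUC/CV/jackknife/importance
SEED=1 Rscript analysis/05_compare_cluster.R # similarity + ecotypes
```

each writing its tables under `results/run_seed1/`.

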