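# synsig

Transcriptomic analysis of combination drug treatments: synergy gene
signatures, single-sample gene-set enrichment, tumor immune-infiltration
stratification, and expression-split survival analysis — with a
synthetic-data generator that gives every stage a planted ground truth.

## Who this is for

Computational biologists analysing multi-arm treatment experiments
(e.g. an HDAC inhibitor, a retinoid and a chemotherapeutic agent, singly
and in combination, against vehicle) who need the standard downstream
battery as tested, scriptable R functions rather than one-off notebook
code: which genes does the combination change beyond *either* single
agent, which pathways move per sample, does the induced module track
immune infiltration in a tumor cohort, and does it stratify patient
survival?

## The statistics at the core

* **Moderated t**: per-gene pooled variance shrunk toward the across-gene
  mean with fixed prior weight d0/(d0 + df), d0 = 4; p from t on df + d0;
  BH step-up FDR. Signatures at ≥ 2-fold and FDR ≤ 0.05.
* **Synergy set**: genes passing the signature thresholds in the
  combination-vs-agent contrast for *both* single agents, with consistent
  direction (union mode available).
* **Enrichment score**: unweighted Kolmogorov–Smirnov running sum over the
  sample's descending expression ranking, in [−1, 1]; invariant to
  per-sample monotone transforms; groupwise one-way ANOVA across arms;
  preranked tests against a random-set null.
* **Gene-wise permutation test**: Spearman ρ between a target-set module
  score and an immune score, compared with 10,000 random same-size gene
  sets; add-one p, so min p = 1/10001 < 0.001.
* **Survival**: Kaplan–Meier product-limit, two-group logrank
  χ² = (O−E)²/V, hazard ratio (O_A/E_A)/(O_B/E_B) with
  exp(log HR ± 1.96·√(1/E_A + 1/E_B)) CI; median expression splits,
  ties low.

Design rationale and model details are in the methods vignette
(`vignettes/synergy-pipeline.Rmd`).

## Worked example

```r
library(synsig)

# 8-arm experiment (Veh, E, A, D, EA, ED, AD, EAD) x 4 replicates x 2 batches
design  <- treatment_design(replicates_per_arm = 4)
effects <- effect_model()   # plants IFN up in ED/EAD, cell-cycle down, HDAC-response 96% up
sim  <- simulate_treatment_experiment(design, effects, seed = 1)
expr <- batch_center(sim$expr, sim$annotation)

# combination-synergy signature: ED vs both single agents, direction-consistent
syn <- synergy_set(gene_stats(expr, sim$annotation, "ED", "E"),
                   gene_stats(expr, sim$annotation, "ED", "D"))
syn
#> <de_signature> ED vs E & ED vs D: 99 up, 78 down (FC >= 2, FDR <= 0.05)

# cohort with a latent infiltration gradient shared by immune + IFN modules
cohort <- simulate_cohort(cohort_model(), seed = 1)
imm <- sprintf("g%04d", 1:50); ifn <- sprintf("g%04d", 51:90)
imm_score <- module_score(cohort$expr, imm)
spearman_cor(module_score(cohort$expr, ifn), imm_score)
#> # A tibble: 1 x 3
#>     rho         p     n
#>   0.995 2.23e-308   500
genewise_permutation_test(cohort$expr, ifn, imm_score,
                          n_perm = 10000, seed = 2, exclude = imm)
#> # A tibble: 1 x 3
#>     rho      p n_perm
#>   0.995 0.0001  10000

table(stratify_infiltration(cohort$expr, imm)$group)
#>    low medium   high
#>    185    162    153

# survival split by the IFN module score
ifn_score <- module_score(cohort$expr, ifn)
surv <- simulate_survival(ifn_score, survival_model(coef = 1), seed = 3)
grp  <- median_split(ifn_score[surv$patient_id])
logrank_test(surv[grp == "high", ], surv[grp == "low", ])
#> <logrank> chi2 = 155.495, p = 1.09e-35, HR = 3.138 [2.530, 3.893]
```

Reading: the synergy signature recovers the planted combination-specific
genes (99 of 100 IFN genes up plus the strongest cell-cycle repressions);
the IFN and immune module scores share the planted latent factor
(ρ = 0.995, permutation p at its 1/10001 floor); the cohort splits into
three infiltration groups; and a high IFN score carries a ~3-fold hazard
(here the planted hazard is *adverse* by construction — the generator's
coefficient, not a biological claim).

Every result type has `tidy()`/`glance()` methods and `autoplot()`
(volcano, PCA, enrichment heatmap, KM curve). `run_pipeline()` executes
all stages from a YAML config into a directory of TSVs plus a hashed
manifest; `validate_config()` checks the config up front.

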