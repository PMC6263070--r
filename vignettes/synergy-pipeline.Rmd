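---
title: "Methods: synergy signatures, enrichment scoring, immune stratification and survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synergy signatures, enrichment scoring, immune stratification and survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synsig)
```

## The analysis this package implements

`synsig` is a reusable implementation of a transcriptomic analysis pattern
common in combination-therapy studies of triple-negative breast cancer:
an eight-arm treatment design — vehicle (Veh), three single agents
(entinostat **E**, an HDAC inhibitor; all-trans retinoic acid **A**;
doxorubicin **D**) and their combinations (EA, ED, AD, EAD) — profiled on
expression arrays in duplicate across two hybridisation batches, followed by

1. **Preprocessing**: background subtraction, quantile normalisation, log2
   transformation, additive batch correction, PCA for design QC;
2. **Differential expression**: gene-wise moderated-t contrasts with
   Benjamini–Hochberg control, signatures thresholded at ≥ 2-fold and
   FDR ≤ 0.05;
3. **Synergy derivation**: genes regulated by a combination relative to
   *both* constituent single agents with consistent direction;
4. **Enrichment**: per-sample rank-based gene-set scores, one-way ANOVA
   across arms, and preranked set tests with a random-set permutation null;
5. **Immune stratification** of a tumor cohort into low/medium/high
   infiltration groups, module scores, Spearman association, and a
   gene-wise permutation test;
6. **Survival**: expression-split Kaplan–Meier curves, logrank test and an
   O/E hazard ratio with a 95% CI.

No real microarray or patient cohort ships with the package; instead, every
stage is exercised against a synthetic-data generator that plants the
statistical structure the analysis assumes, giving each stage a ground truth
to be tested against.

## Models and statistics

### Moderated t (differential expression)

For genes $g$ and a contrast of arms $a$ vs $b$ with $n_a, n_b$ replicates,
the log2 fold-change is $\hat\Delta_g = \bar x_{ga} - \bar x_{gb}$ and the
pooled variance $s_g^2$ has $d = n_a + n_b - 2$ degrees of freedom. With a
handful of replicates per arm, per-gene variances are noisy, so they are
shrunk toward the across-gene mean $\bar{s}^2$ with a fixed prior weight:

$$\tilde s_g^2 = \frac{d_0\,\bar{s}^2 + d\,s_g^2}{d_0 + d},\qquad
t_g = \frac{\hat\Delta_g}{\sqrt{\tilde s_g^2 (1/n_a + 1/n_b)}},$$

with $t_g$ referred to a t distribution on $d + d_0$ df. The prior weight
defaults to $d_0 = 4$; $d_0 = 0$ recovers the textbook pooled-variance t
exactly (this reduction is oracle-tested). A fixed $d_0$ was chosen over an
empirical-Bayes estimate so the statistic is fully specified by the data and
one documented constant.

### Signatures and the synergy set

A signature keeps genes with $|\hat\Delta_g| \ge \log_2(\mathrm{FC})$ and
BH $q_g \le$ FDR (defaults: FC = 2, FDR = 0.05). The synergy set of a
combination (e.g. ED) intersects the signatures of the combination against
each single agent and additionally requires the direction to agree in both
contrasts. The intersection-with-consistent-direction rule is the
conservative reading of "changed relative to either single agent"; a union
mode is available (`synergy_set(..., mode = "union")`) because the stricter
and looser readings are both defensible.

### Per-sample enrichment score

The single-sample score is an unweighted Kolmogorov–Smirnov running sum:
rank the sample's genes by descending expression (ties broken by gene id),
walk the ranking adding $1/|S|$ at members of set $S$ and subtracting
$1/(|U\setminus S|)$ elsewhere, and report the signed maximum-magnitude
deviation, a number in $[-1, 1]$. This is a deliberate simplification of
GSVA-style kernel scoring: it keeps the two properties the downstream
analysis actually uses — invariance to any per-sample monotone transform,
and sign = direction of enrichment — while being exactly enumerable, which
is how it is tested (exhaustive enumeration of all sets at $|U| = 8$).
No numeric equality with the GSVA package is claimed anywhere.

### Permutation nulls

Both the preranked set test and the cohort association test draw their null
from **random gene sets of matched size** ("gene-wise" permutation), not
from sample shuffling: the per-sample infiltration score stays fixed while
the target set is re-drawn from a background universe (all genes minus the
immune core, so the null statistic is independent of the score under the
null). P-values use the add-one estimator $p = (1 + \#\{\text{null} \ge
\text{obs}\})/(N+1)$, bounded below by $1/(N+1)$ — with the conventional
$N = 10{,}000$ the smallest reportable p is $\approx 10^{-4}$, i.e.
"p < 0.001". Sample-label permutation is available behind
`unit = "samples"` for comparison.

### Infiltration stratification

Cohort samples are clustered hierarchically on the matrix restricted to a
core immune gene set and the 3-cut groups are relabelled low → medium →
high by ascending mean immune module score. One design point deserves
emphasis: a **correlation** metric is *provably blind* to the signal of
interest here, because an infiltration factor moves all module genes up or
down together, and Pearson correlation across genes subtracts each sample's
own mean — a coordinated shift changes nothing. Stratification therefore
uses euclidean distance on gene-standardized values; correlation distance
(1 − Pearson) remains the default metric elsewhere, where profile *shape*
is what matters (e.g. heatmap gene clustering).

The module score itself is the mean across member genes of each gene's
z-score across samples (zero-variance members are dropped with a warning);
it is intentionally distinct from the enrichment score so the two can be
cross-checked.

### Survival

The Kaplan–Meier estimator, two-group logrank test and hazard ratio are the
classical formulas: $S(t) = \prod_{t_i \le t}(1 - d_i/n_i)$;
$\chi^2 = (O_A - E_A)^2/V$ with the hypergeometric variance summed over
event times; $\mathrm{HR} = (O_A/E_A)/(O_B/E_B)$ with
$\mathrm{CI} = \exp(\log \mathrm{HR} \pm z_{0.975}\sqrt{1/E_A + 1/E_B})$.
The O/E hazard ratio was chosen over Cox regression because it reuses the
logrank machinery, needs no optimizer, and is the quantity the logrank test
already justifies; it agrees with Cox closely when hazards are
proportional. Expression splits use the median with ties going low — the
simplest fully reproducible cutoff; `prognosis_scan()` exposes a combined
module-score mode as well as the default per-gene scan. These routines are
cross-validated against `survival::survfit()` / `survdiff()` on random
tables to 1e−8 in the test suite; the package's own implementations are the
ones used throughout, the survival package serves only as the oracle.

## The synthetic-data generator

`simulate_treatment_experiment()` draws
$x_{gs} = \mu_g + \beta_{g,\mathrm{batch}(s)} + \delta_{g,\mathrm{arm}(s)}
+ \varepsilon_{gs}$ on the log2 scale: a per-gene baseline
$\mu_g \sim U(6, 12)$, an additive per-gene batch shift drawn once per
batch ($\mathcal N(0, 0.3^2)$ by default — the "minor batch effect"
pattern, exactly removable by mean-centering), planted per-(arm, module)
effects, and i.i.d. Gaussian noise (sd 0.3). Defaults plant the structure
the eight-arm experiment is known for: an IFN module up 1.5 log2 units in
ED/EAD only, a cell-cycle module (MYC/E2F/G2M-like) down in D-containing
arms, and an HDAC-response module whose entinostat effects are 96% upward
(`fraction_up = 0.96`) — a generator parameter mirroring the strong upward
skew HDAC inhibition shows, not a claim about any dataset.

`simulate_cohort()` draws a latent infiltration factor from a 3-component
Gaussian location mixture (locations −2/0/+2, within-component sd 0.4) and
adds it, scaled by loadings 1.0 and 0.8, to a 50-gene immune core and a
40-gene IFN set on top of baseline + noise (sd 0.5). The within-component
sd is the one free parameter the three-group structure does not pin down;
0.4 puts adjacent components ~5 sd apart, the regime in which discrete
low/medium/high groups are a faithful description of the data rather than
an arbitrary discretisation. `simulate_survival()` draws exponential event
times with rate $\lambda_0 e^{\beta\,\mathrm{score}}$ under independent
exponential plus administrative censoring.

What the generator deliberately does **not** emulate: probe-level bead
chemistry, heavy-tailed or count-like marginals, gene–gene correlation
beyond the planted modules, informative censoring, and real cohorts'
subtype structure. Passing tests therefore demonstrate that the
*machinery* is correct and calibrated under its stated model — not that
real data meet that model.

## Numerical choices

* Quantile normalisation maps tied values to the mean of the reference
  quantiles their ranks span (mid-rank convention). Exact idempotence and
  exact equality of sorted columns hold for tie-free (continuous) data;
  with ties both hold up to the tie-averaging itself.
* PCA: SVD of gene-centered (not variance-scaled) data; component signs are
  fixed by making each loading's largest-magnitude entry positive, so
  results are reproducible to the bit.
* Batch centering refuses designs where a batch coincides 1:1 with an arm,
  where removing the batch mean would remove the treatment effect.
* `background_subtract()` uses the per-sample 5th percentile by default and
  floors at 1.0 intensity unit.
* All stochastic operations take an explicit integer seed;
  `run_pipeline()` derives per-stage seeds from one global seed by a fixed
  offset table so stages can be rerun independently yet reproducibly.
* Degenerate inputs error early with located messages (duplicate ids,
  confounded batches, constant vectors, empty intersections, singleton
  groups), never silently propagate.

## Problem sizes used by the test suite

Unit and acceptance tests run the generator at 200–2000 genes, 2–4
replicates per arm, cohorts of 40–500 samples, 50–200 calibration seeds and
500–10,000 permutations — sizes chosen so the full suite completes in well
under a minute while leaving the planted effects at the operating points
stated above (e.g. planted |log2FC| 1.5 at noise sd 0.3 is a 5-sigma
effect at n = 4 per arm, where ≥ 90% recovery is the correct expectation,
and a 100,000-draw Monte-Carlo oracle pins the cohort score correlation).

## Known limitations

* The enrichment scorer is unweighted KS; strongly size-imbalanced sets
  behave differently under weighted (GSEA p = 1) statistics.
* The O/E hazard ratio is biased toward 1 relative to Cox when censoring
  is heavy and unbalanced between groups.
* Hierarchical clustering inherits `stats::hclust` tie-breaking; trees are
  deterministic for a fixed input but merge order between exactly tied
  pairs follows hclust's internal convention.
* The spearman p-value uses the large-sample t approximation; for n < 10
  an exact method would be preferable.
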