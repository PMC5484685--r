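---
title: "Inferring multitrophic community webs from ordination congruence and path models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring multitrophic community webs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophicweb)
```

## The problem

Species-rich ecosystems are sampled as a stack of plot-by-species abundance
tables, one per trophic group — woody and herbaceous plants, herbivorous and
predatory arthropods, fungal guilds, bacterial phyla. The scientific
question this package addresses is whether the *community composition* of
these groups covaries across trophic levels, and, where it does, whether the
statistical support favours bottom-up control (producers structure consumer
communities) or top-down control (consumers structure producer communities).

The pipeline has four stages:

1. **Ordination.** Each group's table is converted to within-plot relative
   abundances and summarised by the site scores of its first two principal
   component axes (`to_relative_abundance()`, `pca_site_scores()`). The 13
   environmental and spatial plot descriptors are likewise reduced to two
   axes by correlation PCA (`environment_scores()`).
2. **Congruence screening.** Every pair of groups is tested for concordance
   of their ordinations with the symmetric Procrustes correlation
   `t = sqrt(1 - m²)` and a permutation (protest) test
   (`procrustes_m2()`, `protest()`, `pairwise_congruence()`), adjusted for
   multiplicity (`adjust_pvalues()`). Redundant or unlinked candidate
   groups can be collapsed with `screen_groups()`.
3. **Path modelling.** Significant pairs seed a maximum-likelihood
   covariance-structure model over the site scores with the environment
   axes as exogenous covariates (`initial_model()`, `websem()`). The model
   is expanded by modification indices (`expand_via_mi()`) and pruned by
   stepwise AIC (`prune_by_aic()`) to a minimum adequate model.
4. **Direction comparison.** The whole search is run once with cross-level
   paths oriented from producers upward and once reversed;
   `compare_directions()` reports both final fits and the AIC difference,
   with `|ΔAIC| < 2` treated as equivocal.

`diversity_web()` runs the same engine on per-group species richness or
Shannon diversity instead of composition axes, starting from the less
conservative all-cross-level initial model.

## The model

All modelled variables are observed (site scores or diversity values), so
the path model is a recursive simultaneous-equation system. In reticular
action form the implied covariance is

$$\Sigma(\theta) = (I - B)^{-1}\,\Psi\,(I - B)^{-\mathsf T},$$

where free entries of $B$ are directed paths and free entries of $\Psi$ are
residual variances (diagonal) and within-level or exogenous covariances.
`websem()` minimises the normal-theory discrepancy

$$F_{\mathrm{ML}}(\theta) = \ln|\Sigma(\theta)| + \mathrm{tr}\,(S\,\Sigma(\theta)^{-1}) - \ln|S| - p$$

with an analytic gradient (quasi-Newton, residual variances on the log
scale; seeded random restarts on non-convergence; start values are zero
paths with sample variances). $S$ is the divisor-$N$ covariance of the
column-centred data, and the reported statistic is
$\chi^2 = N\,F_{\mathrm{ML}}(\hat\theta)$. This convention, rather than
$N-1$, is adopted because it reproduces published worked examples of the
derived RMSEA to print precision; with
$\mathrm{RMSEA} = \sqrt{\max(\chi^2 - \mathrm{df}, 0)/(\mathrm{df}\cdot N)}$,
$(\chi^2, \mathrm{df}, N) = (132.4, 115, 27)$ gives 0.075 where the $N-1$
variant gives 0.076. The close-fit test of $H_0\!: \mathrm{RMSEA} \le 0.05$
uses the upper tail of a noncentral $\chi^2_{\mathrm{df}}$ with
noncentrality $N\cdot\mathrm{df}\cdot 0.05^2$. AIC is computed from the
full Gaussian log-likelihood (constants included), so nested models obey
$\mathrm{AIC}_A - \mathrm{AIC}_B = (\chi^2_A - \chi^2_B) - 2(\mathrm{df}_A -
\mathrm{df}_B)$.

Standard errors come from the inverse expected (Fisher) information at the
optimum. Modification indices are score (Lagrange-multiplier) statistics:
for a candidate parameter $a$ fixed at zero,
$\mathrm{MI}_a = \tfrac{N}{2}\, g_a^2 / s_a$ with $g$ the gradient of
$F_{\mathrm{ML}}$ and $s_a$ the Schur complement of the candidate in the
expected information over free parameters plus candidate. The expected
information is used deliberately: the observed Hessian at a misfitting
restricted model contains $(S-\Sigma)$ terms that can inflate or deflate
score statistics by large factors, which we verified against refit
oracles during development.

All observed variables are standardised to unit variance before fitting.
The data give no natural common scale across ordinations, standardisation
stabilises the optimisation, and AIC *differences* between models on the
same variables — the only AIC quantity the method interprets — are
invariant to it.

## The model search

The search mirrors the three assembly steps of the field protocol:

- only group pairs with significant (raw permutation $P < 0.05$) Procrustes
  correlation enter the initial model;
- each pair contributes a single link on the most significant of the four
  axis-pair correlations (`axis_pair_selection()`; ties broken by larger
  $|r|$, then by fixed pair order);
- links across trophic levels are directed paths oriented by the causal
  regime, links within a level are covariances; environment links are
  selected by the same axis-pair procedure and always point from the
  environment axes.

Only groups holding at least one link enter the model (both their axes);
with no links at all the model reduces to the environment block. This keeps
the variable count — and hence the number of fitted moments — proportional
to the evidence, which matters at 27 plots.

Two numerical choices in the search deserve explanation:

- **Small-sample correction of the adequacy test.** With $p$ observed
  variables and $N$ plots the raw likelihood-ratio statistic is strongly
  inflated when $p(p+1)/2$ is not small against $N$ (at $p = 14$, $N = 27$ a
  true model is rejected at nominal 5% about two-thirds of the time). The
  expansion loop therefore judges global adequacy by the Swain-corrected
  statistic (a multiplicative correction factor depending on $p$, the
  number of free parameters and $N$); reported fit indices keep the
  uncorrected convention above. Without the correction, the expansion step
  chases sampling noise and the two directional branches drift apart
  arbitrarily.
- **Two-tier expansion rule.** While the corrected global test rejects,
  the admissible candidate with the largest modification index at least
  3.84 (the $\chi^2_1$ critical value at 0.05) is freed, ties broken by
  larger expected change. Once the global test is passed, expansion
  continues only for candidates whose index clears a Bonferroni bound over
  the current candidate pool ($\chi^2_1$ at $0.05/\#\mathrm{candidates}$).
  The global test at this scale has little power, and stopping at its
  first non-rejection was observed to leave strong real pathways
  unmodelled in whichever branch happened to fit earlier — biasing the
  direction comparison. The Bonferroni tier frees parameters with
  overwhelming individual evidence while adding essentially nothing under
  a true model.

Pruning is greedy backward elimination: at each step the single path or
covariance whose removal most lowers AIC is dropped (refitting each
candidate with warm starts), until no removal lowers AIC. Residual
variances are never removed. Admissibility is enforced throughout: no
cross-level path against the regime, covariances only within level or
among the exogenous environment axes, nothing directed into the
environment.

## The synthetic generator

`simulate_dataset()` generates the study conditions at desk scale: 27 plots
by default, six groups on three trophic levels (two producer, two
consumer, two top-consumer groups), each group carrying two latent
composition axes. Cross-level transmission follows two parallel chains
(plants → herbivores → predators, or reversed under the top-down
scenario) with coefficient `strength` on the dominant axis and
`0.4 * strength` on the second; the environment's two latent axes load
on the producer groups only (loadings 1.6/1.1 and 1.4/0.9), and groups on
the same level share a noise correlation of 0.3. Latent noise standard
deviations are 1 and 0.6 for axes 1 and 2, keeping the axes separable by
PCA. Species counts are Poisson draws around
$\log \mu_{is} = \mathrm{baseline}_s + \lambda_s^{\mathsf T} x_i$ with 40
species per group, log-normal baselines around 20 counts and loading
spread 0.6; the observed environment table has 13 columns of which four
track the two latent axes and nine are noise.

Design rationale, fixed once: the environment anchoring of the producer
level is the feature that makes causal direction statistically visible in
observational covariance data — in its absence, reversing every path gives
a covariance-equivalent model and no AIC comparison can separate the
regimes. Anchoring the producers (and only them) mirrors the emulated
system, where succession-driven abiotic gradients structure plant
communities directly and higher trophic levels mainly indirectly.
Concentrating trophic transmission on the dominant axis mirrors the
empirical pattern that a community's leading ordination axis carries most
cross-level signal, and keeps the generating structure within reach of a
screen that admits one axis pair per group pair. PCA recovery of the
latent axes from counts plateaus near Procrustes $t \approx 0.9$
regardless of sequencing depth — the residual is the nonlinearity of the
composition transform, not counting noise — so analyses on synthetic data
carry realistic ordination attenuation.

What the generator does *not* emulate: sequencing pipelines and OTU
clustering, spatial autocorrelation, zero inflation beyond what Poisson
sampling produces, gradients in species richness, and any feedback loops
(the generating web is acyclic by construction). Passing tests therefore
show that the pipeline recovers structure *of the kind assumed by the
model*; they cannot validate the causal interpretation on real data.

## Problem sizes used in the test suite

Simulation-backed checks run at reduced replicate counts chosen to keep
the full suite fast while leaving the acceptance thresholds unchanged:
protest null calibration uses 1,000 simulated datasets (KS distance),
chi-square test size 400–1,000 fits at $n = 200$, modification-index null
calibration 300–500 fits, single-omitted-path recovery and null-path
pruning 40–60 seeds, and the direction-recovery experiment 24 seeds per
scenario (20 at null strength) at 27 plots and strength 0.8, with 199
permutations per protest call. Parameter recovery uses one fit at $n = 1000$ plus 120 replicates
at $n = 150$ for interval coverage.

## Known limitations

- The engine fits observed-variable path models only: no latent measurement
  models, no robust or categorical estimators, no missing-data handling.
- The likelihood is normal-theory; site scores of relative abundances are
  bounded and can violate normality in small samples.
- Greedy expansion and pruning find a local AIC optimum, not the best
  subset; with 27 plots the direction comparison is honest but noisy, and
  equivocal outcomes are common even at strong coupling.
- The multiplicity adjustment is Benjamini–Hochberg; the expected number
  of false discoveries ($m\alpha$) is reported alongside as a descriptive
  quantity.
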