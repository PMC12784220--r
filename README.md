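# brainprofiles

Different people can do the same cognitive task equally well with visibly
different brain activation patterns. `brainprofiles` implements an analysis
pipeline for detecting this *many-to-one mapping* in cohort task-fMRI
studies of visual short-term memory (VSTM): it finds groups of brain regions
whose activation covaries across people, strips out a dominant global
responsivity factor, discovers latent participant subgroups from the
residual activation profiles, models continuous-report memory errors with a
circular mixture, and runs the accompanying statistics for comparing and
characterizing the subgroups. A synthetic-cohort generator with planted
ground truth makes every stage testable end to end.

## The models

**Modules from inter-individual covariance.** Given per-subject, per-ROI
contrast estimates \(\beta_{s,r}\) for a memory-load contrast (load 3 vs
load 1), task-responsive ROIs are kept when \(|T_{s,r}| > 1.96\) in at least
10% of subjects. The ROI-by-ROI Pearson correlation matrix across subjects
is partitioned with consensus Louvain community detection: modularity

\[ Q(\gamma) = \frac{1}{2m} \sum_{ij \in \text{same module}}
   \left( w_{ij} - \gamma \frac{k_i k_j}{2m} \right) \]

is locally maximized by greedy Louvain with single-node refinement, 500
stochastic repetitions are assembled into an agreement matrix, thresholded
at a permutation null, and re-partitioned until consensus. The resolution
\(\gamma\) is swept over 1–1.5 (step 0.05) and the partition most similar to
a reference partition by adjusted mutual information (AMI) is selected;
modules with fewer than 15 ROIs are dropped.

**Responsivity residualization.** Per-subject mean activation across all
selected ROIs (*overall responsivity*) is regressed out of each module's
mean activity; the across-subject module mean is added back so values remain
interpretable as activity levels.

**Latent profiles.** The residual module activities plus the responsivity
indicator feed a latent profile analysis: Gaussian mixtures with diagonal
covariances \(\Sigma_g = \lambda_g B_g\) (families EII, VII, EEI, VEI, EVI,
VVI), fitted by multistart EM and selected by BIC and ICL (larger is
better), with a parametric bootstrap likelihood-ratio test for the number of
classes.

**Behaviour.** Continuous-report errors follow a three-component mixture:
von Mises around the target (weight \(p_T\), concentration \(\kappa\)), von
Mises around a non-target (misbinding, \(p_{NT}\)), and uniform guessing
(\(p_U\)). Precision is the inverse circular SD in degrees,
\(\mathrm{SD} = \sqrt{-2\ln(I_1(\kappa)/I_0(\kappa))}\), and items in memory
\(K = \mathrm{load}\times(1 - p_U)\).

**Statistics.** Welch heteroscedastic ANOVA and pairwise Welch t-tests,
chi-squared tests, Benjamini–Hochberg FDR, default-prior Bayes factors (JZS
t-test, g-prior one-way ANOVA, stretched-beta correlation BF), Bayesian
R², age-adjusted partial correlations with Fisher z comparisons between
subgroups, and analytic power for Pearson correlation tests.

## Worked example

```r
library(brainprofiles)

cfg <- pipeline_config(simulation = cohort_config(), seed = 42)
report <- run_pipeline(cfg)

report$selected_gamma
#> [1] 1
report$chosen_G
#> [1] 4
adjusted_mutual_information(report$partition$membership,
  report$truth$roi_module[names(report$partition$membership)])
#> [1] 1
head(report$subgroup_stats[, c("variable", "F", "p", "bf10")])
#>        variable         F           p         bf10
#> 1           age 0.7043525 0.552040786   0.05955824
#> 2           icv 1.3728123 0.256386622   0.08931151
#> 3 mean_kurtosis 7.0628675 0.000283244 105.06387433
```

The simulated cohort plants 5 ROI modules and 4 participant subgroups in
200 subjects. The report shows that consensus module detection recovered the
planted partition exactly (AMI = 1), the latent profile analysis selected
four classes, and the subgroup statistics recover the planted white-matter
(mean kurtosis) subgroup effect — F(3, ·) = 7.06, BH-FDR q < 0.001, BF₁₀ ≈
105 — while age and intracranial volume, which carry no planted subgroup
effect, stay null.

Analytic results print directly:

```r
round(100 * power_correlation(rho = 0.30, n = 12))   # 16  (% power)
round(100 * power_correlation(rho = 0.50, n = 42))   # 93
n_for_power(rho = 0.30, power_target = 0.80)         # 85 participants
bf_correlation(r = -0.07, n = 113, rscale = 1/3)     # 0.281
```

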