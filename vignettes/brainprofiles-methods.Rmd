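---
title: "Methods: modules, profiles, and mixtures in brainprofiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modules, profiles, and mixtures in brainprofiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and scientific background

`brainprofiles` implements a cohort-level analysis of the *many-to-one
mapping* between brain activity and behaviour: the observation that distinct
neural activation profiles can support the same level of task performance.
The pipeline starts from ROI-level tables — per-subject contrast estimates
(betas) and t-values for a memory-load contrast in a visual short-term
memory (VSTM) task, per-trial continuous-report behavioural records, and a
covariate table — and produces: a partition of ROIs into modules defined by
*inter-individual* covariance, residual module activity after removing a
global responsivity factor, latent participant subgroups, behavioural
mixture parameters, and the subgroup statistics connecting them. Voxel-level
processing (first-level GLMs, normalization, diffusion preprocessing) is out
of scope; the package consumes tables such preprocessing produces.

# Module detection from inter-individual covariance

The similarity between two ROIs is the Pearson correlation of their load
contrasts *across participants*: two regions belong together when the
participants who activate one strongly also activate the other strongly.
This is deliberately not temporal connectivity.

**ROI selection.** An ROI enters the network when `|T| > t_threshold`
(default 1.96, a liberal p < 0.05 screen) in at least
`ceiling(min_fraction * n)` participants (default 10%). The threshold is
strict: a t-value exactly at the cut does not count. The magnitude is used
because both increased and reduced activation are of interest.

**Negative correlations.** The correlation matrix before residualization is
dominated by positive entries (the shared responsivity factor loads
positively everywhere), so the default policy zeroes negative weights before
modularity is evaluated; `negative = "keep"` retains them for
sensitivity analyses. This choice is configurable because no single
convention for signed modularity is canonical.

**Louvain with refinement.** `louvain_partition()` is an authored
implementation: greedy local moving (first-improvement under a seeded node
order, with the option of moving a node into a fresh singleton community),
aggregation of communities into super-nodes, and repetition until no gain,
followed by a Kernighan–Lin-style single-node refinement sweep on the
original graph. With a handful of seeded restarts — the algorithm is always
deployed with restarts here, since consensus runs it hundreds of times —
the best solution equals the exhaustive-enumeration modularity optimum on
every graph with eight or fewer nodes we have swept; the test suite
re-checks this property on random graphs each run. A single run can land in
a local optimum, which is precisely why the consensus stage exists.

**Consensus.** Because Louvain is stochastic, `consensus_partition()` runs
it `n_repetitions` times (default 500), forms the co-assignment (agreement)
matrix, and zeroes entries at or below a null threshold before
re-partitioning the agreement graph, iterating until all repetitions agree.
The null threshold is the maximum entry over agreement matrices built from
label-permuted copies of the runs (`null_permutations` of them, default
100). Taking the maximum rather than a quantile is the conservative choice;
the percentile is not pinned down by any convention we know of, so it is
deliberately the strictest one. If thresholding empties the matrix (a
signature of a structureless network), the best-modularity run is returned
rather than erroring, since "no stable modules" is itself a result.

**Resolution selection.** `choose_gamma()` computes a consensus partition
for each γ in 1–1.5 (step 0.05) and selects the γ whose partition maximizes
adjusted mutual information with a reference partition (in simulation, the
planted truth; on real data, an a-priori network atlas). AMI uses the
permutation-model expected mutual information and the arithmetic mean of
the entropies as normalizer — the variant choice matters little in practice
but is stated here because several exist. Modules smaller than
`min_module_size` (default 15 ROIs) are dropped and their ROIs marked
unassigned (label 0).

# Responsivity residualization

Overall responsivity — each subject's mean beta across all selected ROIs —
typically explains the majority of variance in every module. To look beyond
it, each module's mean activity is regressed (OLS, with intercept) on
responsivity across subjects and replaced by residual + module grand mean.
The add-back restores the location information (whether a module was
activated or deactivated overall) without changing any subsequent
inference; residuals are exactly orthogonal to the regressor and the grand
mean is preserved to machine precision. Two readings of "regress out the
mean activity" are possible — per-ROI or per-module; we residualize per
module (that is what enters the profile analysis) and additionally expose
`roi_responsivity_r2()` for the per-ROI variance-explained summary.

# Latent profile analysis

The indicator matrix is `[responsivity, residual module 1..K]`. Latent
profile analysis fits Gaussian mixtures with diagonal covariance
\(\Sigma_g = \lambda_g B_g\) (\(\det B_g = 1\)); restricting to
spherical/diagonal families encodes the assumption that correlation between
modules must be *caused by* subgroup structure rather than modelled within
subgroups. M-steps follow the standard volume/shape decompositions, with
VEI and EVI using alternating closed-form updates of volumes and shape.

Numerical choices:

* **Initialization** is seeded kmeans++-style multistart (default 20
  starts) followed by a short k-means and a soft assignment; this differs
  from the hierarchical-agglomeration initialization some reference
  implementations use, and can land in different local optima. The test
  suite cross-checks the attained log-likelihood against `mclust` on the
  same data and model.
* **Variance floor** of `1e-6` times the pooled per-dimension variance
  prevents singular components; starts whose components empty are discarded.
* **Convergence**: relative log-likelihood change below `1e-8` or 500
  iterations; the EM trace is asserted non-decreasing on every fit.
* **Scores**: `BIC = 2 loglik − n_params log n` (larger is better) and
  `ICL = BIC − 2 × entropy(responsibilities)`, so ICL ≤ BIC always.

The bootstrap likelihood-ratio test simulates `n_boot` datasets from the
fitted null model, refits both class counts on each, and applies the
add-one rule `p = (1 + #{LRTS* ≥ LRTS}) / (n_boot + 1)`; p can never be 0.
Calibration requires symmetric effort: the observed and bootstrap fits must
use the same number of EM starts, otherwise the observed alternative fit
finds better optima than its bootstrap counterparts and the test
anticonservatively inflates.

# The behavioural mixture

Continuous-report response errors mix three sources: imprecise memory of
the probed target (von Mises, concentration κ shared across von Mises
components), misbinding to one of the `load − 1` non-targets (the same von
Mises around each, weight split uniformly), and uniform guessing. Load-1
trials have no non-targets; their misbinding weight is folded into the
remaining components by renormalization. Fits are per subject and per load,
because loads are separate experimental conditions.

EM details: responsibilities are computed per trial over {target, each
non-target, uniform}; weights update as mean responsibilities; κ updates by
Newton inversion of \(A(\kappa) = I_1(\kappa)/I_0(\kappa)\) at the
responsibility-weighted mean cosine of the component-centred errors, capped
at 500 and floored at 0. Three κ starts {1, 4, 16} guard against the
guessing/low-κ ridge; convergence is `|ΔLL| < 1e-6` or 500 iterations. As
κ → 0 the von Mises components coincide with the uniform component and the
weights become unidentifiable (a flat likelihood ridge); the fitter
therefore reports the guessing-only solution (pU = 1, κ = 0) whenever the
full mixture does not beat it by an AIC margin — one log-likelihood unit
per extra free parameter — so near-guessing subjects are labelled as such
instead of receiving arbitrary weight splits.

Summaries: precision is `1 / (circular SD in degrees)` with
\(\mathrm{SD} = \sqrt{-2 \ln A(\kappa)}\); κ = 0 maps to precision 0 by
convention. Items in memory is taken as `K = load × (1 − pU)`. **This
formula is a package convention**: the quantity "number of items stored" is
not computationally pinned down by the model itself, and alternative
definitions exist (e.g. including misbinding weight); with the defaults
used here it yields load-wise means near 0.95 / 1.8 / 2.4, the scale
expected for this task family. The load-1 performance screen
(`screen_load1()`, default 30°) uses the model-implied SD at the fitted κ
rather than the raw mean absolute error, because the model SD is robust to
a handful of guesses.

# The synthetic cohort generator

`generate_cohort()` emulates the structure the pipeline assumes, with
ground truth for every stage:

\[ \beta_{s,r} = a_s L_r + \mu[g(s), m(r)] + u_{s,m(r)} + \epsilon_{s,r} \]

* `a_s ~ N(1, 0.20)`: global responsivity; loadings `L_r ~ U(0.5, 1.5)`
  keep it positively loaded everywhere, qualitatively matching the strong
  module-vs-global correlations seen in real activation tables.
* `μ[g, m]`: subgroup × module mean patterns. The defaults are ±0.5 sign
  patterns, *row-centred* so that every subgroup has the same expected
  overall responsivity — subgroup identity lives in the pattern, not the
  level. This also keeps the within-class covariance of the LPA indicators
  approximately diagonal with homogeneous scale, which is the LPA's own
  modelling assumption.
* `u_{s,m} ~ N(0, 0.20)`: module-level subject effect (the planted
  within-module covariance); `ε ~ N(0, 0.30)` ROI noise. Null ROIs are pure
  noise and are removed by the ROI selection screen in practice.
* t-values are `t_scale × beta` (default 2.0) — a deterministic pseudo-t;
  first-level estimation noise is out of scope.
* Behaviour: per-load mixture parameters with defaults
  (pT, pNT, pU, κ) = (0.95, 0, 0.05, 15), (0.85, 0.05, 0.10, 12),
  (0.72, 0.08, 0.20, 10) for loads 1–3, plus small per-subject jitter on
  the guessing weight. These imply K ≈ 0.95 / 1.8 / 2.4.
* Covariates: age uniform over 18–88 and independent of subgroup by default
  (a planted age effect is available but off, reflecting that subgroup
  structure need not be an age story); intracranial volume with no planted
  effects; a mean-kurtosis summary with an age slope and planted subgroup
  offsets, so the statistics layer has a true positive to find.

No published estimates exist for the within-module inter-subject
correlation magnitudes this generator controls, so the SNR defaults were
fixed once, during design, for testability: strong enough that recovery
failures indicate implementation defects rather than statistical bad luck.
Consequences of this choice: passing recovery tests demonstrates
correctness of the machinery, not that real cohorts of ~100 participants
carry this much signal. The generator also omits several features of real
data — spatial autocorrelation between ROIs, heavy-tailed noise, missing
data, and any dependence between behavioural parameters and brain
subgroups (behaviour and brain structure are planted independently unless
configured otherwise).

# Statistics layer

Standard tests are delegated to base R (`oneway.test` with
`var.equal = FALSE`, `t.test`, `chisq.test` with Yates correction for 2×2
tables to match the environment default, `p.adjust(method = "BH")`); the
test suite verifies each against hand-computed textbook formulas. The
Bayes factors are authored implementations:

* **JZS t-test BF**: Cauchy(0, √2/2) prior on the standardized effect via
  one-dimensional quadrature over the inverse-gamma mixing variable, with
  effective N = n₁n₂/(n₁+n₂) for two samples.
* **One-way ANOVA BF**: g-prior on orthonormal sum-to-zero effect
  contrasts with `g ~ InvGamma(1/2, rscale²/2)` (default rscale 1/2),
  marginalized by quadrature. At k = 2 it matches the JZS t-test BF at the
  corresponding scale to numerical precision.
* **Correlation BF**: stretched symmetric beta prior
  \(p(\rho) \propto (1-\rho^2)^{1/\mathrm{rscale} - 1}\) (default width
  1/3), with the exact sampling density of r (hypergeometric-series
  evaluation) integrated over the prior.

**Reproducibility analysis of the correlation BF.** At the sufficient
statistics r = −0.07, n = 113 with the default width 1/3, this evaluates to
BF₁₀ = 0.281, and an independent Python implementation of the same exact
test (`pingouin`) returns the identical value. Published values near 0.18
for this configuration cannot be produced by this prior at n = 113 for
*any* r (the minimum over r is ≈ 0.26); they are consistent instead with a
wider prior (κ ≈ 1, the uniform stretched beta). The package reports what
the stated default computes.

Power for the two-sided Pearson correlation test uses the bias-corrected
Fisher-z approximation with the critical value mapped from the exact t
threshold; it reproduces 16% at (ρ = 0.30, n = 12), 93% at (0.50, 42), 50%
at (0.30, 42), and a minimum n of 85 for 80% power at ρ = 0.30.

Partial correlations are residual-based (p from t with df = n − 2 − k,
Fisher CI with df n − 3 − k), and subgroup comparisons of correlations use
Fisher z with the covariate count entering both groups' df (k = 1 for age;
k = 0 is available since conventions differ). FDR families follow the
practice of adjusting within a declared family — across the group-level
tests of one module–behaviour pair, and across the pairwise comparisons of
one pair — rather than across everything. The joint decision rule
"FDR-adjusted p < 0.05 and BF₁₀ > 3" is reported as a label, never applied
as a filter. Subgroups below `min_group_n` (default 13) are excluded from
association analyses with the reason logged, reflecting the very low power
(≈16% for a medium effect at n = 12) such groups afford.

# Problem sizes used in the checks

The test suite exercises the pipeline at sizes chosen so the full run
completes comfortably on one CPU while leaving the statistical checks
well-powered: recovery cohorts of 120–200 subjects with 24–60 active ROIs;
consensus with 30–100 repetitions (the 500-repetition default remains the
recommendation for real analyses); LPA selection over G = 1..6 with 6–10 EM
starts; mixture recovery over 100 replicates of 500 trials; LRT calibration
over 200 replicates with 99 bootstrap draws at n = 40, d = 1, capped at 50
EM iterations per fit (symmetrically for observed and bootstrap fits). The
end-to-end synthetic run (200 subjects, 5 modules, 4 subgroups, full γ
sweep) takes about a minute and is bitwise reproducible from its seed: a
single master seed is fanned out to per-stage child seeds by a fixed
counter scheme, so each stage is independently reproducible too.

# Known limitations

* Residualizing K module means on the overall responsivity — essentially
  their own average — induces a compositional negative correlation of order
  −1/(K−1) among the residual indicators within any subgroup. With the
  seven-plus modules typical of real parcellations this is mild, but with
  very few modules (K ≤ 3) it violates the diagonal-mixture assumption
  strongly enough that BIC can prefer an extra class; the module-size
  filter's tendency to keep several modules is protective here.
* Louvain optimality is only verified exhaustively for small graphs; on
  large networks consensus mitigates but does not eliminate local optima.
* The LPA initialization differs from agglomeration-based reference
  implementations; model *selection* agreement was checked empirically, not
  proven.
* `K = load × (1 − pU)` is one of several defensible items-in-memory
  definitions; comparisons of K across studies should confirm the formula.
* The ANOVA Bayes factor uses quadrature where sampling-based
  implementations use Monte Carlo; tolerances are set by the quadrature's
  relative error (~1e-8), but priors beyond the single-factor fixed-effects
  design are not implemented.
* Bayesian R² uses the conjugate noninformative linear model with 4000
  seeded posterior draws; backends with other default priors will differ in
  the third decimal.
* The synthetic generator's SNR is optimistic by design (see above).
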