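---
title: "Latent coupling of risk-factor panels and brain morphology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent coupling of risk-factor panels and brain morphology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(brainpls)
```

## The analysis problem

Cardiometabolic risk factors — abdominal obesity, elevated blood pressure,
dyslipidemia, and insulin resistance — tend to co-occur, and their joint
association with regional brain structure is better captured by one
multivariate mapping than by variable-at-a-time regressions. `brainpls`
implements that mapping as a partial least squares (PLS) *correlation*
analysis: given a subjects-by-regions morphometry block $X$ (cortical
thickness in mm, subcortical volume in mm³) and a subjects-by-variables
clinical block $Y$, both deconfounded and z-scored, the region-by-variable
correlation matrix $R = \mathrm{cor}(X, Y)$ is decomposed by SVD,

$$R = U \, \Delta \, V^{\mathsf T},$$

yielding latent variables: paired covariance profiles $(u_j, \delta_j,
v_j)$. The explained variance of latent variable $j$ is
$\delta_j^2 / \sum_k \delta_k^2$. Subject scores are the projections $XU$
(imaging score) and $YV$ (clinical score). Downstream, the first latent
variable's regional stability map is mediated against cognition and
contextualized against cell-type expression and connectome topology.

Because the cohort data this kind of analysis is usually run on are
access-restricted, the package ships a synthetic-data module that generates
every input with the statistical structure the analysis assumes, with the
planted truth recorded. All tests and the acceptance script run end to end
on these synthetic cohorts; what they demonstrate is therefore the
*correctness and calibration of the machinery* (recovery of planted
structure, valid error rates), not any property of a particular cohort.

## The generative model

`gen_cohort()` draws, per subject, a clinical latent $t_c \sim N(0,1)$ and
an imaging latent $t_i = a\,t_c + \sqrt{1-a^2}\,\eta$. The blocks are

$$Y = \kappa\, t_c v^{\mathsf T} + Z_{\mathrm{conf}} B_c + \sigma E, \qquad
  X_{\mathrm{raw}} = \kappa\, t_i u^{\mathsf T} + Z_{\mathrm{conf}} B_m + \sigma F,$$

with $u, v$ unit-norm loading vectors, coupling $\kappa \in [0,1]$
(default 0.8 in the recovery experiments), residual SD $\sigma$ (default
0.5), and linear contamination by z-scored confounds (age, sex, education,
cohort). Morphometry is emitted on a thickness-like scale
($2.5 + 0.2\,X_{\mathrm{raw}}$ mm) so values are positive before
standardization. Cognition follows the planted mediation chain on
standardized latents, $y = b\,t_i + c'\,t_c + \sigma_y \epsilon$, so the
standardized path coefficients $(a, b, c')$ the estimator should recover
are exactly the generator parameters; setting $a = 1$ collapses $t_i$ onto
$t_c$, the shared-latent model used for PLS recovery experiments.
Missingness is MCAR and confined to the clinical block, matching the
assumption under which k-NN imputation from complete covariates is
recoverable. Confound contamination is exactly linear, so OLS
residualization removes it completely — a property the preprocessing tests
assert.

Choices a scientist should know about:

* With $\kappa = 0.8$, $\sigma = 0.5$, the population correlation between
  the block latent scores is $\kappa^2 / (\kappa^2 + \sigma^2) \approx
  0.72$; recovery tests check the sample value against this closed form.
* Parcel geometry is a mirrored Fibonacci lattice on a per-hemisphere unit
  sphere, scaled to a 100 mm sphere with hemispheres offset ±110 mm in x.
  Smooth maps come from a Gaussian process with exponential kernel
  $\exp(-d/\ell)$ on centroid distances, per hemisphere; $\ell = 50$ mm in
  the calibration experiments, chosen so that nearest-neighbour parcels
  (≈ 30–45 mm apart at 100 parcels/hemisphere) correlate at ≈ 0.4–0.5.
* Connectomes are sampled with edge probability $\propto \exp(-d/\tau)$,
  boosted within planted modules, weights uniform in (0, 1]; expected
  density is calibrated to the request. Expression matrices give every gene
  a smooth noise map and add a shared signal map to the genes of designated
  categories.
* What the generator does **not** emulate: realistic marginal
  distributions of risk factors, site/scanner effects, non-linear confound
  effects, vertex-level data, or geodesic distances (Euclidean centroid
  distances stand in). Passing tests bound the machinery's behaviour under
  the stated model only.

## Preprocessing

Imputation is k-nearest-neighbour with $k = 4$, with donors ranked by
Euclidean distance over the z-scored variables of the *same* risk-factor
group (a missing HDL is imputed from subjects nearby in the lipid block),
ties broken by subject order, and the imputed value the unweighted donor
mean. If a subject's entire group is missing the distance falls back to all
clinical variables, with a warning. Confound residualization regresses each
column on an intercept plus the confounds (education enters as a numeric
ordinal, cohort as binary); it is idempotent and leaves residuals exactly
orthogonal to the confounds. Z-scoring uses the sample SD. Cross-cohort
harmonization (for tests administered differently per cohort) z-scores
within cohort, then once more pooled.

The sensitivity-analysis utilities mirror a case-control design: a
consensus-style binary classification (central obesity plus at least two of
high triglycerides, low HDL, elevated BP or treatment, elevated glucose or
treatment; all thresholds configurable), greedy 1:1 Mahalanobis matching
without replacement in seeded random case order (deterministic and
auditable, with standardized-mean-difference diagnostics), and a per-parcel
group GLM returning the group t-statistic with Benjamini–Hochberg
q-values.

## Inference for the latent variables

**Permutation test.** Subject order of $X$ alone is shuffled, the
decomposition recomputed, and per-latent-variable explained variance
compared with the observed value; $p = (1 + \#\{\mathrm{perm} \ge
\mathrm{obs}\})/(1 + n_{\mathrm{perm}})$, with $n_{\mathrm{perm}} = 5000$
by default. Permuted and observed latent variables are paired **by rank**:
the $j$-th largest permuted explained variance is compared with the $j$-th
observed one. Under the null the ranked statistics are exchangeable, so
LV1's p-value is calibrated (measured type-I error 0.045 at $\alpha=0.05$
over 200 null cohorts, uniform by KS) and later LVs are conservative. The
alternative pairing — Procrustes-rotating each permuted solution onto the
observed clinical vectors before reading off explained variance
(`align = "procrustes"`) — matches LVs by profile instead of rank, but the
rotation spreads permuted singular-value mass across components, leaving
the aligned nulls systematically below the observed maximum; we measured
LV1 rejection of ≈ 0.99 on null data with that statistic, so it is
available but not the default.

**Bootstrap.** Subjects are resampled with replacement jointly from both
blocks ($n_{\mathrm{boot}} = 5000$ by default); each resampled solution
*is* Procrustes-aligned to the original (rotation estimated on the
clinical-side $V$, which has fewer columns and is stabler, applied jointly
to $U$ and $V$) — here alignment is appropriate because the resampled
solution estimates the same population structure and only its
rotation/sign/order is arbitrary. The bootstrap ratio is the original
region weight divided by the bootstrap SD of the aligned weights; it is
z-like, and regions with $|\mathrm{BR}| > 1.96$ are called significant.
Clinical loadings get 95% percentile CIs. Resamples that produce a constant
column are redrawn (at most 10 times, logged).

**Sign convention.** Each latent variable is flipped so its
largest-magnitude clinical weight is positive; flipping the sign of an
input column flips only the matching loadings, never explained variance or
p-values.

**Cross-validation.** 10-fold by default: the decomposition is fit on
training subjects, held-out subjects are projected with the training
singular vectors, and the out-of-sample Spearman correlation of the score
pairs is reported per fold.

## Mediation

`fit_single_mediator()` estimates, on z-scored complete cases, `a` from
`m ~ x + covs`, `b` and `c'` from `y ~ x + m + covs`, and `c` from
`y ~ x + covs`; `ab = a·b` and the OLS identity `ab + c' = c` holds to
numerical precision and is asserted. The indirect effect's CI and p-value
come from a subject-level percentile bootstrap (default 5000 resamples;
two-tailed sign-crossing p with add-one correction); other paths use OLS
t-tests. Covariates default to age, sex, and education (no cohort), and are
left on their own scale (slopes absorb it). Classification: *none* unless
`ab`, `a`, and `b` are all significant; given mediation, *full* if `c'` is
non-significant, *partial* if `c'` stays significant with `|c'| < |c|`
(same-direction shrinkage). Batch mode fits one model per cognition column
with listwise deletion per test and BH-FDR within each path type across
tests (the joint-across-paths alternative is a one-line change in
`mediate_batch()`; within-path was chosen so each path family controls its
own FDR).

Recovery tests feed the estimator the generator's latent scores rather than
PLS-estimated scores: with estimated scores, mediator measurement error
re-routes part of the indirect effect into an apparent direct effect, and
the test would conflate estimator correctness with score attenuation. The
pipeline stage, of course, runs on the estimated scores — and its `c'`
estimates are accordingly attenuation-biased upward relative to the planted
value, which is expected behaviour, not a defect.

## Spatially constrained null models

Parcel maps are spatially autocorrelated, so naive correlation p-values
between two maps are badly anti-conservative (measured false-positive rate
≈ 0.18–0.33 at $\alpha = 0.05$ for independent smooth maps). Three
value-preserving null models are provided; all produce surrogates whose
value multiset equals the original's exactly, so distribution-only
statistics are invariant by construction.

* **Spin permutations** (default n = 1000): one uniform random rotation per
  surrogate for the left hemisphere, its x-mirrored twin for the right;
  parcels are reassigned one-to-one to nearest rotated neighbours (greedy
  with exclusion, in random order). The one-to-one variant was chosen over
  duplicate-allowing nearest neighbour so each surrogate is an exact
  permutation. Spin indices depend only on geometry and seed, so one index
  set can be reused across maps on the same parcellation
  (`spin_perms` argument) — the calibration experiments rely on this.
* **Variogram-matched surrogates**: permute, smooth with a distance kernel
  from a bank of radii (5 radii at the 5th–50th percentile of distances),
  linearly rescale plus a white-noise nugget fitted to the binned empirical
  semivariogram (12 bins to the 60th distance percentile, count-weighted),
  and rank-remap to the original values. The kernel and nugget scale are
  selected on pilot surrogates *by the variogram of the finished,
  rank-remapped surrogate* — the remap compresses the noise contribution
  nonlinearly, so judging candidates before remapping chooses too-smooth
  kernels. Ensemble-mean variograms match the original's to ≈ 6–10% mean
  relative error on well-estimated lag bins, against a ≈ 5% floor set by
  the original's own binned-estimate noise.
* **Spatial-lag surrogates**: maximum-likelihood fit of
  $y = \rho W(d_0) y + \epsilon$ with $W$ row-normalized
  $\exp(-d/d_0)$, profiling over a log-spaced $d_0$ grid anchored at short
  range (from a quarter of the median nearest-neighbour spacing to the
  median distance — percentiles of *all* distances put every candidate at
  cross-hemisphere scales and the fit underestimated smoothness);
  surrogates are $(I - \rho W)^{-1}\epsilon$, rank-remapped. $\rho$ is
  capped at 0.99 for invertibility, with a warning.
* **Degree-preserving rewiring** for connectome-dependent statistics:
  Maslov–Sneppen double-edge swaps on the binary topology with weights
  carried along; binary degree sequence and edge count are conserved
  exactly.

Calibration (asserted in the acceptance suite): for independent pairs of
smooth maps (200 parcels, 50 mm lengthscale), spin and variogram tests
reject at 0.02–0.10 at $\alpha = 0.05$ while the parametric Spearman test
rejects at > 0.15. The empirical p is add-one two-tailed:
$(1 + \#\{|null| \ge |obs|\})/(1 + n)$. The three nulls are reported side
by side and never combined into one decision.

## Contextualization

Degree centrality is the row sum of connection weights, returned as
average-ranks (negative weights are rejected — functional matrices must be
made non-negative upstream). Neighborhood abnormality is
$A_i = \frac{1}{N_i}\sum_{j \in N_i} C_j w_{ij}$ over the $N_i$ connected
neighbours, NA for isolated nodes; it matches a brute-force double loop to
1e-12 in tests. Connectivity gradients use row-wise top-10% sparsification,
cosine affinity (negatives clipped to zero), and diffusion-map embedding
with anisotropic normalization $\alpha = 0.5$ and diffusion time 0
(eigenvectors scaled by $\lambda/(1-\lambda)$); a disconnected affinity
graph is an error naming the components.

Gene-category enrichment (virtual histology): per category, the effect map
is Spearman-correlated with each member gene's map, Fisher-z transformed
(r clipped at $1 - 10^{-7}$), and averaged into $Z(r_{sp})$; the null
recomputes $Z$ on spatial-lag surrogates of the effect map, p is two-tailed
empirical, and BH-FDR runs across categories. The alternative reading of
the procedure — average the category's z-scored gene maps first, then
correlate once — is implemented behind `aggregation = "category_mean"`;
neither is silently preferred, but the gene-wise aggregate is the default
because it matches the aggregate-z statistic reported with this method
family. Planted-enrichment experiments (10 categories × 20 genes, signal in
2) recover exactly the planted categories in ≥ 90% of seeds and flag
nothing on pure noise in ≥ 18/20 seeds.

## Pipeline, workflow shape, and reproducibility

The package is organized as an analysis workflow: numbered drivers under
`analysis/` (simulate → preprocess → PLS → mediation → contextualization →
report) are thin narratives over the package functions, writing tables
under `results/`; `run_pipeline()` chains the same stages programmatically
with stage toggles. All defaults live in `pipeline_config()` (k = 4,
n_perm = 5000, n_boot = 5000, n_spin = 1000, 10 folds, α = 0.05, BR
threshold 1.96). Per-stage seeds derive deterministically from the master
seed and stage name; rerunning a config reproduces every stochastic output
bit-identically (asserted by hashing the output tree). I/O is delimited
text with header rows (empty field = missing) plus JSON for scalar results;
generator truth goes to a separate JSON sidecar, never into data tables.

The demonstration bundle plants the morphometric loading pattern *on the
same smooth map* the signal gene categories express, so the PLS
bootstrap-ratio map is spatially structured and genuinely coupled to
expression; the network statistics (degree, gradients, and — absent
planted propagation — neighborhood abnormality) then act as negative
controls in the demo run, while the acceptance script additionally builds a
network-propagated map to exercise the positive case.

### Problem sizes used in tests

Test and acceptance runs scale the default resampling constants down to
keep the suite quick while leaving each property decidable: recovery
cohorts use n = 2000 subjects, 60 regions, 12 clinical variables with 500
permutations / 200–500 bootstraps; type-I calibration uses 200 null
cohorts of n = 100 with 200 permutations; spatial-null calibration uses
200 map pairs at 200 parcels with 99 surrogates each; enrichment recovery
uses 20 seeds at 100 parcels with 200 surrogates. Package defaults remain
the full-scale defaults.

## Known limitations

* Euclidean centroid distances approximate geodesic distances; vertex-level
  (surface-mesh) spins are out of scope.
* The spatial-lag model family cannot perfectly reproduce a per-hemisphere
  exponential-kernel Gaussian process, so its null is slightly narrow for
  very smooth maps; the enrichment FDR consequently sits near (not below)
  its nominal level in the planted experiments. Spin and variogram nulls do
  not share this limit.
* Permutation p-values for latent variables beyond the first are
  conservative under the rank pairing.
* Mediation is single-mediator, cross-sectional, and makes no causal
  claims; there is no SEM or multiple-mediator support.
* The design is not a general PLS toolbox: no regression-flavoured PLS
  (PLS-R/PLS-DA) and no sparse variants.
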