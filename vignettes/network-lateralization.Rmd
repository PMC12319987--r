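---
title: "Measuring and relating network lateralization with surface areas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and relating network lateralization with surface areas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latnet)
```

## The measure

`latnet` treats hemispheric lateralization of a cortical functional
network as a property of its surface territory. Given an individual's
parcellation — a per-vertex assignment of the cortical surface to
discrete networks — each network $k$ occupies surface areas
$\mathrm{LH\,SA}_k$ and $\mathrm{RH\,SA}_k$ on the two hemispheres, and
its **network surface area ratio** is

$$\mathrm{NSAR}_k \;=\;
\frac{\mathrm{RH\,SA}_k - \mathrm{LH\,SA}_k}
     {\mathrm{LH\,SA}_k + \mathrm{RH\,SA}_k}.$$

The ratio is threshold-free, hard-bounded in $[-1, 1]$, negative when
the network's territory favours the left hemisphere, and exactly
$\pm 1$ when a network exists on a single hemisphere. No scaling factor
is used in the denominator. A network absent from both hemispheres has
no defined ratio and propagates as a missing value — it is never imputed
as 0, which would fake perfect symmetry.

Surface areas are computed from triangulated hemisphere meshes
(millimetres; areas in mm²). Each vertex receives one third of the area
of every incident triangle (the barycentric split). This rule is not the
only possible one — Voronoi-type weights exist — but it is the standard
conservative choice: vertex areas sum exactly to the total face area,
which makes area bookkeeping testable (the package asserts conservation
to 1e-9 relative error, and exact $s^2$ scaling of areas under
coordinate scaling). Degenerate faces contribute zero. Whether partial
vertex areas at label boundaries should be split between adjacent
networks is an open question for any vertex-based area measure; we
assign each vertex wholly to its label, which is what label-based
surface tooling does in practice.

Individual parcellations arrive with arbitrary cluster numbering, so
they are aligned to a reference scheme (by default a 17-network
resting-state taxonomy) with a Hungarian assignment that maximizes
pooled vertex overlap across both hemispheres (`hungarian_match` on the
negated `overlap_matrix`). The cost is vertex-count overlap by default
with an area-weighted option; hemispheres are pooled rather than matched
separately, which guarantees one consistent labeling for the pair. Ties
between equally optimal assignments are broken deterministically (lowest
index first).

## Covariate adjustment and inference

Analyses of who is lateralized and how lateralizations covary operate on
covariate-adjusted values. Per network, raw NSAR is regressed on
mean-centered age (years), mean-centered mean framewise displacement
(mm), sex (0/1) and handedness (Edinburgh Handedness Inventory,
−100..100), and each fitted effect is subtracted as measured from its
covariate's sample mean:

$$\mathrm{NSAR}^{adj}_i = \mathrm{NSAR}_i -
\sum_j \hat\beta_j \,(x_{ij} - \bar x_j).$$

A subject sitting at the sample means keeps its raw value, and the
adjustment is idempotent (re-adjusting changes nothing — the refit
coefficients vanish). Ordinary least squares is used, with no shrinkage;
networks are adjusted independently.

A network is called lateralized when the intercept of that same model is
significant at the Bonferroni-corrected level $\alpha/m$ — for
$\alpha = .05$ and 17 networks, 0.00294, displayed as 0.003 (comparisons
always use the unrounded value). With several datasets the call requires
significance in every dataset with a consistent intercept sign.
Like-lateralized networks are ranked pairwise by stacking the two
networks' values in long format and regressing on a 0/1 network
indicator plus the covariates. The stacking deliberately mirrors the
classical description of this comparison; it ignores the within-subject
dependence of the two stacked rows, so `compare_networks_pairwise`
offers a paired $t$ test as a cross-check (`paired_check = TRUE`), and
its null rejection rate is verified by simulation in the test suite.

The dependent hypothesis — that stronger left lateralization of one
network accompanies stronger right lateralization of another across
individuals — is assessed three ways: the Pearson correlation between
per-subject averages of left- and right-lateralized networks, the full
network-by-network correlation matrix (with Fisher-z intervals; the
$p \ge .05$ display mask affects rendering only, never inference), and
factor models.

## Factor-analytic machinery

The assumption battery and both factor stages are implemented directly:

* **Bartlett sphericity**: $\chi^2 = -(n - 1 - (2p+5)/6)\ln|R|$ on
  $p(p-1)/2$ df.
* **KMO**: marginal versus anti-image partial correlations from
  $R^{-1}$. For any two variables the partial equals the marginal
  correlation, forcing KMO $= 0.5$ — an algebraic identity the tests
  exploit ($r = 0$ is the 0/0 degenerate case).
* **Doornik–Hansen**: variables are standardized, orthogonalized through
  the eigenstructure of their correlation matrix, and the transformed
  skewness and kurtosis statistics are summed into a $\chi^2(2p)$
  statistic. Its size under multivariate normality is checked by
  simulation.
* **VIF**: the diagonal of $R^{-1}$, identical to $1/(1-R^2_j)$ from
  per-variable regressions.
* **EFA**: iterated principal-axis factoring with squared multiple
  correlations as initial communalities, convergence tolerance 1e-6,
  200-iteration cap, Heywood communalities clipped to 1 with a warning.
  Loadings are unrotated (rotation is a separate, optional concern: the
  bipolar one-factor-positive/one-factor-negative pattern this analysis
  looks for is only visible unrotated); per-factor variance proportions
  are each retained eigenvalue over their sum. Retention combines the
  eigenvalue ≥ 1 rule with `parallel_analysis` (95th percentile of
  reduced-matrix eigenvalues from random normal data of matching size).
  Note that principal-axis solutions are determined only up to rotation
  and sign, and a 2-factor model needs at least 6 indicators to be
  identified — recovery tests therefore plant orthogonal loading columns
  on 8 indicators.
* **CFA**: maximum likelihood, minimizing
  $F_{ML} = \ln|\Sigma(\theta)| - \ln|S| + \mathrm{tr}(S\Sigma^{-1}) - p$
  over loadings and log-parameterized residual variances, factor
  variances fixed at 1. $T = (n-1)F_{ML}$, CFI against the diagonal
  independence baseline (same $n-1$ convention), RMSEA
  $= \sqrt{\max(T - df, 0)/(df\,(n-1))}$, SRMR over standardized
  residuals including the diagonal. Optimization runs `nlminb` from two
  starts; the suite cross-checks the minimized discrepancy against an
  independent Nelder–Mead search over the same parameterization.

**CFA identification.** With four indicators on two unit-variance
factors, fixing the factor covariance at zero leaves 8 free parameters
against 10 sample moments, hence 2 degrees of freedom; freeing the
covariance gives df = 1. The zero-covariance constraint is the default
because it is the identification consistent with a reported
two-factor df of 2 for this indicator layout; the free-covariance
variant is available. One caveat is intrinsic to the layout: each
two-indicator block constrains only the product of its two loadings, so
the loading *split* within a block is a likelihood ridge. Fit statistics
(T, CFI, RMSEA, SRMR) are invariant along the ridge; reported loadings
are whatever point the optimizer reaches, and recovery tests plant equal
loadings per factor where the symmetric solution is the meaningful one.

## Reliability tools

`icc_two_session` implements the two-way, single-measures ICC for two
sessions. The default *consistency* form
$(MS_R - MS_E)/(MS_R + MS_E)$ satisfies the identity
$\mathrm{ICC} = (F-1)/(F+1)$ with $F = MS_R/MS_E$ on $(n-1, n-1)$
degrees of freedom; the *absolute agreement* form, which additionally
charges session mean differences, is available via `type = "agreement"`.
Published two-session reliabilities in this literature are consistent
with the consistency form at some decimal roundings and with neither
form at others, so both are provided and the choice is explicit.
Confidence intervals follow the standard F-based construction.

`wilcoxon_signed_rank_exact` computes $V$ (sum of ranks of positive
differences; zeros dropped, ties share average ranks) and an exact
two-sided $p$ as the doubled smaller tail of the distribution of $V$
over all $2^n$ sign assignments. The distribution is built by a
generating-function convolution over doubled ranks — mathematically
identical to enumerating the $2^n$ assignments, exact under ties, and
cheap up to the $n = 25$ cutoff after which a normal approximation with
continuity and tie corrections takes over. Eight all-positive
differences give $V = 36$ and $p = 2/256 \approx .008$, the canonical
worked example, and the suite verifies agreement with literal
enumeration for $n \le 12$.

"Minutes of data" in stability analyses is modeled abstractly: an
increment with more data is an estimate with smaller error variance.
`incremental_stability` correlates each increment against one
independent reference per subject; `split_runs` provides the even/odd,
first/second-half and seeded random schemes used in task-effect
comparisons.

## The synthetic-data generator

Real multi-session fMRI datasets of the relevant scale are
access-restricted, so the package ships a generator whose defaults are
fixed to the study conditions it emulates and are not meant to be tuned
per analysis:

* **Population structure** (`default_simulation_config`): 17 networks;
  3 planted left-lateralized (Language −0.25, Dorsal Attention-A −0.30,
  Default-C −0.15) and 5 right-lateralized (Visual-B +0.15,
  Salience/VenAttn-A +0.10, Control-B +0.25, Control-C +0.15, Limbic-B
  +0.35); residual sd 0.10, giving moderate single-network reliabilities.
  Cross-network covariation comes from two orthogonal latent factors: a
  bipolar factor (left networks negative, right networks positive) and a
  smaller Language-versus-Dorsal-Attention contrast. The bipolar
  loading scale is solved from the implied covariance (by `uniroot`, to
  1e-12) so that the population correlation between averaged left- and
  averaged-right values equals the requested coupling, −0.65 by default.
  `implied_network_cov` and `implied_left_right_cor` expose the ground
  truth.
* **Covariates**: age ~ N(28.5, 3.6) years, sex Bernoulli(0.5),
  Edinburgh handedness a right-dominant mixture (90% N(65, 25), 10%
  N(−40, 30), clipped to ±100), mean FD ~ N(0.08, 0.02) mm floored at
  0.03 — a young-adult, low-motion sample. Covariate effects default to
  zero, matching conditions where no covariate is reliably associated
  with lateralization; effects can be planted per network and are
  applied to centered covariates.
* **Rendering** (`render_parcellation`): network $k$ receives fraction
  $f_k$ of the combined surface area (default $0.9/17$ each, the
  remaining 10% standing in for the medial wall, label 0), split across
  hemispheres as $(1 \mp t_k)/2$ for target NSAR $t_k$. Seeded region
  growing claims unassigned vertices breadth-first, jumping to a fresh
  patch if walled in, and stops at the vertex that minimizes the
  absolute area error. On icosphere subdivision-4 templates (2562
  vertices per hemisphere) one vertex is ~0.4% of a network's area, so
  achieved NSAR sits within ±0.02 of target — and the ±1 endpoints are
  exact because a zero-area target allocates no vertices. Subdivision 4
  is the default template for rendering; the vertex count is far below
  cortical meshes, but NSAR depends only on area ratios, which the
  icosphere represents exactly.
* **Run noise** (`generate_runs`): each run independently reassigns a
  fraction of label-boundary vertices to a neighbouring network,
  emulating run-to-run parcellation instability; label-0 territory is
  untouched.
* **Connectivity** (`generate_connectivity`): a per-network latent
  factor model — vertex loadings $a_v$ with $a_v^2 \sim U(0.3, 0.8)$,
  left/right factors of one network correlated by the homotopy weight —
  yields a positive-semidefinite correlation matrix with graded
  supra-threshold structure, so the autonomy index declines smoothly as
  homotopy rises and vanishes at full homotopy.

What the generator does **not** emulate: BOLD time series, spatial
autocorrelation of parcellation errors, anatomical asymmetries
(Yakovlevian torque, per-hemisphere template differences), distance-
dependent connectivity, or heavy-tailed NSAR distributions. Passing
tests therefore certify the estimators and their calibration under a
clean generative model, not robustness to every property of real
cortical data.

## The autonomy index and its sign

The convergent-validity companion to NSAR is a count-based autonomy
index: per vertex, the fraction of supra-threshold functional
connections (default threshold $r > 0.25$) to the vertex's own
hemisphere minus the fraction to the opposite hemisphere, each
normalized by hemisphere vertex count; per network, the mean over the
network's vertices on both hemispheres. In this orientation the index is
*direction-agnostic*: it grows with hemispheric autonomy whichever
hemisphere hosts the network. Its across-subject correlation with the
*signed* NSAR is therefore negative for left-lateralized networks and
positive for right-lateralized ones — the mixed sign pattern that
functional-connectivity specialization measures display against signed
asymmetry indices, and the pattern the test suite asserts. The
`sign_flip` argument negates the index for comparison with conventions
that orient autonomy the other way; a global flip reverses both signs of
the pattern at once and cannot change which networks correlate
negatively.

## Numerical and interface choices

* Meshes use 1-based vertex indices internally; GIFTI, FreeSurfer and
  OFF readers translate from the 0-based on-disk conventions. Text
  formats print coordinates with 17 significant digits, so parse → write
  → parse is bit-exact; the FreeSurfer binary path is bit-exact on its
  float32 grid.
* Label 0 is reserved for medial wall/unassigned vertices everywhere:
  excluded from every network statistic, dice and overlap computation,
  but included in area-conservation checks.
* All generators take mandatory seeds and restore the caller's RNG
  state; identical seeds give identical output.
* Dice of a network absent from both parcellations is reported missing
  rather than 1 or 0; the overall dice simply omits it.
* Problem sizes in the shipped checks — 300-subject populations,
  subdivision-4 rendering, 100 identification replicates, 2000-replicate
  null calibrations — were chosen as the smallest sizes at which the
  Monte Carlo error of each check is comfortably below its tolerance.

## Known limitations

* The pairwise network comparison inherits the long-format dependence
  caveat described above; use the paired cross-check when in doubt.
* The CFA reports a likelihood-ridge point for within-block loading
  splits (see above); standard errors for loadings are deliberately not
  reported.
* The autonomy index reimplementation fixes one reasonable
  count-normalization and threshold; published variants differ in both,
  so only sign patterns and orderings, not magnitudes, should be
  compared across implementations.
* Hungarian matching assumes the individual parcellation and the
  reference share a label count; merging or splitting clusters is out of
  scope.
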