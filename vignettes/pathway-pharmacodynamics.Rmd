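---
title: "Pathway pharmacodynamics of methylprednisolone: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway pharmacodynamics of methylprednisolone: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paldyn)
```

## The problem

Methylprednisolone (MPL) is a synthetic glucocorticoid whose transcriptional
consequences depend strongly on how it is presented: a single intravenous
bolus clears within hours, while a constant infusion holds the
drug–receptor signal at a new steady state for days.  Time-series
microarray studies in adrenalectomized rats (acute: 50 mg/kg bolus, 17
sacrifice timepoints over 0–72 h, 2–4 animals each, GEO GSE490; chronic:
constant infusion, 11 timepoints over ~7 days, GSE5101) capture these
regimens at the whole-transcriptome level.  `paldyn` analyses such data at
the level of *pathways*: it extracts each pathway's dominant temporal
activity patterns, establishes which are statistically meaningful, and then
asks which mechanistic model of glucocorticoid regulation can reproduce
them — and hence whether a pathway responds transiently, persistently,
with rebound, with tolerance, or by moving to a new steady state.

## Pathway activity levels (PALs)

Expression profiles are replicate-averaged per timepoint and z-scored per
gene (mean 0, sample SD 1 across timepoints; the sample n−1 convention is
used everywhere).  For a pathway with member matrix $X$ (genes ×
timepoints), the SVD $X = U \Sigma V^{T}$ yields right singular vectors
$v_k$ — unit-norm temporal profiles we call pathway activity levels — and
fractional variabilities $f_p(k) = \sigma_k^2 / \sum_j \sigma_j^2$.  A PAL
is a "metagene": the common temporal trend of the pathway's genes.  Two
conventions make the decomposition deterministic:

* replicates are averaged *before* z-scoring and SVD, so a PAL has one
  value per timepoint (the decomposition needs one column per timepoint to
  yield temporal profiles);
* the SVD sign ambiguity is resolved by requiring a non-negative inner
  product with the pathway's mean z-scored profile (ties: first nonzero
  element positive).

### Coverage and significance

A pathway is only interpretable if the dataset represents it.  Fractional
coverage $f_c$ is the fraction of a pathway's genes with measured
profiles; its one-tailed Fisher exact (hypergeometric) p-value is computed
against the universe of unique genes across the whole supplied catalog,
with measured genes intersected with that universe first.  Pathways with
fewer than `min_measured` (default 3) measured members are dropped —
"low-occupancy" pathways give uninformative Fisher p-values; the exact
cutoff is a configuration knob because no canonical value exists.

Each PAL's $f_p$ receives a bootstrap p-value: the null distribution is
built from `n_boot` random gene sets of the same size drawn from the full
filtered dataset, and $p(k)$ is the add-one-corrected fraction of null
draws with rank-$k$ $f_p$ at least as large as observed (so
$p \in [1/(n_\text{boot}+1), 1]$).  A pathway is *significant* when its
coverage p-value is ≤ 0.05 and its leading PAL is significant at 0.05.

**Why leading ranks, sequentially.**  A pathway exposes as many ranks as
timepoints, and each rank's null p-value is approximately uniform.
Declaring a pathway significant when *any* rank fires would inflate the
pathway-level false-positive rate to several times the nominal level (we
observe 30–40% on null data at α = 0.05).  `paldyn` therefore tests ranks
sequentially from rank 1 and stops at the first non-significant rank —
the standard way of testing leading singular components.  The
pathway-level false-positive rate then equals the calibrated rank-1 rate,
and "total $f_p$" sums a prefix of dominant PALs, which is also what the
published total-activity fractions (40–90%) look like.

### Bootstrap ensembles and clustering

To propagate replicate variability into PAL space, every gene's timepoint
value is resampled from a normal distribution about its replicate mean
with its replicate SD (timepoints with one animal fall back to the gene's
pooled SD across timepoints), the decomposition is re-run, and the leading
significant PALs are retained; the default is 1000 bootstraps, as in the
original studies.  For efficiency the significance gate reuses one null
$f_p$ distribution computed from the original dataset rather than nesting
a fresh null inside every bootstrap — the null describes random gene sets
of the dataset, which the bootstrap perturbation does not change
materially.

Retained profiles are clustered with k-means (k-means++ seeding, 20
restarts, best inertia).  The cluster number is chosen by the gap
statistic with `B = 50` uniform reference sets drawn over the data's
PCA-aligned bounding box (the variant recommended by the statistic's
authors), picking the smallest $k$ with
$\mathrm{Gap}(k) \ge \mathrm{Gap}(k{+}1) - s_{k+1}$; `k_max` defaults
to 4.  Profiles are compared by Euclidean distance on the sign-aligned,
unit-norm vectors, so SVD scale and sign are not nuisance dimensions.
Each cluster is reported as its centroid with per-timepoint member SD —
the error band around PAL profiles.

## The mechanistic models

### Pharmacokinetics

Two-compartment model with plasma and tissue amounts $A_p, A_t$:

$$\frac{dA_p}{dt} = k_0 + k_{21} A_t - \left(k_{12} + \frac{CL}{V_p}\right) A_p,
\qquad \frac{dA_t}{dt} = k_{12} A_p - k_{21} A_t,$$

with $A_p(0)$ the bolus amount (acute: 50 mg/kg, $k_0 = 0$) or $k_0 > 0$
for constant infusion.  The free drug concentration driving the receptor
is $C_{MPL} = 0.43\,A_p / V_p$.  Published parameter values are built in:
acute $CL = 3.48$ L/(h·kg), $V_p = 0.73$ L/kg, $k_{12} = 0.98$,
$k_{21} = 1.78$ 1/h; chronic $k_0 = 220$ mg/(kg·h), $CL = 5.61$,
$V_p = 0.82$, $k_{12} = 0.32$, $k_{21} = 0.68$.  The tabulated chronic
$k_0 = 220$ mg/(kg·h) is used verbatim although the nominal infusion is
0.3 mg/(kg·h); the source tables are internally consistent with their
receptor-model units, so we adopt the printed value and note the
discrepancy rather than resolve it.  Units are carried as printed
throughout; the contract is internal consistency of trajectories, not
absolute unit correctness.

### Receptor dynamics

The glucocorticoid receptor cascade (receptor mRNA $R_m$, free cytosolic
receptor $R$, cytosolic complex $DR$, nuclear complex $DRN$):

$$\frac{dR_m}{dt} = k_{s,Rm}\Big(1 - \frac{DRN}{IC_{50,Rm} + DRN}\Big) - k_{d,Rm} R_m$$
$$\frac{dR}{dt} = k_{s,R} R_m + R_f k_{re} DRN - k_{on} C_{MPL} R - k_{d,R} R$$
$$\frac{dDR}{dt} = k_{on} C_{MPL} R - k_T\, DR, \qquad
  \frac{dDRN}{dt} = k_T\, DR - k_{re} DRN$$

with $k_T$ the translocation rate into the nucleus and $k_{re}$ the loss
rate out of it (the tabulated definitions; the narrative description of
$k_{re}$ in the source is self-contradictory and the table is taken as
authoritative).  Initial conditions are the drug-free steady state —
$R_m(0) = k_{s,Rm}/k_{d,Rm}$, $R(0) = k_{s,R} R_m(0) / k_{d,R}$,
$DR(0) = DRN(0) = 0$ — so with no drug every state is constant, which the
tests assert exactly.

### PAL regulation models

Receptor-mediated (an indirect-response model driven by $DRN$):

$$\frac{dPAL}{dt} = k_s\Big(1 \pm \frac{DRN}{IC_{50,PAL} + DRN}\Big) - k_d\, PAL,
\qquad PAL(0) = k_s / k_d.$$

Biosignal-mediated (a delayed transduction $BS$ opposing the direct
effect, producing rebound / tolerance / new steady states):

$$\frac{dBS}{dt} = k_e (DRN - BS)$$
$$\frac{dPAL}{dt} = k_s (1 \pm S\,DRN)\Big(1 \mp \frac{BS^{\gamma}}{IC_{50,PAL}^{\gamma} + BS^{\gamma}}\Big) - k_d\, PAL.$$

The ± signs are pathway-specific and never tabulated in the source, so
they are explicit enumerated parameters and the fitting stage tries all
variants (both receptor signs, all four biosignal sign pairs).  A useful
closed form guides test construction: with $\gamma = 1$ and
$S = 1/IC_{50}$, the chronic steady state satisfies
$(1 + S d)(1 - d/(IC_{50}+d)) = 1$ for any $DRN$ steady state $d$, i.e.
the pathway returns exactly to baseline despite sustained drug — the
canonical *tolerance* construction.

### Numerics

No ODE-solver package is assumed; the integrator is an adaptive
Dormand–Prince RK45 in compiled code with rtol 10⁻¹⁰ / atol 10⁻¹² by
default (fitting uses 10⁻⁸/10⁻¹⁰).  The system's stiffness ratio is
modest ($k_T = 58.1$ vs $k_{d,R} = 0.0403$ 1/h, ≈1.4·10³), so an adaptive
explicit method meets every stated accuracy contract — the acute bolus
solution matches a matrix-exponential closed form to better than 10⁻⁶
relative — at negligible cost; an implicit method would buy nothing here.
The PK forcing of the receptor system uses the exact biexponential
solution of the linear PK system (diagonalized in R), so no interpolation
error enters the receptor simulation.

## Fitting and classification

Fitting minimizes the residual sum of squares between the model trajectory
and a cluster centroid through three stages, each seeded with the previous
stage's best point: bounded simulated annealing (with internal restarts),
compass pattern search, then a bound-constrained quasi-Newton polish
(L-BFGS-B standing in for SQP, which has no installed implementation).
Rates and IC50 are searched in log₁₀ space; default bounds span the
published parameter magnitudes by about ±2 decades (rates
$[10^{-4}, 10^{2}]$ 1/h, $IC_{50} \in [10^{-2}, 10^{4}]$,
$\gamma \in [0.5, 10]$, $S \in [10^{-6}, 1]$).  Stage budgets (2000 SA
evaluations, 1000 pattern-search evaluations by default) are configuration
knobs; several independent chains are run and the best kept, because the
biosignal objective has secondary local minima (a fast-equilibrium basin
with jointly inflated $k_s, k_d$).  The RSS trace across stages is
non-increasing by construction and asserted in the tests.

**Identifiability.**  PALs are unit-norm singular vectors with arbitrary
scale and sign, while the ODE models produce absolute activity levels, so
an affine map $a \cdot PAL_\text{model} + b$ is estimated jointly with the
parameters.  The model output is exactly linear in $k_s$ (including its
initial condition), so $k_s$ is profiled out by separable least squares;
with a free affine map $k_s$ is absorbed into $a$ entirely and reported
as 1.  Parameter-recovery tests therefore fix the map
(`affine = "none"`), which restores identifiability of $k_s$; recovery
from noiseless self-generated centroids is then exact to well under 5%.

**Model choice.**  Candidates are ranked by RSS with a parsimony rule
standing in for the original visual inspection: the receptor-mediated
model is preferred when its RSS is within 10% of the best
biosignal-mediated RSS *or* within 0.1% of the centroid's total sum of
squares (fits that close are visually indistinguishable; the simpler
mechanism wins ties — without the absolute tolerance the ratio test
becomes a coin flip on optimizer noise when both models fit essentially
exactly).

**Response taxonomy.**  With baseline $b_0 = PAL(0)$,
$\text{peak} = \max_t |PAL - b_0|$ and $\text{end} = |PAL(T) - b_0|$, the
deterministic rules are, in order: *tolerance* if the regimen sustains the
drug and end < 0.1·peak; *new steady state* if end ≥ 0.25·peak and the
trajectory is flat at the horizon (|slope|·horizon ≤ 0.05·peak);
*rebound* if after the primary extremum the trajectory crosses baseline
and reaches ≥ 0.2·peak on the opposite side; *transient* if the regimen is
a bolus and end < 0.1·peak; otherwise *persistent*.  A flat trajectory is
persistent with a zero-effect flag.  The thresholds (0.1, 0.25, 0.2, 0.05)
are configuration constants: the source defines the classes verbally only.
All rules are ratios of deviations, so labels are invariant to affine
rescaling of the trajectory.

## The synthetic-data generator

The generator states the world the tests live in: signal genes are
$g_i(t,r) = \text{loading}_i \cdot PAL_\text{true}(t) + \varepsilon$ with
i.i.d. Gaussian replicate noise, loadings uniform on [0.5, 1.5] with an
optional anti-correlated fraction; null genes are pure noise; and
`simulate_incoherent_genes()` adds genes with independent random temporal
profiles — active by any differential-expression filter but sharing no
structure, which is the correct null pool for PAL significance.  Default
time grids are the printed designs (17 points over 0–72 h, dense in the
first 12 h; 11 points over 0–170 h); replicate counts are drawn from 2–4
(acute) or 3–4 (chronic) as in the animal studies.  The replicate noise SD
defaults to 0.1 — about 10% of the unit-scale trajectory amplitude, a
realistic spread for z-scale microarray replicates; the source reports no
within-timepoint variances, so this default is a free parameter and is
*not* calibrated to GSE490/GSE5101.

What the generator does *not* emulate: probe-level artifacts,
normalization, batch effects, platform differences between the acute and
chronic arrays, or gene–gene correlation beyond the single shared
trajectory.  A green test establishes that the machinery recovers a known
world of this shape — not that the biological conclusions of any
particular dataset are correct, and not the published dataset-level counts
(51/61 covered, 49/61 significant, 29 common), which depend on the real
arrays and a specific KEGG snapshot and are out of desk-scale reach by
construction.

## Degenerate inputs and edge policies

Constant genes (zero temporal SD) cannot be z-scored and are dropped with
a warning; a constant gene never passes the F-filter.  Pathways with fewer
than two measured members raise an insufficient-coverage error.  Empty
k-means clusters trigger re-seeding, then a reduction of `k` with a
warning.  ODE failures inside the fitting objective return a large penalty
and the stage continues.  All randomness is funneled through explicit
seeds (one per stage in the pipeline, derived from the master seed), and
the RNG state of the caller is always restored.

## Known limitations

* The EDGE time-course filter of the original work is replaced by a plain
  one-way ANOVA F-test across timepoints — deliberately simple plumbing.
* The exact bootstrap scheme of the original supplementary material is
  unavailable; the random-gene-set null is one defensible reading of
  "bootstrapping of the original gene set".
* Only single-bolus and constant-infusion regimens are modeled; no
  absorption models, no inter-animal variability.
* Model selection reports an RSS ranking with a parsimony rule; no formal
  information criteria or parameter uncertainty are provided.
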