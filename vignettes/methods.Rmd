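---
title: "Models, numerical choices and limits of the four-proxy pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, numerical choices and limits of the four-proxy pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what each model
assumes, which tunable parameters matter, what the synthetic generators do
and do not emulate, and where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## The inference problem

Diet leaves several partially independent signatures on a bird's skeleton:
overall body size, the geometry of the pedal claws, the lever arms of the
jaw, and the strain a jaw section accrues under a standard muscle load.
None is decisive alone. The pipeline therefore treats each proxy as a
source of *exclusions* (categories a measurement renders implausible) and
*rankings* (discriminant posteriors over categories), and synthesises them:
the permitted set is the complement of the union of exclusions, ranked by
mean normalised posterior; an exclusion always outranks a high posterior,
but the conflict is logged with provenance rather than silently dropped.

Diet categories are defined by threshold percentages of the diet
(`diet_cutoffs()`, shipped as editable JSON): e.g. invertivores need 90%
invertebrates at the strict "standard" level and 60% at the relaxed
"semi-specialist" level; generalists have no category above 30% (40% semi).
Thresholds are read inclusively (90+% means ≥ 90). Mechanical subcategories
(hard/medium/soft invertebrates; hard/soft fruit; husking/swallowing
granivory) come from annotations, not percentages, because they reflect
food material properties rather than proportions. Before classification,
ectotherm and endotherm tetrapod percentages are merged and any unknown
vertebrate percentage is split evenly between fish and tetrapods.

## Phylogenetic machinery

Time trees carry branch lengths in Ma; fossils are grafted at stated stem
ages with tips terminated at their oldest occurrence, unstated divergences
spaced 0.01 Ma apart (recursively for polytomies, in input order), and the
result rescaled linearly where a fixed total depth (94 or 131 Ma) is
required. Grafting near-simultaneous divergences makes the Brownian
covariance `C` ill-conditioned, so the inverse square-root factor used by
the permutation test is computed by eigendecomposition with an eigenvalue
floor of 1e-12.

Signal statistics follow the K family: the ratio of raw to C⁻¹-weighted
mean squared deviations from the phylogenetic mean, normalised by its
Brownian expectation, so K = 1 under Brownian motion — exactly 1 on an
equal-branch star tree for any non-constant trait, which the tests assert.
The multivariate form sums both quadratic forms over trait columns and
reduces to K for one column (asserted to 1e-10 over 50 random instances).
Significance uses tip shuffling, not residual rotation, matching the
published univariate test; p-values carry (count+1)/(nperm+1) smoothing so
the smallest reportable p is 1/(nperm+1).

The pairwise group comparison ("phylogenetic HSD") transforms data and
design by the C^(-1/2) factor, computes group least-squares means, and
builds the null by permuting intercept-only residuals and refitting
(residual randomisation). 1000 permutations are the default by convention.
Calibration is verified empirically: type-I error at α = 0.05 over 200 null
replicates must lie in [0.02, 0.08], and power must rise monotonically with
effect size.

## Claw and skull geometry

Claw curvature is the central angle of the unique circle through the three
outer-curve landmarks — a deterministic chord-and-arc construction chosen
because the source measurement (an on-screen angle tool) is not otherwise
specified. If the circumradius exceeds 1e6 × chord, the claw is treated as
straight (0°, with a warning) rather than erroring: effectively straight
ground-bird claws exist. Arc length is radius × angle; the seven analysis
variables are the four angles plus three arc-length ratios to a reference
digit (DIII by default; DIV available, and the change-of-reference identity
between the two is asserted exactly).

The six jaw indices are ratios of straight-line distances and areas on a 2D
lateral geometry, so all are invariant to rigid motion and uniform scale
(asserted). Open choices, resolved and recorded: the adductor line of
action is *required as two input points* (never inferred from images);
skull length is the projection extent onto a declared long-axis vector
(chord length would differ for curved skulls); the occlusal equilibrium
line for AO is the rostral–cranial chord offset by the arclength-projected
mean signed deviation of the occlusal polyline — the unique offset at which
the area ventral of the line balances the gap dorsal of it — with a
per-taxon flag reversing the offset direction for recurved bills; recessed
teeth are excluded from the occlusal polyline by the caller; and ACH uses
the outer outline area with holes *ignored* by default (the configuration
with the stronger predictive power), with hole subtraction behind a flag
for sensitivity work.

## Body mass

The mass regression is a fixed published linear model on six log10 skeletal
measurements with a correction factor near 1. Two things are deliberately
explicit configuration rather than hidden assumptions: the fitted mass unit
(`unit_to_g`; the source fit's unit is not restated here) and the interval
half-width on the log10 scale (default log10(1.25), a stand-in calibrated
so mean/lower ratios are ≈ 1.25, since the source error model is not
restated either). Guild cut-points on log10 mass maximise the Youden index
J = sensitivity + specificity − 1 over all midpoints between consecutive
distinct values; *all* maximisers are returned because real datasets
produce ties. Mass-band exclusion rules: vertivory excluded when the upper
bound is below 300 g, invertivory when the lower bound exceeds 450 g,
folivory/frugivory below 250 g, granivory/nectarivory above 400 g; ranges
straddling a band exclude nothing.

## Plane-strain finite elements

Jaw sections are meshed with constant-strain triangles under plane strain
(mm / N / MPa; strains reported ×1e6). CSTs were chosen for transparency;
their discretisation error is bounded empirically instead of hidden: the
uniform-traction patch test must be exact to 1e-9, a slender cantilever
must match Timoshenko beam theory within 5% at a fine mesh, and halving the
element size must change MWAM strain by under 2% *at the operating
resolution of ~12 elements through the jaw depth* (`target_h = 0.25` on the
30 mm synthetic jaws). Coarser meshes are used in tests that only compare
models against each other, where discretisation error cancels in the
ordering.

Constraints are applied by elimination (exactness of the patch test): the
articular pin fixes both translations and the bite point is fixed along a
stated direction — implemented by rotating that node's degree-of-freedom
pair into the constraint frame, so the whole model can be rigidly rotated
and principal strains remain invariant to 1e-8 (asserted). The muscle is a
single resultant force at the attachment node, 45° from the coronal plane
by default; distributing it over a segment is a known refinement not
implemented. Loads scale from a 6 N reference by F ∝ √area: in a
unit-thickness 2D model stress scales as force/length and area as length²,
so the square-root rule holds the strain state constant across
geometrically similar models — verified to 1e-8 by the similarity oracle.
The exponent is exposed in configuration because the source scaling
equation is cited, not restated.

No constrained-triangulation library is available in the target
environment, so meshing uses a structured strip mesher for x-monotone
outlines (lateral jaw profiles are height fields over the long axis); the
dorsal band occupying 20% of local thickness is labelled rhamphotheca by
element centroid. Non-x-monotone polygons are rejected rather than meshed
badly.

## The intervals method and compositional handling

A strain field is summarised as the percent of model area in each of n
equal strain intervals over a range shared by *all* compared models
(computing a per-model range would make profiles incomparable; the solver
enforces this by erroring on out-of-range strains). Strain fields use the
magnitude convention (|max principal strain|), so the range starts at 0.
Profiles are compositions: zeros are replaced by the mean of a lognormal
fitted to the column's nonzero entries (method of moments on logs),
truncated above at the column detection limit — guaranteeing every imputed
value is positive and below the smallest observed nonzero — followed by
multiplicative re-closure to 100. The source replacement estimator is
cited, not restated, so the *contract* (positivity, sub-detection-limit,
closure) is what the tests enforce. The analysis matrix is the ilr
transform in the sequential-binary-partition pivot basis (any orthonormal
basis gives the same distances; the clr–ilr isometry is asserted to 1e-10);
clr is used only for interpreting weightings. The interval count is chosen
by convergence: the smallest candidate whose inter-model distance matrix
correlates ≥ 1 − 0.01 with the next candidate's — the package's
formalisation of an informally described convergence test, with constant
distance vectors treated as perfectly concordant when identical.

## Ordination, discriminants, agreement

PCA uses the correlation matrix (unit-variance inputs, removing units);
axis signs are fixed by making the largest-magnitude loading positive.
Fossils are standardised by the *training* mean/sd and rotated — they never
influence the fit. LDA uses Fisher axes from the W⁻¹B eigenproblem and
Gaussian posteriors under the shared covariance; priors default to training
class proportions (matching common tooling defaults) with uniform priors a
flag, because the original choice is not stated. Singleton groups are
rejected by design (they warp discriminant spaces); a singular pooled
covariance — expected when ilr interval data have more columns than group
members — triggers a small ridge (1e-8 × trace/dim) with a warning. DAPC
feeds the first n PCs (default: 99% variance, configurable) into the same
LDA; with all PCs it must reproduce plain LDA exactly, which is asserted on
20 random datasets. Agreement between an a-priori classification and
discriminant predictions uses the two-rater (Cohen) kappa form; the
literature this follows names Fleiss while using a two-rater workflow, and
the package implements the two-rater form rather than guessing.

## What the synthetic generators emulate — and what they do not

Each generator is a deterministic function of (configuration, seed), with
guild-level constants in one auditable place (`synth_calibration()`):

* **Trees**: pure-birth (Yule) conditioned on tip count, rescaled to 94 Ma
  — realistic imbalance without downloads; no extinction, no rate shifts.
* **Traits**: multivariate normal with covariance σ²C plus additive guild
  effects plus iid noise. Default guild effects sit at the vertices of a
  regular simplex separated by 4 within-guild sds
  (`guild_trait_effects()`): clearly recoverable planted structure, the
  regime a planted-structure test is meant to exercise (comparable to the
  ≥ 0.95 reclassification-kappa tier asserted for well-separated guilds).
* **Masses**: lognormal per guild with means at the reported guild
  averages (invertivores 75 g, vertivores 1426 g, folivores 1537 g,
  frugivores 259 g, granivores 45 g, nectarivores 36 g) and a common log10
  sd of 0.45 back-derived from the printed ranges read as roughly ±3 sd.
  With equal sds the analytic density crossing between invertivores and
  vertivores is the log-midpoint, ≈ 327 g. The recovered Youden cut-point
  is tested as the *mean* over 20 independent n = 2000 cohorts against
  that crossing (within 5%), because a single cohort's empirical maximiser
  scatters ~10%: J is flat near its optimum.
* **Claws**: exact three-point arcs with guild-centred curvature (ground
  birds ≈ 40°, raptors ≈ 100°) under random rigid placement — so recovery
  is exact by construction; no allometry, no digit-specific ecology.
* **Jaws**: x-monotone profiles whose depth/length ratio is drawn per
  guild — deep for strong-jawed guilds (granivores that husk, folivores),
  slender for weak-jawed guilds (most invertivores, piscivores). Deeper
  sections have larger second moments of area, so under √area load scaling
  strong-guild MWAM strain falls below weak-guild MWAM in the large
  majority of paired draws (asserted at ≥ 80%).
* **Diet tables**: constructive inverses of the classifier — each row is
  built to meet its label's cut-off, and the round trip is asserted for
  all 13 categories at both specialist levels.

A green test on this world establishes that the machinery is correct and
that planted structure of the stated magnitude is recovered; it does *not*
establish that real skulls and claws separate this cleanly, that guild mass
distributions are lognormal with equal spread, or that anatomical shape
variation reduces to an aspect ratio. The generators target statistical
structure, not anatomy.

## Known limitations

* The FE model is 2D, single-resultant-load, suture-free, and comparative
  only: absolute bite forces and failure predictions are out of scope.
* The mass interval half-width is a stand-in, not a refit of the source
  regression's error model.
* The consensus rule set formalises a narrative synthesis as
  exclusion-union plus posterior-mean ranking; judgment-call arguments can
  be encoded as explicit rules but none are hard-coded. TM (pedal) verdicts
  contribute soft evidence only and never exclusions by default.
* The classifier exclusion floor (posterior < 0.05) is a configuration
  choice with no published value behind it.
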