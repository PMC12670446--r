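---
title: "Methods: geometric-morphometric phenotype scoring of 3D facial shape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric-morphometric phenotype scoring of 3D facial shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoscore)
```

## The problem

Skeletal dysplasias such as achondroplasia produce a recognizable facial
gestalt — midface hypoplasia, a depressed nasal bridge, frontal bossing.
When a therapy acts on the underlying growth biology, a natural question is
whether the face measurably shifts toward normative morphology over the
course of treatment. morphoscore answers this with dense homologous 3D
landmarks: every scan is a $k \times 3$ configuration in which landmark $j$
corresponds anatomically across scans (in practice produced by nonrigid
atlas registration; registration itself is outside this package's scope).

The pipeline has five stages: bilateral symmetrization, generalized
Procrustes alignment, a principal-component shape space with a data-driven
retained dimension, a regression-derived phenotype axis with normalized
projection scores, and two inferential procedures — a paired multivariate
test of overall shape change, and a longitudinal mixed model of score
change under treatment.

## Superimposition and symmetrization

Configurations are compared in shape space: centered, scaled to unit
centroid size ($\mathrm{CS} = \sqrt{\sum_j \lVert x_j - \bar x \rVert^2}$),
and rotated onto a consensus by generalized Procrustes analysis (GPA). Each
iteration re-centers and rescales every configuration to unit size, rotates
it onto the running consensus (proper rotations only — reflections are
forbidden so a mirror-image face can never be silently matched), and
updates the consensus until its root-mean-square movement falls below
$10^{-8}$ (at most 100 iterations; hitting the cap sets a flag rather than
erroring). Keeping every configuration at exactly unit size each iteration
is a deliberate choice over partial-Procrustes variants; the resulting
coordinates are dimensionless.

Faces are bilaterally structured, and asymmetry is mostly noise for this
analysis, so each configuration is symmetrized before alignment: reflect
about the sagittal plane ($x = 0$ by convention — template builders and
readers must place the midline there), swap left/right labels to restore
homology, align the reflected copy back onto the original by ordinary
Procrustes superimposition, and average the two pointwise. The pairwise
alignment uses translation and rotation **only**: reflection is an
isometry, so there is no scale to recover, and allowing scale would shrink
the reflected copy toward the original (the optimal Procrustes scale is
below 1 whenever two shapes differ), breaking the fixed-point property.
With rotation-only alignment the operation is numerically idempotent and
symmetric inputs are exact fixed points — both are verified in the test
suite on random asymmetric configurations. Whether the original/reflected
pair should instead be aligned jointly to a grand consensus is genuinely
underdetermined; pairwise alignment was chosen because it makes each scan's
symmetrization independent of the rest of the sample.

## Shape space and component retention

Aligned configurations are flattened to $3k$-vectors and decomposed by
covariance PCA (coordinates share units after unit-size scaling, so
correlation PCA would be wrong). No tangent-space projection is applied
before the PCA: facial shape variation at this scale is small, the
distinction is numerically minor, and we prefer the simpler, documented
choice.

The retained dimension is chosen by Horn-style parallel analysis: a
component is kept if its eigenvalue exceeds the 95th percentile of the
matching eigenvalue from reference data with no correlation structure, and
the retained count is the largest $m$ such that components $1..m$ all
pass. The default reference permutes each variable independently across
samples (100 draws), which preserves every marginal distribution exactly; a
Gaussian reference with matched per-variable SDs is available via
`reference = "normal"`. Permutation nulls are conservative for weak
secondary structure — variance concentrated in the first components
inflates the permuted spectrum — so the retained count can shed a little
mass from directions of interest; this is a known limitation discussed
below. The pipeline floors the retained count at 2 so downstream
multivariate statistics remain defined.

## The phenotype axis and its scores

On the pooled untreated controls (normative plus affected; treated scans
are excluded from this fit), each retained PC score is regressed on

$$ s = \beta_0 + \beta_1 a + \beta_2 a^2 + \beta_3 a^3 + \beta_4\,\mathrm{sex} + \beta_5\,\mathrm{group} + \varepsilon $$

with age $a$ centered at the pooled control mean (raw centered polynomials,
not orthogonal ones — the simplest faithful cubic), sex coded 0/1 and group
coded 0 = normative, 1 = affected. The vector $v$ of group coefficients
across PCs is the **phenotype axis**: the displacement from the age- and
sex-adjusted normative mean to the affected mean.

A scan with PC scores $s$, age $a$ and sex $x$ is scored against its own
normative prediction $\hat\mu_0(a, x)$ (the model with group set to 0):
$r = s - \hat\mu_0(a, x)$, raw projection $= r \cdot v / \lVert v\rVert$,
and **normalized score** $= r \cdot v / \lVert v\rVert^2$. The double
division fixes the score's scale: the normative mean scores 0 and a scan
displaced by exactly the axis scores 1, so the affected control mean sits
at 1 by least-squares construction. Scores are additionally expressed in
SDs of the affected-control scores (for plotting against that cohort's
spread), and — if the affected controls show a significant linear age trend
at level $\alpha$ — treated scores are residualized with the control
regression coefficients before longitudinal modelling; otherwise they are
passed through unchanged and the non-significant test is reported.

Per-vertex heatmap fields decompose the same quantity locally: with
$d_j$ the scan's displacement at landmark $j$ from its normative
prediction and $v_j$ the landmark-space axis there, the vertex score is
$(d_j \cdot v_j)/\lVert v_j\rVert^2$, zeroed where
$\lVert v_j \rVert \le \varepsilon \lVert v \rVert / \sqrt{k}$
($\varepsilon = 10^{-3}$, configurable) to avoid dividing by locally absent
signal. The $\lVert v_j\rVert^2$-weighted mean of the vertex scores equals
the global normalized score — an algebraic identity (the out-of-basis part
of $d$ is orthogonal to $v$'s basis expansion) that the suite checks for
every scan of a synthetic study. This local decomposition is a reasoned
construction; its aggregation identity is self-imposed, not inherited.

## Inference

**Paired multivariate test.** First-vs-last visit change in the treated
group is tested with a paired Hotelling $T^2$ restricted to the leading
$p$ PCs (by default $\min(13,\ n-1)$ — with 14 subjects a 13-dimensional
test is the most the design supports, giving the $F(13, 1)$ reference its
single denominator degree of freedom). $T^2 = n\,\bar d^\top S^{-1} \bar d$
with $S$ the $n-1$-denominator covariance of the paired differences and
$F = \frac{n-p}{p(n-1)} T^2 \sim F(p,\, n-p)$. No covariance shrinkage is
applied; the caller caps $p$ instead.

**Longitudinal mixed model.** Treated scores are modelled with
`lme4::lmer` by maximum likelihood:

$$ \mathrm{score}_{it} = \beta_0 + \beta_1\,\mathrm{protocol}_i + \beta_2\,t_{it} + \beta_3\,\mathrm{protocol}_i \times t_{it} + u_i + \varepsilon_{it} $$

where $t$ is years from first dose (negative for pre-dose visits of
placebo-first subjects, which are retained in the model) and $u_i$ is a
per-subject random intercept. The treatment-time effect is tested by a
likelihood-ratio $\chi^2$ with 1 df against the same ML fit without the
time main effect; protocol and the interaction are tested by single-term
deletion likewise. One subtlety matters: the protocol indicator and the
interaction are entered as explicit numeric columns, because with factor
coding R re-expands `protocol:time` into per-protocol slopes whose span
absorbs a deleted `time` main effect, making the test vacuous. Whether the
1-df test should instead delete time together with the interaction is
exposed as `drop_interaction_with_time`.

## The synthetic cohort generator

Real registered facial scans cannot ship with a package, so validation
rests on a generator whose ground truth is known exactly. The template is a
jittered half-ellipsoid point cloud — the analysis needs homology and
bilateral structure, not anatomy — with paired landmarks mirrored exactly
across $x = 0$ and midline landmarks on the plane. Effects are smooth
displacement fields: i.i.d. Gaussian noise smoothed by a Gaussian distance
kernel over the template, symmetrized under the bilateral map (group
effects must not create asymmetry), orthogonalized against the template's
similarity tangent directions (translations, infinitesimal rotations,
scaling — any such component would be absorbed by Procrustes alignment,
making part of the injected effect unrecoverable *by construction*), and
scaled to a prescribed RMS magnitude.

Each scan is the template plus additive effects — cubic age growth, sex,
the group displacement for affected and treated subjects, a per-subject
random smooth offset, a treatment displacement along the group axis
proportional to years on drug, and i.i.d. coordinate noise — followed by a
random similarity acquisition transform (uniform rotation, translation in
$[-10, 10]^3$, scale in $[0.5, 2]$) that the alignment stage must undo.
Because treatment acts along the group axis only, the true score is linear
in time on drug, matching the mixed model's assumption; placebo-first
subjects' pre-dose scans receive no treatment displacement but keep their
negative time covariate.

Default design (the validation study used throughout): $k = 60$ landmarks
(25 pairs + 10 midline), 200 normative and 96 affected cross-sectional
controls with ages uniform on 3–16 y, and 14 treated subjects at 7 visits
0.5 y apart, 4 of 14 on the placebo-first protocol (first dose one year
in), first-visit ages $\sim \mathcal N(5, 1)$. Effect magnitudes: group
RMS 0.08 vs coordinate noise SD 0.01 (a clearly expressed gestalt), sex
RMS 0.03, per-subject offset SD 0.03 (individual facial variation of the
same order as the sex effect), small cubic growth coefficients
(0.02, −0.002, 10⁻⁴ per y, y², y³), and a treatment slope of −0.05
normalized-score units per year, which over a ~3-year follow-up moves a
treated face a sixth of the normative–affected distance. For mixed-model
calibration, `simulate_score_table()` generates scores directly under the
model's own data-generating process with subject-intercept SD 0.3 and
per-visit SD 0.1 — substantial session-to-session score variability is a
documented feature of real repeated facial scans, and these magnitudes make
the 14 × 7 design's power moderate rather than trivial.

What the generator does **not** emulate: registration error structure
(spatially correlated, expression-dependent), missing or excluded scans,
measurement-protocol differences between cohorts, and non-additive or
non-linear shape effects. Passing tests therefore demonstrate correctness
of the estimators under the stated model, not robustness to those
real-data complications.

## Numerical choices

- GPA: tolerance $10^{-8}$ on consensus RMS movement, max 100 iterations,
  consensus initialized at the first configuration (order affects outputs
  only up to a global rotation; pairwise shape distances are invariant,
  which the suite checks).
- OPA uses the SVD solution with the determinant sign corrected so the
  rotation is always proper.
- The axis regression solves all PCs jointly through one QR decomposition;
  rank deficiency is reported with the offending design column, and an
  exactly zero group contrast raises a degenerate-axis error rather than
  returning a direction of length 0.
- Hotelling with all-zero differences returns $T^2 = 0$, $p = 1$ without
  touching the (singular) covariance; otherwise a singular covariance is an
  error advising fewer dimensions.
- Zero-variance score tables give infinite log-likelihoods in both nested
  LMM fits; the NaN difference is reported as $\chi^2 = 0$.

## Problem sizes used in validation

The shipped tests validate at the default study scale: a full 394-scan
study end to end (about half a minute), axis recovery over 20 simulated
cohorts of 100 + 100 controls, parallel-analysis rank recovery over 50
seeds of a 100 × 60 rank-5 signal, Hotelling size over 2000 simulated
14-pair studies, and mixed-model bias/coverage over 200 and size over 2000
simulated score tables of the 14 × 7 design.

## Known limitations

- Parallel analysis with permutation nulls is conservative for secondary
  structure; on cohorts with rich individual variation it retains a small
  basis that can shed a few percent of the phenotype axis. When the axis
  itself is the object of interest, fit it on a larger basis and let the
  retention rule govern only exploratory decomposition.
- The score is a one-dimensional summary along the control contrast; shape
  change orthogonal to the axis is invisible to it by design (the paired
  Hotelling test is the complementary, less specific instrument).
- Landmarks are treated as exchangeable coordinates; no surface geometry,
  semilandmark sliding, or missing-landmark imputation is provided.
- The mixed model fits a random intercept only; random slopes are not
  supported (with 14 subjects they are rarely identifiable anyway).
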