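# morphoscore

Regression-based phenotype scoring of dense 3D facial landmark shape.

Conditions that disturb craniofacial growth — achondroplasia is the
motivating case — produce a recognizable facial gestalt. Given dense
homologous landmark configurations (one `k × 3` matrix per scan, with
landmark *j* anatomically corresponding across scans) and per-scan
metadata (subject, group, age, sex, treatment timing), morphoscore
quantifies *how strongly each face expresses that gestalt* and whether the
expression changes under treatment. It is aimed at quantitative
craniofacial researchers working with registered surface scans; the
nonrigid registration that produces the landmarks is out of scope.

## The method

1. **Symmetrization + superimposition.** Each configuration is averaged
   with its reflected, label-swapped copy after Procrustes alignment, then
   the sample is superimposed by generalized Procrustes analysis at unit
   centroid size (proper rotations only).
2. **Shape space.** Covariance PCA of the aligned coordinates; the
   retained dimension is chosen by Horn-style parallel analysis
   (permutation reference, 95th percentile).
3. **Phenotype axis.** On untreated controls, each retained PC score is
   regressed on `1 + age + age² + age³ + sex + group` (age centered, group
   0 = normative / 1 = affected). The group-coefficient vector **v** spans
   the age- and sex-adjusted normative and affected means.
4. **Scores.** A scan with PC scores *s* is scored against its normative
   prediction μ̂₀(age, sex): with *r = s − μ̂₀*, the normalized score is
   *r·v / ‖v‖²*, so the normative mean scores 0 and the affected mean
   scores 1. Per-vertex fields *(dⱼ·vⱼ)/‖vⱼ‖²* decompose the same score
   locally for heatmaps; their ‖vⱼ‖²-weighted mean equals the global score.
5. **Inference.** First-vs-last treated shape change: paired Hotelling
   T² on the leading PCs, F = (n−p)/(p(n−1))·T² ~ F(p, n−p). Score change
   on treatment: `lme4` linear mixed model
   `score ~ protocol + time + protocol:time + (1 | subject)` (ML), with
   the time effect tested by a 1-df likelihood-ratio χ².

A synthetic cohort generator with exact ground truth (bilateral template,
smooth symmetric effect fields, cubic growth, per-subject offsets, a
treatment slope along the group axis, and random acquisition similarity
transforms) backs every validation claim.

## Worked example

```r
library(morphoscore)

cfg <- study_config(cohort = cohort_spec(seed = 42))
report <- run_study(cfg)
report
#> Phenotype-scoring study report
#>   scans: 394, retained PCs: 5 (90.3% variance)
#>   mean normalized score by group:
#>     achondroplasia  1.000
#>     normative       0.000
#>     treated         0.950
#>   Paired Hotelling T2 = 1078 on 14 pairs, 5 dims: F(5,9) = 149.2315, P = 0.0000
#>   LMM time effect: chi2 = 146, df = 1, P = 1.445e-33, b = -0.0436 /y
#>   artifacts: /tmp/.../demo
```

The default simulated study has 200 normative controls, 96 affected
controls and 14 treated subjects at 7 half-yearly visits. Reading the
output: the affected and normative control means sit at exactly 1 and 0 on
the normalized score (the axis construction guarantees this on the fitting
sample); treated subjects average 0.95, pulled below the affected mean by
treatment; the paired Hotelling test sees the (simulated) strong
first-to-last shape change; and the mixed model estimates a score change of
−0.044 per treated year (truth: −0.05), decisively nonzero (χ² = 146,
df = 1). `report$axis`, `report$scores` and the written artifacts
(`scores.csv`, `inference.json`, per-subject heatmap PLYs) expose every
stage; `axis_recovery_cosine(report)` compares the fitted axis with the
generator's injected one.

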