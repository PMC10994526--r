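---
title: "Eigenbrain covariance decomposition: models, conventions and design"
author: "eigenbrain authors"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Eigenbrain covariance decomposition: models, conventions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`eigenbrain` implements a covariance-decomposition analysis of FDG-PET
brain images: preprocessing, participant-by-voxel SVD ("eigenbrains"),
Horn's-method component retention, voxel-wise group Z maps, eigenbrain
score-to-phenotype regressions, meta-analytic spatial decoding, and
eigenvalue-based multiclass linear discriminant diagnosis, together with a
fully specified synthetic-cohort generator. This vignette is the package's
own account of the model, every tunable that matters, the numerical
conventions, and the reasoning behind the genuinely open design choices.
It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

# The decomposition model

Let $x_i(v)$ be subject $i$'s uptake at voxel $v$ on a shared template
grid. Preprocessing divides each image by its mean over a reference region
(the pons, a region relatively spared in dementia), removing the
multiplicative global-uptake nuisance, and smooths with an isotropic
Gaussian kernel (default FWHM 6 mm; $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2}\,\cdot\,\mathrm{voxel\ mm})$ voxels).

Each masked image vector is then *robust-scaled*,
$\tilde x_i = (x_i - \mathrm{median}(x_i)) / \mathrm{IQR}(x_i)$, and the
rows are stacked into the participant-by-voxel matrix $X$. The thin SVD
$X = U D V^\top$ yields:

* **eigenbrains** (rows of $V^\top$): orthonormal, *bipolar* spatial
  patterns — each opposes a relatively hypometabolic pole to a relatively
  hypermetabolic pole; they describe relative metabolism at the cohort
  level, not hypometabolism per se;
* **scores** ($U D$, the per-subject "eigenvalues" in this literature):
  signed expressions of each pattern; a positive and a negative score
  describe opposite polarity of the same pattern;
* **percent covariance**: component $k$ explains
  $100\, d_k^2 / \sum_j d_j^2$. Because "percentage of absolute variance"
  admits a second reading, `pct_covariance(type = "absolute")` also
  reports $100\, d_k / \sum_j d_j$; the squared share is the default.

Two conventions make results bit-reproducible:

* **Sign**: pattern directionality is mathematically arbitrary, so every
  eigenbrain is flipped to make its maximum-|loading| voxel positive, with
  the matching score column flipped in step; flips are recorded.
* **Voxel order**: masked voxels are enumerated lexicographically, first
  array axis fastest (R's column-major order).

**Column centering.** The decomposition performs only per-image
centering/scaling; voxel-wise (column) centering is off by default and
exposed as `svd_decompose(column_center = TRUE)`. A consequence worth
knowing: without column centering the score columns are exactly
*orthogonal* vectors, but their Pearson sample correlations are small
nonzero numbers (the left singular vectors have nonzero means); with
column centering the sample correlations are exactly zero. The package's
independence claims are therefore stated, and tested, as orthogonality.

# Component retention: Horn's parallel analysis

Factoring should stop when a component explains no more variance than
chance-structured data of the same dimensions. The null model permutes
each row's entries independently — preserving every subject's value
distribution while destroying spatial covariance — `n_null` times
(default 100, minimum 20), and records the null spectra. Retention is the
longest *contiguous prefix* of components whose observed $d_k^2$ exceeds
the 95th percentile (configurable) of the corresponding null $d_k^2$:
stopping at the first failure mirrors the sequential logic of the rule
and avoids retaining a late component on a chance excursion.

# Group contrast maps

Z maps compare a patient group against controls matched for sample size,
age and sex. Matching is deterministic: within each sex stratum, patients
are visited in subject-id order and greedily take the nearest-age unused
control, ties broken by smallest control id.

The map itself is computed in two modes because the construction "group
mean images scaled by their respective standard deviation" is ambiguous:

* `ratio` (default, the literal reading):
  $Z(v) = m_a(v)/s_a(v) - m_b(v)/s_b(v)$ — antisymmetric in the groups and
  invariant to rescaling either group;
* `standardized_difference` (the conventional control-referenced effect
  size): $Z(v) = (m_a(v) - m_b(v))/s_b(v)$ — *not* antisymmetric unless
  the two SDs agree, which is why it is not the default.

SDs use the $n-1$ denominator. Voxels where either group SD falls below
$10^{-8}$ are zeroed and counted (`excluded_voxels`) rather than erroring:
synthetic masks legitimately contain constant voxels (e.g. the reference
block). Maps are purely descriptive; no cluster inference is attempted.

# Phenotype links

Scores are linked to outcomes by one model per outcome, with **no
multiple-testing correction** — estimates are reported with raw p-values,
and readers should treat the table as descriptive. Predictors (and, for
linear models, the outcome) are z-scored inside the model so that
"standardized beta" and "odds ratio per SD of score" are well-defined;
the source analyses report standardized coefficients without defining the
standardization, so the package fixes one. Covariates (age, sex) are not
included by default — the upstream description is silent on them — but the
design matrices are plain, so callers can extend them.

Logistic links report convergence trouble explicitly: a `status` field
distinguishes `ok`, `non_convergence`, and `separation` (detected from
fitted-probability warnings or implausibly large coefficients) instead of
emitting silent numbers.

Levene-type heteroscedasticity tests default to median centering (the
Brown-Forsythe variant) for robustness; chi-squared tests are Pearson
without continuity correction, with a warning on small expected counts.
Cognitive composites average the available scaled scores per domain
(scaled-score convention: population mean 10, SD 3), except the Wisconsin
Card Sorting Test and Trail Making Test B, which always pass through as
singleton domains. CSF biomarker banding uses p-tau cutoffs 54/58 pg/ml
and ATI cutoffs 0.8/1.2 with strict inequalities at the band edges
(values on an edge are borderline); PET positivity is strictly greater
than 1.42 (amyloid SUVR) and 1.29 (tau SUVR). When the two CSF bands
disagree the combined call is *borderline* with both sub-bands reported —
the sources state no combination rule, so the package picks the
conservative one.

# Linear discriminant diagnosis

`fit_lda()` is the classical shared-covariance Gaussian discriminant:
class means, pooled within-class covariance ($n - C$ denominator), priors
defaulting to class proportions (overridable to uniform), and axes from
the generalized eigenproblem of between- versus within-class scatter —
always $\min(C-1, \mathrm{rank})$ of them, so four diagnostic groups over
nine score features give exactly three. The default report is
**resubstitution** accuracy: the upstream analysis describes no
cross-validation, so the package reproduces that convention and offers
`cv_lda()` (stratified k-fold) as a clearly separate extension.

Two variants address heteroscedastic, non-normal scores:

* **signed log**: $y = \mathrm{sign}(x)\ln(1+|x|)$ — monotone, odd, fixes
  zero; chosen because scores are signed and a plain log is undefined for
  half of them;
* **robust**: minimum covariance determinant (MCD) location/scatter per
  class with support fraction $\lfloor 0.75 n\rfloor$, pooled by class
  size. MCD needs more observations than features per class; classes that
  are too small (e.g. a 7-member class with 9 features) are a loud error
  rather than a silent fallback, because no principled estimate exists
  there.

`analytic_gaussian_accuracy()` evaluates the *expected* accuracy of a
univariate equal-variance LDA exactly: the discriminant functions are
lines in the feature, their upper envelope is resolved by the convex-hull
trick into one winning interval per class (low-prior classes can be
swamped and win nowhere), and accuracy is the prior-weighted probability
mass each class's own normal places on its interval. A Monte-Carlo twin
(`simulate_gaussian_accuracy()`) implements the same rule by simulation
and serves as its cross-check.

# The synthetic-cohort generator

The generator defines the package's study conditions: a 4-group patient
cohort (default sizes 52/30/7/28) plus 117 controls on an 18×22×18 grid of
6 mm voxels (~5100 brain-mask voxels), with `k_true = 3` planted patterns.
Masked voxel values are

$$x_i(v) = g_i\,\bigl(b + \textstyle\sum_k \ell_{ik} p_k(v) + \varepsilon_i(v)\bigr),$$

with constant baseline $b = 1.2$ (uptake relative to the reference
region), per-subject global scale $g_i \sim U(0.8, 1.2)$, unit-norm
orthonormal bipolar patterns $p_k$ (smoothed white-noise fields,
Gram-Schmidt orthogonalized, zero over the reference block), loadings
$\ell_{ik} \sim N(\mu_{g(i),k}, 0.5^2)$, and voxel noise
$\varepsilon \sim N(0, 0.05^2)$. The reference block is exactly $g_i b$,
so pons normalization removes the global scale *exactly*, not just in
expectation. Ages are drawn per group from the published per-group
age-at-scan means/SDs, with onset derived by subtracting a truncated
normal disease duration so onset ≤ scan always holds; control ages come
from the patient mixture (age matching) and sexes reproduce the patient
sex ratio. Cognition follows linear links mapped to the scaled-score
convention (mean 10, SD 3 in controls); behavioural flags are Bernoulli
through a logistic link; biomarker values centre on the published
per-group medians with availability following the published collection
rates. One RNG stream is seeded once per cohort and consumed in a fixed
documented order, giving bit-identical outputs per seed (including across
changes of the global-scale interval, which is mapped from raw uniforms by
hand so the stream never shortcuts).

**Identifiability by construction.** The default group-mean matrix is not
hand-picked: it is the solution (computed once, hard-coded) of three
simultaneous constraints — (i) the loading columns are orthogonal under
cohort-size weights with distinct second moments (2.0/1.2/0.7), (ii) all
four patient groups share one loading-vector norm, and (iii) the
qualitative ordering holds (component 1 highest in bvAD, component 2 in
dAD, component 3 higher in dAD/aAD than bvFTD, controls at zero).
Constraint (i) matters because an SVD can only recover individual
patterns, rather than an arbitrary rotation of their span, when subject
loadings are uncorrelated across components with separated variances.
Constraint (ii) matters because the per-image IQR scaling shrinks
high-signal images more; if one group carried a systematically larger
loading norm, that scaling would re-weight the groups and re-introduce
correlation. With equal norms it acts as a uniform scalar on patients
(controls, having no mean signal, contribute nothing to the between-group
moment).

**What the generator does *not* emulate.** The baseline is spatially flat,
so the synthetic images lack the dominant shared-anatomy component real
cohorts have (which is why column centering is not needed here); there is
no scanner point-spread anisotropy, attenuation, partial-volume effect, or
longitudinal change; noise is white before smoothing; and the planted
patterns are smooth random fields, not anatomically plausible networks.
Passing tests therefore demonstrate that the *pipeline* recovers known
structure under its stated assumptions — not that real-patient topography
would be recovered, and no claim about real cohorts (component counts,
coefficient values, topographies) is made or tested.

# Numerical conventions

* Quantiles (median, IQR) use linear interpolation between order
  statistics (R type 7) everywhere.
* A flat image (zero IQR) is an error naming the subject, at
  normalization, matrix construction and projection alike.
* Smoothing uses half-sample symmetric reflection at volume edges, applied
  to the full volume *before* masking; the 1-D operator is symmetric with
  unit row sums, so constants and total mass are conserved exactly. The
  kernel is truncated at 4 sigma.
* The pipeline order is normalize → smooth → scale; smoothing commutes
  with the global scale, so the order of the first two steps only matters
  through the reference-mean estimate.
* Greedy component alignment maximizes |Pearson r| without reuse;
  control matching breaks age ties by smallest subject id; LDA prediction
  ties break toward the first class in level order (measure-zero events).
* Grid mismatches (dims, voxel size, affine) are hard errors with a diff
  report; nothing is resampled. Registration is assumed done upstream.

# Problem sizes used by the tests

The suite exercises two scales, chosen as the package's own test design:
structural and invariance checks run on a down-scaled cohort (10×12×10
grid, 30 patients + 20 controls), while every recovery-strength claim
(Horn retention across 20 seeded cohorts, eigenbrain alignment,
LDA-versus-baseline margins, noise-degradation monotonicity) runs at the
full default conditions — 234 subjects on ~5100 mask voxels — with 30
permutation replicates per Horn run (the function's floor is 20; the
package default stays 100). Null-calibration simulations use 2000 replicates with
50 subjects per group and a 3×4 contingency design, sizes at which the
asymptotic reference distributions of the Levene and Pearson chi-squared
statistics are uniform at Kolmogorov-Smirnov resolution.

# Known limitations

* Varimax or other rotations, sparse/nonnegative factorizations, and
  cross-cohort embeddings are out of scope.
* Z maps are descriptive; no voxel-wise inference is provided.
* The robust LDA intentionally refuses under-sized classes instead of
  shrinking or regularizing; users with tiny classes should reduce the
  feature count first.
* Missing cognitive data are dropped per model, never imputed; raw
  neuropsychological scores are assumed already age-adjusted.
* NIfTI support covers 3-D volumes on one grid; dynamic frames and
  resampling are not handled.
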