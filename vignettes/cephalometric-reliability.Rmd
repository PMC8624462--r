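---
title: "Measuring the reliability of 3D cephalometric landmarking"
author: "cephrr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the reliability of 3D cephalometric landmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cephrr)
```

## The problem

Three-dimensional cephalometric analysis of craniofacial CT scans
requires two ingredients: named anatomical landmarks located in image
coordinates, and a reference frame — almost always anchored on the
Frankfort Horizontal (FH) plane — in which clinically meaningful
anteroposterior, transversal and vertical measurements can be read off.
Both ingredients are produced by human operators, so both inherit human
variability. `cephrr` quantifies that variability with the
variance-component machinery of gauge repeatability & reproducibility
studies (ISO 5725), applied to a 33-landmark catalog spanning
conventional cephalometric points, skull-base and facial foramina, and
dental points.

Two questions drive the design. First, per landmark and axis: how large
is the dispersion when the *same* operator repeats an annotation
(repeatability, `s_r`) and when *different* operators annotate the same
scan (reproducibility, `s_R`)? Second, at the level of derived
quantities: even if the FH-defining landmarks are individually noisy,
are *vertical measurements* taken against an FH plane still reliable —
and is a proposed alternative plane that replaces porion with the
internal acoustic foramen (IAF) actually parallel to the conventional
one?

## The measurement model

One annotation of landmark $\ell$ on subject $j$ by operator $i$ in
session $k$ is modelled per axis as

$$ y_{ijk} = m_{j} + B_{i} + e_{ijk}, \qquad
   B_i \sim N(0, \sigma_L^2), \quad e_{ijk} \sim N(0, \sigma_r^2), $$

with $m_j$ the subject's true coordinate, $B_i$ a *persistent* operator
bias (the ISO "laboratory effect": constant across subjects and
sessions) and $e_{ijk}$ independent session noise. The estimators in
`rr_components()` follow the ISO 5725-2 scheme with operators as
laboratories and subjects as levels, pooled to one record per landmark
and axis:

* each operator-by-subject cell contributes its within-cell variance
  $s^2_{ij}$ with weight $n_{ij}-1$, giving the pooled repeatability
  variance $s_r^2$;
* for each subject observed by at least two operators, the variance
  $s^2_{d,j}$ of cell means across operators estimates
  $\sigma_L^2 + \sigma_r^2/\bar n$; averaging over subjects and
  subtracting $s_r^2/\bar n$ (truncated at zero, pre-truncation value
  kept in diagnostics) gives $s_L^2$;
* $s_R^2 = s_r^2 + s_L^2$.

On balanced designs this is algebraically identical to the one-way
ANOVA mean-squares solution, which the test suite verifies to 1e-10
against an independent `lm()`/`anova()` oracle. With cells missing, the
weighted pooling degrades gracefully: singleton cells still inform cell
means (hence $s_L$) but not $s_r$; subjects seen by a single operator
contribute nothing to $s_L$.

Results are reported the way this literature reports them: as 95%
confidence intervals equal to $2 s_r$ and $2 s_R$ in mm (a single value,
not an interval pair), classified as *acceptable* (≤ 1 mm), *useful*
(1–2 mm) or *caution* (> 2 mm) on the worse of the two. The boundaries
are inclusive. Statistical indices such as intraclass correlations are
deliberately not offered; they conflate subject heterogeneity with
measurement error and are a poor fit for landmarking reliability, which
is why this field prefers the SD-based reporting together with modified
Bland-Altman plots (deviation of each repetition from the subject mean,
limits at $\pm 2 s_R$).

### Sample size

`sample_size(A, n)` returns
$\mathrm{round}\!\left(z^2 / (2 A^2 (n-1))\right)$, the approximate
number of subjects needed so the estimated R&R standard deviation from
$n$ repetitions per subject has 95% relative uncertainty $A$. Rounding
is to the *nearest* integer, not the ceiling: with $A=0.15$, $n=6$ the
unrounded value is 17.07 and the canonical answer is 17. This choice is
deliberate and documented here because the two conventions disagree for
such borderline values.

## Geometry

`build_fh_frame()` constructs the subject frame from right porion, left
porion and left orbitale: origin at mid-porion, $x$ from right to left
porion, $z$ along the FH-plane normal, $y = z \times x$, giving a
right-handed left/posterior/superior triad. Two conventions needed
fixing where common practice is silent:

* **Normal orientation.** Nothing in the three defining points
  distinguishes superior from inferior. The frame takes a
  `superior_hint` vector, defaulting to scanner $+z$ (CT patient frames
  conventionally point $+z$ toward the head). When the hint is withheld
  (`superior_hint = NULL` in `fh_frames()`), the sign is chosen so that
  the subject's mean Menton — unambiguously below the FH plane — gets a
  negative $z$ coordinate. A hint orthogonal to the plane normal is an
  error, not a guess.
* **Degeneracy.** Three points spanning a triangle of area
  ≤ 1e-6 mm² produce an error rather than an arbitrary plane.

Two distinct plane constructions are used downstream, mirroring the two
uses in practice: the *mean* FH plane per subject (6-repetition mean
landmarks, after outlier removal) defines the reorientation frame and
the parallelism analysis; *session* planes (that operator's raw points)
define the vertical measurements, so that vertical R&R reflects the
whole per-session construction chain. Vertical measurements are
*signed* distances; absolute values would fold sign noise near zero
into a bias, and are taken only in cohort summaries of the IAF
distances, which are genuinely bounded away from zero.

The angle between planes is $\arccos |n_a \cdot n_b|$ in degrees — an
absolute dihedral angle in $[0^\circ, 90^\circ]$, symmetric and
invariant under common rigid motion.

## Outlier screening

The screening is automated where the original practice was "inspection
plus the standard's recommendations":

1. **Gross rule (removes data).** An observation farther than
   `gross_mm` from the componentwise cross-operator median of its
   landmark/subject group is flagged. The median over six repetitions
   cannot be dragged by a single gross error, so this rule is
   deterministic and has, by construction, zero false flags when noise
   is an order of magnitude below the threshold. The default is
   `gross_mm = 5` mm: about ten standard deviations above the noisiest
   per-axis SD the simulator emulates (~1 mm), yet comfortably below
   the ≥ 8 mm landmark-confusion errors this rule exists to catch
   (a mistaken anatomical definition displaces a point by several mm,
   not fractions of one).
2. **Grubbs test (removes data).** Per subject/landmark/axis, the
   operator cell means (computed after gross exclusion) are tested with
   Grubbs' single-outlier statistic at `grubbs_alpha = 0.01`; a
   significant cell is flagged whole. With only three operators the
   test has little power (the statistic's maximum barely exceeds the
   1% critical value), which is the statistically honest behaviour —
   three laboratories cannot convict one of themselves with confidence.
   Strata with fewer than three cells are skipped and logged.
3. **Mandel h/k (advisory).** Between-operator ($h$) and
   within-operator ($k$) consistency statistics with their ISO critical
   values are reported for inspection but never remove data by default.

`apply_outlier_report()` marks flagged observations `outlier_removed`;
every downstream statistic works on the surviving observations only,
and the pipeline logs each removal with its rule and statistic.

## The simulator

`simulation_truth()` + `simulate_annotations()` generate complete
studies from the same model the estimators assume, plus the geometry
the estimators do *not* assume:

* **Template.** A synthetic 33-landmark adult craniofacial layout
  (porions 65 mm apart, FH plane within ~2° of axial, dental landmarks
  inferior-anterior). Design values, not measured data — chosen only to
  satisfy anatomical ordering constraints.
* **Subject variation.** A mirror-symmetric shape component
  (`subject_sd`, default 3 mm; bilateral pairs move together,
  reflected) plus a small independent asymmetric component
  (`asymmetry_sd`, default 0.5 mm). The split matters: purely
  independent offsets would make simulated skulls far more asymmetric
  than real ones and inflate the angle between the two FH planes well
  beyond clinically reported magnitudes (the inter-orbital line then
  tilts out of the FH plane by ~1–3°). With the default split the
  cohort mean absolute inter-plane angle lands in the 2–3° range with
  a cant draw of half-normal SD 2.4°.
* **Operator bias.** Drawn once per operator/landmark/axis, shared
  across subjects and sessions (a per-subject-varying bias is a
  possible extension but off by design: the ISO model presumes a
  persistent laboratory effect). Bias and session noise are drawn in
  the subject's anatomical frame — where the anisotropy of manual
  landmarking error is meaningful — before the random rigid pose
  (rotation ≤ 10°, translation ≤ 30 mm by default, so scanner $+z$
  remains a valid superior hint; larger poses exercise the Menton
  fallback).
* **Controlled cant.** The IAF pair is projected onto the conventional
  FH plane and lifted along its normal by $d \tan(\theta)$, $d$ being
  the distance of mid-IAF behind the inter-orbital line. In a perfectly
  symmetric anatomy this realizes the dihedral angle $\theta$ exactly;
  residual asymmetry (Or-R off the conventional plane) perturbs it, so
  the truth records the *realized* angle — the actual noise-free angle
  of that anatomy — rather than the drawn $\theta$. Recovery tests
  compare against the realized value.
* **Outliers.** Arbitrary (operator, session, landmark, subject)
  offsets added last, in scanner coordinates.

`paperlike_scenario()` packages the study conditions this package was
built around: 20 subjects × 3 operators × 2 sessions, anisotropic
per-landmark SDs reproducing the characteristic reliability ranking
(orbitale/porion poor along x, gonion along y/z, B point along z,
dental landmarks tight), `sigma_L = 0.7 * sigma_r`, half-normal cant
(SD 2.4°), and the historical gross-error episode: both mental foramina
displaced 8 mm posteriorly by operator 3 in session 1 for subjects
4–20 — an operator misreading an anatomical definition.

What the simulator does **not** emulate: voxel-size-dependent
localization error, correlated errors between axes or neighbouring
landmarks, operator learning between sessions, and segmentation-induced
surface artefacts. Passing recovery tests therefore demonstrates that
the estimators are correct under the stated model, not that any
particular clinical dataset satisfies that model.

## Numerical choices and validation sizes

* Unit-normal tolerance 1e-12; orthogonality of frames ~1e-10;
  degenerate-triangle threshold 1e-6 mm²; file round-trips hold to
  1e-9 mm (nine decimal places written).
* `s_L^2` truncation at zero keeps `s_R ≥ s_r` always; ties in the
  Grubbs maximum are flagged together; `acos` arguments are clamped
  to [−1, 1].
* The validation suite runs: 100 random balanced designs against the
  ANOVA oracle (equality to 1e-10); 6 × 200 Monte-Carlo replicates of a
  3-operator, 200-subject, 2-session stratum for SD recovery (mean
  $\hat s_r$ within 5%, mean $\hat s_R$ within 10% — the wider band
  reflects the 2 degrees of freedom available for $\sigma_L$ with three
  operators, which biases $\hat s_R$ slightly low by Jensen's
  inequality when $\sigma_L$ dominates); 500 clean 20-subject studies
  for the zero-false-flag property; 25-replicate cohorts for cant
  recovery. These sizes keep the whole suite in the low minutes on a
  single core while leaving Monte-Carlo error well inside the asserted
  tolerances.

## Known limitations

* The two file dialects are pragmatic stand-ins; no public schema
  exists for the commercial annotation exports this data typically
  comes from. DICOM volumes, meshes and annotation software projects
  are out of scope: the package starts at landmark coordinate tables.
* Pooling assumes a common within-subject SD across subjects
  (homoscedasticity across the cohort), the standard assumption of
  this study design.
* With three operators, $s_L$ — and hence $s_R$ — is intrinsically
  noisy; single-study reproducibility values should be read with that
  in mind (the sample-size formula quantifies the repeatability side
  only).
* The exact anatomical definition of the IAF landmark is debated;
  simulated IAF behaviour encodes one plausible reading.
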