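---
title: "Methods: from raw GC-TOFMS cubes to cross-validated metabolic patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw GC-TOFMS cubes to cross-validated metabolic patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predmet)
```

predmet implements a predictive-metabolomics workflow for two-class
comparisons of GC-TOFMS profiles: windowed multivariate curve resolution of
the raw data cube, internal-standard normalization, OPLS-DA pattern
recognition with w*-based variable selection, seven-fold cross-validation
with CV-ANOVA significance testing, and ROC evaluation of the
cross-validated score pattern.  This vignette explains each model, its
assumptions, the tunable parameters, and the design decisions taken where
more than one defensible convention exists.

## The data model

A raw measurement is a cube: for each sample, a retention-time × m/z
intensity matrix.  Within a short retention-time window holding $k$
co-eluting compounds, the bilinear model for sample $s$ is

$$ M_s(t, m) = \sum_{j=1}^{k} a_{sj}\, g_j(t)\, f_j(m) + E_s $$

with $g_j$ the elution profile (unit integral), $f_j$ the mass spectrum
(non-negative, unit sum), and $a_{sj}$ the amount of compound $j$ in sample
$s$.  Relative quantification means recovering $a_{sj}$ up to a common
scale.

## Synthetic data as study conditions

No instrument data ships with the package; a generator produces cubes and
feature tables with known ground truth, at the scale of the study it
emulates: a few hundred resolved features per matrix, a two-class design
with a small informative subset (7–13 features per comparison), co-eluting
Gaussian peaks organised in time windows, 11 internal standards in the
full-scale configuration, and occasional failed samples.

Generator conventions, chosen once:

* **Elution peaks are Gaussian**, spectra are sparse non-negative vectors
  over integer m/z bins (8 fragments each, up to 500 bins).  Tailing and
  spectral skew are deliberately not modelled: the resolution claims being
  tested concern overlap, not peak shape.
* **Overlap** 0–1 sets adjacent peak centers $4\sigma(1-\text{overlap})$
  apart: 0 is baseline separation, 0.5 puts centers two standard deviations
  apart, 1 is complete co-elution.
* **Noise is detector-like**: Gaussian with standard deviation proportional
  to the local signal plus a 1 %-of-maximum dark floor, so `snr` is the
  apex signal-to-noise ratio.  A purely homoscedastic alternative spreads
  far more total noise energy across the thousands of near-empty cells of
  a window than any reasonable reading of "SNR 100" implies, and distorts
  rank selection.
* **Areas are log-normal**, so feature tables are strictly positive and
  behave like relative concentrations.  Informative features receive a
  class-mean shift of `effect_size` pooled standard deviations on the log
  scale, with a random sign per feature; `correlation` adds a shared
  within-class factor across the informative block (default 0.3 — within-
  class correlation and effect sizes are not reported for the original
  cohort, so these defaults are realistic rather than calibrated).
* **Internal standards** have class-independent areas; when present, every
  sample's whole signal is multiplied by a log-normal recovery factor
  (sdlog 0.2), giving IS normalization real instrumental variation to
  remove.
* **Retention-index markers** are a fixed linear ladder shared by all
  samples; cubes are generated aligned, which is why chromatographic
  warping is out of scope.

What passing tests on this generator do *not* show: robustness to peak
tailing, m/z calibration drift, retention-time warping between samples,
detector saturation, or matrix effects.  Conclusions about real data
transfer only to the extent those artefacts have been handled upstream.

## Curve resolution

Each cube is baseline-corrected (per sample and channel: morphological
opening — rolling minimum then maximum over `window_length` points —
smoothed by a moving average, subtracted, clipped at zero; the opening
tracks drifting baselines without the low bias of a plain rolling
minimum).  The time axis is segmented at the lowest local minima of the
smoothed total-ion-current curve subject to a minimum window width, with
half-open `[start, end)` windows, 0-based.

Within a window the sample-concatenated matrix is factorized by
alternating least squares under non-negativity (both factors) and
unimodality (each sample's elution segment), initialized from the purest
m/z channels (iterative residual-norm maximization).  The rank is the
smallest number of singular values explaining ≥ 99 % of the variance,
capped at `max_components` — the source workflow states no rank rule, so
the package pins this spectral-energy convention.  Iteration stops when
the relative fit change drops below `tol` (default 1e-9) or at `max_iter`
(default 500); non-convergence flags the result rather than failing.
Spectra are normalized to unit sum, so each sample's per-component area is
the trapezoidal integral of its own resolved elution segment — identical
to "sample scale × common-profile integral" when shapes are shared across
samples, and more general when they are not.

Manual curation of split peaks is replaced by an automatic merge: two
components in adjacent windows merge when their spectral cosine exceeds
0.98 and their apexes are within two time points.  Retention indices come
from linear interpolation of apex times between marker anchors
(extrapolation outside the ladder is flagged).  Library matching takes the
best cosine among entries within `ri_tol` retention-index units and
assigns the identity only at cosine ≥ `min_score`; unidentified features
are kept in the analysis.

Internal-standard normalization divides each sample's areas by the
geometric mean of its IS areas (the geometric mean is the natural location
estimate for multiplicative recovery variation) and drops the IS features;
a sample with any non-positive IS area cannot be normalized — the
signature of a failed derivatization — and is excluded with a logged
reason.

## Pattern recognition

Feature tables are unit-variance scaled by default (centering plus
division by the column SD).  The original software family defaults to this
convention, but the source description does not state it; pareto scaling
is available and results can be scaling-sensitive.

OPLS-DA with a single binary response fits `A_orth` orthogonal components
followed by one predictive component ("1 + A_orth + 0").  A property worth
knowing: with one response, the predictive weight vector w* is
mathematically identical to the first NIPALS PLS weight regardless of
`A_orth` — orthogonal score vectors are y-orthogonal by construction, so
deflation never changes $X^\top y$.  What the orthogonal correction
changes is the predictive *scores* (cleaned of structured y-orthogonal
variation) and the variance bookkeeping, which is exactly why score plots
and R2X decompositions from OPLS are easier to read than PLS ones.  w* is
unit-norm and oriented so the class coded 1 has positive mean score.

Seven-fold cross-validation deals samples into folds by a deterministic
stratified round-robin (sorted by class, then original order); the
original software's fold rule is order-based but unstated, and a
deterministic rule makes runs reproducible without a seed.  Scaling is
refit inside every training split.  Held-out predictive scores form the
cross-validated score pattern tcv[1]p; $Q^2 = 1 - \mathrm{PRESS}/\mathrm{SS}$
is computed on the response, the discriminant-analysis convention.  When a
class has fewer members than $k$, the round-robin deal degrades to leaving
single class members out.

The orthogonal-component count is the smallest value after which one more
component fails to improve Q2 by more than 0.01.  All final models in the
emulated study are of "1 + 0 + 0" form; the search exists for data that
need it.

## CV-ANOVA

The significance of a cross-validated model is tested by

$$ F = \frac{(\mathrm{SS} - \mathrm{PRESS})/A}{\mathrm{PRESS}/(N - 1 - A)},
   \qquad p = P\!\left(F_{A,\,N-1-A} > F\right), $$

with $A$ the total component count (predictive plus orthogonal).  The
reference construction is published only as a method name in the source
description, so the degrees of freedom are a package convention — pinned
by a null simulation (200 null tables at the study's sample size give a
p < 0.05 fraction of a few percent) rather than by agreement with external
software.  PRESS ≥ SS yields F ≤ 0 and p = 1; a vanishing PRESS floors
the p-value at the smallest positive double rather than zero.

## Variable selection, and an honest caveat

From the all-feature model, features whose w* falls outside
mean(w*) ± 2 SD(w*) are selected — a single pass on the signed weights
(the ± band reads as two-sided on the signed distribution; an
absolute-value variant would differ only at the margin).  The final model
is refit on the selected features with fresh cross-validation and
CV-ANOVA.  Per-feature Mann–Whitney U tests (exact by full enumeration
when the smaller group has ≤ 8 members and no ties; otherwise the normal
approximation with tie and continuity corrections) and median-based
direction arrows annotate the report; they never gate selection, and no
multiplicity correction is applied by default (Benjamini–Hochberg is
available as an option).

The caveat: cross-validating only the refit — not the selection — inflates
the final model's Q2 and CV-ANOVA significance, because the features were
chosen by their association with class on the same samples.  On pure-noise
tables the final-model p-value is essentially always "significant".  This
is a faithful property of the emulated workflow, not an implementation
artefact.  The package therefore reports both the initial (all-feature)
cross-validated diagnostics, whose type-I error is controlled, and the
final post-selection diagnostics, which are the workflow's reported
figures.  Claims of significance should rest on the initial model or on
external validation.

## ROC evaluation of score patterns

ROC analysis is applied to the cross-validated predictive scores — never
to refit in-sample scores, which are grossly optimistic on null data.
AUC is all-pairs concordance with half credit for ties (the Mann–Whitney
identity), reported as-is without forcing ≥ 0.5.  The 95 % interval is a
stratified percentile bootstrap (resampling within each class,
`n_boot = 1000` by default, seeded); with perfectly separated,
well-margined scores every replicate has AUC 1 and the interval
degenerates to the "1.000 (1.000–1.000)" form.  The original study's
external ROC tool is uncharacterized beyond its outputs; the percentile
bootstrap reproduces its degenerate-certainty behavior, which is why it
was chosen over normal-theory intervals.

## Curation and study orchestration

`curate_table()` drops artifact features (near-zero relative variance),
failed samples (≥ half the features collapsed to near zero), and gross
analytical outliers.  Outlier screening uses a robust rule — scores more
than five interquartile ranges from the median on the first two principal
components of the *log-transformed* table — rather than the Hotelling-T²
95 % ellipse that `pca_overview()` reports for visualization: the 95 %
ellipse flags about 5 % of perfectly ordinary samples by chance, which
would silently change sample arithmetic, while the 5×IQR fence has a
negligible false-positive rate yet sits far below the displacement of a
grossly scaled profile (log scale matters: raw-scale scores of log-normal
data are heavy-tailed enough to breach the fence occasionally).  Every
exclusion carries a reason code, and curation aborts if more than a
quarter of the samples would be dropped — almost always mis-scaled input,
not bad samples.

Survival comparisons dichotomize survival time: `gbm` (≤ 4 months short
vs ≥ 36 months long) and `oligodendroglioma` (≤ 24 vs ≥ 36) presets ship
with the package; samples strictly between the break-points are excluded.
The long class uses an inclusive ≥ bound, which matters only for a
survival of exactly 36.0 months.  `run_study()` executes curation followed
by every configured comparison — curation always precedes modeling, and no
comparison ever sees an excluded sample — and serializes the report as
delimited text plus a full-precision JSON snapshot that round-trips.

## Problem sizes and numerical choices

The packaged simulations run at reduced scale — e.g. 10–20 samples and one
to four windows for resolution checks, 40 + 40 samples × 200 features for
modeling checks, 25-seed power and 200-seed null batteries — sizes chosen
so the full battery completes in well under a minute each while estimating
the fractions involved to ±2–3 %.  Degenerate inputs are defined
throughout: all-zero windows resolve to an empty feature set; zero-variance
columns are dropped with a warning under unit-variance scaling; constant
responses, empty selections and empty survival classes raise errors that
name the remedy; ALS non-convergence flags results instead of failing.
Ties in direction arrows are labelled ambiguous rather than forced.

## Known limitations

* No multi-class OPLS-DA, O2PLS, multi-response Y, or survival regression;
  survival is dichotomized exactly as in the emulated design.
* No chromatographic warping; cubes are assumed aligned (true for the
  generator, an upstream responsibility for real data).
* The MCR-ALS reading of the hierarchical resolution stage is a stated
  substitute for unpublished original scripts: windowed ALS with
  non-negativity, unimodality and purest-variable initialization.
* Post-selection significance is biased (see above); the package reports
  it for fidelity, flanked by the unbiased pre-selection diagnostics.
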