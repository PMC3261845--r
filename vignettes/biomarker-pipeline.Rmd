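---
title: "Discovery, validation and plasma assay analysis for colorectal neoplasia biomarkers"
author: "neomarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovery, validation and plasma assay analysis for colorectal neoplasia biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neomarker)
```

## The analysis this package implements

Colorectal neoplasia biomarker programs follow a three-phase design:
candidate transcripts are *discovered* on genome-wide expression arrays over
normal, inflamed (IBD/colitis), adenoma and cancer tissue; survivors are
*validated* on an independent cohort measured with a targeted platform; and a
shortlisted marker is finally assayed by qPCR in tissue and in plasma, where
a blood test would actually operate. `neomarker` implements the statistical
machinery of all three phases over matrices of normalized log2 intensities
(probesets in rows, samples in columns) and long-format cycle-threshold
tables, together with a synthetic-data module that plants known effects so
every stage can be verified against ground truth.

## Differential expression

For a contrast between two phenotype-label sets (class A vs class B, e.g.
normal + IBD vs adenoma + cancer), every probeset is tested with the
equal-variance two-sample Student's t-test on log2 intensities:

$$ t \;=\; \frac{\bar x_B - \bar x_A}{s_p\sqrt{1/n_A + 1/n_B}},
\qquad s_p^2 = \frac{(n_A-1)s_A^2 + (n_B-1)s_B^2}{n_A+n_B-2}. $$

The pooled (not Welch) form is the deliberate default — RMA-style log2 data
have reasonably stable within-class variances, and the pooled test is the
field's convention for this design. Multiple-testing correction is
Bonferroni at discovery (family-wise error control over ~10^4 probesets) and
Benjamini–Hochberg at validation (FDR over a pre-specified candidate list).
Fold change is the difference of class means on the log2 scale, so the
"two-fold" rule is `|log2FC| >= 1`, applied *inclusively*: a planted effect
of exactly one log2 unit passes. Significance is likewise inclusive
(`p_adj <= alpha`, default 0.05); both cutoffs are configurable because the
strict/inclusive distinction is rarely stated in published work.

Two degenerate cases are defined rather than propagated as `NaN`, because
they arise systematically on noise-free synthetic data: two identical
constant groups give `t = 0, p = 1`, and zero pooled variance with unequal
means gives `p = 0` with a `degenerate` flag.

Genome-level structure is summarized by `pc_scores()`: sample scores from
the SVD of the probeset-centered matrix, with variance fractions
`d_k^2 / sum(d^2)`. On cohorts like these the first component is expected to
track neoplastic status.

## The switched-on/off caller

The phenotype-specific caller rests on one assumption: most transcripts in a
given tissue are not expressed, so most probesets report only non-specific
background. The per-probeset means across all arrays are ranked and the
observed value at the nearest-rank 30th percentile (`ceiling(0.3 * n)`-th
order statistic) is taken as the transcriptional-silence threshold `tau` — a
conservative upper bound on background. Nearest-rank (not interpolated) is
intentional: the threshold should be an actually observed probeset value.

A class is called **off** when its summary statistic (default the class
median; configurable via `class_call_quantile`) falls below `tau` and **on**
when it is at least `tau`, with ties counting as on and an optional
dead-band `margin` around `tau` producing indeterminate calls. A probeset
already significant in the contrast's differential expression test is called
`on_in_b` when class A is off and class B on, `off_in_b` in the mirror case.
The class-level aggregation rule and the DE-eligibility gate are the two
genuinely open design choices here; the median was chosen for robustness and
both are surfaced in the configuration and recorded in run manifests.

## Validation concordance

Discovery candidates (significant and at least two-fold changed) are
translated to the validation platform by composing a probeset-to-symbol map
with a symbol-to-probeset map, keeping provenance and reporting unmapped
ids. A translated candidate *validates* when its BH-adjusted p-value on the
validation cohort is at most alpha **and** its direction matches discovery;
a stricter subcount adds the two-fold filter. Correction defaults to the
candidate set only — the validation platform exists to test precisely that
pre-specified list — with whole-chip correction available by flag.
Candidates absent from the validation matrix are excluded from the
denominator and reported separately, so mapping failure is never conflated
with biological non-validation.

## qPCR analysis

**Tissue.** Relative quantification uses the comparative-threshold method
with an endogenous reference (HPRT1) and a designated calibrator sample:
`dCt = Ct_target - Ct_ref`, `ddCt = dCt - dCt_calibrator`,
`RQ = 2^-ddCt`. One cycle is exactly a factor of two; the calibrator has
`RQ = 1` by construction. Replicates are averaged over determined values
only; duplicate pairs more than 1.5 cycles apart are flagged as discordant
(warning, not exclusion — a standard QC convention).

**Plasma.** Each sample is spiked with armored RNA before extraction, so the
spike's Ct measures extraction yield. Normalization is additive on the Ct
scale:

$$ Ct_{norm} = Ct_{sample} - (Ct_{arm,sample} - \overline{Ct}_{arm,panel}) $$

which cancels any per-sample offset applied identically to all targets —
exactly the yield error mode. The published description of this scaling is
verbal; the additive-on-Ct reading implemented here is the standard one.
Detected samples are expressed as fold change versus the control-group
median, `FC = 2^(median_ref - Ct)`, so the control median maps to 1.
Detection requires at least 2 determined replicates of 3 (configurable);
undetermined replicates are *never* imputed at the cycle cap, which would
bias `ddCt` — detection and quantification are kept separate.

Group comparisons use the Mann–Whitney rank test: exact by full enumeration
of labelings for combined n up to 12 without ties, otherwise the
tie-corrected normal approximation without continuity correction (so
identical groups give p = 1 exactly). Classification of a sample as
neoplasia from Ct features uses logistic regression fitted by IRLS with a
small ridge penalty (1e-4) on slopes only; perfectly separated Ct panels —
plausible at n = 60 — would otherwise diverge. The decision rule is the
inclusive `P(neoplasia) >= 0.5`.

## What the simulator emulates — and what it does not

`sim_config()` describes a cohort on the log2 scale: a Gaussian background
floor (default mean 5, SD 0.5 — a typical RMA floor), a constitutively
expressed fraction (default 0.4) shifted 3 log2 units up, planted
differential effects (default one log2 unit, the two-fold rule's boundary)
on the neoplasia contrast, and planted on/off probesets. Class counts
default to 20/10/10/20 over normal/IBD/adenoma/cancer — the qualitative
shape of real discovery cohorts (normals and cancers dominating) at desk
scale. Within-class noise is Gaussian on the log2 scale (log-normal
intensities), default SD 0.5; the real cohorts' within-phenotype variance is
not published, so this is a convention, chosen once.

Two generator choices deserve explanation. Planted baselines are
*deterministic* (exactly `background_mean + expressed_mean_shift`), so that
in the zero-noise limit planted log2 fold changes are observed exactly — the
property the exactness tests rely on. And the silent class of a planted
on/off probeset sits at `background_mean - background_sd` rather than at a
random background draw: the silence threshold lies near the *middle* of the
background mass, so a truly silent transcript must be planted in the lower
background range for its off-call to be well-defined; one SD below center is
a typical low-background intensity.

The paired-cohort generator shares one truth between discovery and
validation and removes the effect from an exact `1 - f` fraction of planted
probesets in validation (`round(f * n)` concordant), with independent noise
— the idealized model behind directional concordance counting.

The plasma simulator draws per-group true target Ct (defaults 41/38.5/36.5
for normal/adenoma/cancer, SD 1.5, chosen to emulate the reported pattern of
frequent detection in neoplasia and infrequent detection in controls at 60
PCR cycles), adds a per-sample yield offset to all targets identically, and
drops replicates with probability `1 - plogis((midpoint - Ct)/slope)`
(midpoint 40, slope 1.5) for the low-abundance target. Dropout is restricted
to that target by default because the abundant control and the spike
amplify reliably in practice. The published work gives only
detected/not-detected outcomes, no detection model; the logistic form is
this package's choice.

None of this emulates probe-level artifacts, batch effects, RNA degradation,
non-Gaussian heavy tails, or correlated genes. Passing tests therefore
demonstrate that the *statistical machinery* is correct under its stated
model, not that the thresholds would transfer unchanged to a particular real
cohort.

## Numerical choices and problem sizes

* Nearest-rank percentile, inclusive cutoffs, and ties-at-`tau` = on are all
  documented above; each is an explicit argument.
* BH adjustment delegates to `stats::p.adjust`; the test suite checks it
  against an independent brute-force step-up enumeration on all short
  inputs.
* The exact Mann–Whitney path enumerates all `choose(n, n_x)` labelings up
  to combined n = 12; beyond that the tie-corrected normal approximation is
  used.
* IRLS stops when the largest coefficient step falls below 1e-10, with a
  100-iteration cap; non-convergence is an error, never a silent result.
* The verification suite uses cohorts of 200–1000 probesets with 20–80
  samples and 200–500 simulation replicates — sizes at which every
  distributional property checked has narrow Monte-Carlo error while the
  whole suite runs in well under a minute on one core.

## Known limitations

* The equal-variance t-test is the deliberate default; strongly
  heteroscedastic classes would favor Welch (available via the underlying
  statistics but not wired into `run_contrast`).
* On/off calling depends on a single global threshold; arrays with strongly
  shifted background distributions would need per-array calibration, which
  is out of scope here.
* Concordance counting treats candidates as exchangeable; it does not model
  correlated probesets targeting the same gene.
* The plasma classifier is single-feature logistic by default usage; no
  cross-validation machinery is included.
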