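---
title: "Outlier detection in linear series from the arithmetic-progression sum"
author: "apoutliers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outlier detection in linear series from the arithmetic-progression sum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apoutliers)
```

## The model

Many monitored processes — a biogas reactor's H~2~ content during stable
operation is the motivating example — produce series that are expected to be
*linear* in time: increasing, decreasing or constant. A finite arithmetic
progression (AP) with $n$ terms satisfies

$$\frac{a_{\min} + a_{\max}}{S_n} = \frac{2}{n},$$

where $S_n$ is the sum of all terms: the sum of the two extreme elements,
relative to the total, is fully determined by the length alone. A linear
series without outliers *is* an AP, so any departure of this ratio from
$2/n$ implies contamination, with no distributional assumption, no model
fit, and no standardization — the ratio lives in $(0, 1]$ by construction.
A ratio above $2/n$ implicates the maximum, below $2/n$ the minimum.

`ap_ratio()` computes this raw indicator. It is fragile in practice — with
negative values the numerator or denominator can vanish or flip sign — so
detection uses two rearrangements that first shift the series by its
minimum (`mms_max()`) or flip it through its extremes, the *complement*
`series_complement()` (`mms_min()`):

$$\mathrm{MMS}_{\max} = \frac{a_{\max} - a_{\min}}{S_n - n\,a_{\min}},
\qquad
\mathrm{MMS}_{\min} = \frac{a_{\max} - a_{\min}}{n\,a_{\max} - S_n}.$$

Both equal $2/n$ exactly on any AP (any sign, any slope), both lie in
$(0,1]$, and a value strictly above the threshold flags the corresponding
extreme as a **significant outlier**. On a constant series both scores are
$0/0$; the package returns the `NO_SIGNAL` sentinel (`NA_real_`), meaning
"no outlier detectable", which the pipeline treats as a clean stop, never
as an error.

## The detection threshold

The working threshold widens the exact-line indicator by a factor $k$:

$$R_w = \frac{2}{n}\,(1 + k), \qquad 0 \le k \le \frac{n}{2} - 1,$$

so $R_w \in [2/n, 1]$ (`detection_criterion()`). $k$ is the one tunable
that matters: it sets the width of the *linear border* inside which
elements count as clean. The package ships two profiles:

* `criteria_config()` — $k_{\mathrm{MMS}} = 0.5$,
  $k_{\mathrm{EMMS}} = 0.01$: the setting validated on synthetic lines.
* `criteria_config(preset = "field")` — $k_{\mathrm{MMS}} = 0.2$,
  $k_{\mathrm{EMMS}} = 0.1$: the wider-tolerance profile used on real
  sensor segments.

Flags require a **strict** inequality (score $> R_w$); equality is
consistent with the border. The choice between `>` and `>=` is otherwise
free; strictness ensures an exact AP is never flagged even at $k = 0$.

## Handling removed and missing values without imputation

Removing a detected outlier (or starting with gaps) would horizontally
shift every later element and destroy the linear relation. Two
imputation-free repairs are used, one per phase:

**Angular shifting** (`angular_shift_value()`,
`compact_after_removals()`). Each surviving element is re-placed at its
compacted offset along the ray from the reference element through its
*original* value:
$a_{\mathrm{new}} = a_0 + (a_{\mathrm{orig}} - a_0)\,
\frac{\text{new offset}}{\text{orig offset}}$.
Any point on a line through the reference lands exactly on that line at
its new offset, so a clean series survives compaction unchanged.
Recalculation always starts from original values, never from previously
recalculated ones, which makes the result independent of the removal
order. Initial missing values are treated exactly like removals. Elements
before an interior reference shift symmetrically with negative offsets.

**The constant-value transform** (`constant_transform()`). The series is
mapped to the absolute residuals around the line through the reference
with the mean slope $m = \sum (a_k - a_0) / \sum (x_k - x_0)$ over present
elements:
$a_k^{TT} = |(a_k - a_0) - (x_k - x_0)\,m|$.
A perfect line maps to all zeros *regardless of which elements are
missing*, so this form needs no repair at all. The reference maps to
exactly 0, and the output is invariant under adding any linear trend.

## EMMS: interior outliers

MMS can only implicate the current extremes; an interior outlier that is
neither maximum nor minimum drives it into *Bad Detection* (the worked
example `c(100, 101, 102, 103.6, 104)` scores
$\mathrm{MMS}_{\min} = 0.426 > \mathrm{MMS}_{\max} = 0.377$ and wrongly
implicates the minimum). The enhanced scores (`emms_scores()`) therefore
operate on the transform, where every outlier *becomes* the maximum and
the minimum is identically 0 at the reference:

$$\mathrm{EMMS}_{\max} = \frac{a^{TT}_{\max}}{S^{TT}_n}, \qquad
\mathrm{EMMS}_{\min} = \frac{a^{TT}_{\max}}{n\,a^{TT}_{\max} - S^{TT}_n}.$$

Outliers are present whenever **either** score exceeds $R_w$; the
removable element is always the transform's argmax. An earlier design of
this package halted the EMMS loop when only the minimum-side score fired,
reasoning that the transform's argmin (the reference) is not removable.
That halt proved wrong in validation: a minimum-side-only signal typically
means many comparable residuals remain — heavy contamination with no
single dominant point — and stopping there leaves outliers in place, while
removing the largest residual remains correct. The argmin itself is indeed
never removed.

Because the transform's slope estimate is corrupted by gross outliers,
EMMS is not applied directly to raw data by default: the pipeline runs MMS
first (`phase = "emms"` exists for callers who know better).

## The two-phase pipeline

`detect_outliers()` iterates:

1. **MMS phase.** Compact the survivors by angular shifting, classify at
   $R_w(n_{\mathrm{current}}, k_{\mathrm{MMS}})$, remove the flagged
   extreme as a `significant_outlier`, repeat. Both $2/n$ and $R_w$ are
   recomputed at the shrinking window size.
2. **EMMS phase.** On the survivors *at their original indices* (the
   transform is inherently gap-proof, so no compaction), classify at
   $R_w(n, k_{\mathrm{EMMS}})$, remove the argmax as a
   `nonsignificant_outlier`, recompute the transform — removing an
   outlier changes the biased slope — and repeat.

Each phase ends on a quiet step (`below_threshold`), a degenerate window
(`no_signal`, `insufficient_elements` below 3 elements) or the defensive
iteration cap. The result carries a per-position `outlier_labels` frame
(`nonoutlier` / `significant_outlier` / `nonsignificant_outlier` /
`missing`) and a `detection_trace` with every iteration's scores,
threshold, action and termination reason.

**Bad-Detection termination.** When the window's first and last elements
are assumed clean (the default situation: the reference is the first
element), a flag on either endpoint is a contradiction and both phases
terminate immediately (`bad_detection_endpoint`). This is the automatic
Bad-Detection detector; `guard_endpoints = FALSE` disables it for users
with prior knowledge of where outliers can occur. When the reference has
been overridden to an interior element the endpoint assumption no longer
holds, so the guard reduces to the reference itself; a flagged reference
always terminates (`reference_flagged`), since removing the one element
assumed clean is never coherent.

**Multiple references.** The method needs a single clean anchor. When none
is known, `detect_multi_reference()` tries each candidate and keeps the
best fitting run. Ranking note: runs that hit a Bad-Detection termination
are ranked below cleanly terminated runs *before* comparing nonoutlier
counts — a run terminated at its first step labels everything nonoutlier
and would otherwise always win — with ties going to the earliest
candidate.

## The synthetic validation harness

`simulation_spec()` / `make_series()` emulate the validation design:
a base line on positions $0..n-1$, a contamination fraction (default 50%),
and optional missing regions, with ground-truth labels returned alongside.

* **Line defaults.** Intercept 1050, slope $\pm 1$ (or 0 with positive
  intercept for constant lines). These keep every base value positive and
  away from zero for $n \le 1000$, so a multiplicative outlier can never
  coincide with the line itself; the scores are affine invariant, so the
  particular values carry no information beyond that.
* **Non-Gaussian mode.** The stated contamination is multiplicative,
  "very small and very large", factors $\pm 10^{-2}$ to $\pm 10^{2}$. No
  sampling law is stated; magnitudes are drawn log-uniformly (each decade
  equally likely, covering both "very small" and "very large") with a
  random sign.
* **Gaussian mode.** Additive $N(0, \sigma)$ perturbations with
  $\sigma$ = 5% of the base line's value range — mild, symmetric, no
  extreme points, which is what renders the MMS phase inactive. A constant
  line has zero range, so $\sigma$ falls back to 5% of the absolute
  intercept (sensor-noise scale).
* Outlier positions are uniform among present positions, excluding the
  (first present) reference when `protect_reference = TRUE`; the count is
  $\lfloor \mathrm{fraction} \times n_{\mathrm{present}} \rfloor$.
* The generator is deterministic under `seed`.

`evaluate_labels()` reports the four validation percentages (correct and
false nonoutliers relative to actual nonoutliers; correct and false
outliers relative to actual outliers), and `run_validation_suite()` runs
the trend x mode x size grid. The validation configuration disables the
endpoint guard: the design guarantees a clean reference and clean-by-
construction truth, and an injected outlier that lands on the last
position would otherwise (correctly, but uninformatively) terminate the
run. The guarded default remains the right choice for field data.

Problem sizes used by the shipped validation checks: $n \in \{10, 100,
1000\}$, three trends, 20 seeds (10 for the missing-region scenario, whose
four regions of 50+100+100+50 positions leave 700 present elements).

## What validation does and does not show

On this design the detector is essentially exact at moderate sizes: at
$n = 100$ and $n = 1000$ with 50% non-Gaussian contamination, runs flag
every injected outlier with no false flags, missing regions included. The
acceptance script reports the pooled false-flag-plus-miss rate across all
sizes; it comes out around 0.1%.

That residual rate is concentrated at $n = 10$ and is structural, not
numerical. With 5 of 10 positions contaminated, a draw in which several
factors have small magnitude puts half the points in a coherent cluster
far below a positive line (any $|f| \ll 1$ maps a positive value toward
zero regardless of sign). Such a cluster corrupts the series sum — both
MMS scores stay under $R_w$, the self-masking failure of sum-based
statistics at 50% breakdown — and can capture the transform's slope
estimate, making clean far points the largest residuals. No reference
choice on the clean side fixes a lost majority. Users should treat 50%
contamination at $n \approx 10$ as beyond the method's reliable regime.

Similarly, "Gaussian contamination leaves MMS inactive" is a
sloped-trend property: on a *constant* line the MMS score of half-exact,
half-perturbed values is scale-free (both the level and $\sigma$ cancel),
so MMS fires on a fixed fraction of draws — about a quarter of replicates
at $n = 10$ — whatever the noise level, and on an asymmetric draw the
implicated extreme can be a clean point (all clean values tie at a
constant line's extremes). The flags it does produce are almost always
true outliers; the behaviour is a classification-severity quirk, not a
correctness failure, but it means the "MMS stays silent under Gaussian
noise" rule of thumb should not be relied on for constant segments.

Synthetic lines are exact between outliers. Real sensor data carry
baseline noise everywhere, so clean points never transform to exact
zeros, `NO_SIGNAL` stops are rarer, and $k$ must be tuned to the noise
band (the `field` preset is a starting point). Passing the synthetic
checks therefore demonstrates the mechanics — scores, repairs,
termination — not field accuracy on any particular instrument.

## Numerical choices

* Degeneracy floors: a value range (MMS) or transform maximum (EMMS) at or
  below $10^{-9}$ relative to the data scale counts as zero and yields
  `NO_SIGNAL`. Exact-zero tests are meaningless after floating-point
  arithmetic with non-integer slopes; $10^{-9}$ is far above accumulated
  rounding and far below any deviation of practical interest.
* Ties among equal extremes (or equal residuals) flag the earliest
  position; an exact tie between the two MMS scores prefers the maximum
  side. Both rules are arbitrary but fixed, keeping runs reproducible.
* Score equality checks in the test suite use a relative tolerance of
  $10^{-12}$ for pure-arithmetic identities ("equals $2/n$").
* `max_iterations` defaults to the series length — one cannot remove more
  than everything — and exists purely as a defensive cap.

## Known limitations

* One series, one line: no segmentation of longer nonlinear records, no
  multivariate support. Piecewise-linear data must be windowed upstream.
* Everything rests on the reference element being clean; with a
  contaminated reference only significant outliers are found reliably,
  and `detect_multi_reference()` is the recovery tool.
* The breakdown regimes above: 50% contamination at very small $n$, and
  MMS severity on constant-with-Gaussian-noise segments.
* Baseline alternatives (least-squares residual screens, sigma filters,
  Grubbs-type tests) are deliberately out of scope; the package implements
  the AP-sum method only.
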