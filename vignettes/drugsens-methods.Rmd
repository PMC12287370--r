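---
title: "Methods: drug sensitivity scoring, target addiction and synergy analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug sensitivity scoring, target addiction and synergy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugsens)
```

This vignette documents the models and conventions the package
implements, the parameters that matter and their defaults, what the
synthetic generators do and do not emulate, and the design decisions
taken where the underlying procedures were genuinely open.

## The screening context

The pipeline targets plate-based viability screens of paired parental
and drug-resistant B-cell malignancy models (e.g. lymphoma cell-line
pairs where the resistant derivative was raised by prolonged sub-lethal
exposure to a PI3Kδ inhibitor) and of primary CLL cells. Treatments —
single agents and 1:1 fixed-molar combinations — are printed at five
log-spaced concentrations (1–10,000 nM by default; drug-specific ranges
such as 0.1–1,000 nM are supported, and all concentrations are stored in
nM), viability is read out by luminescent ATP assay after 72 h, and each
plate carries vehicle (0.1% DMSO) and full-kill (100 µM benzethonium
chloride) control wells.

## Viability normalization

Each compound well is rescaled against its own sample's pooled controls,

$$v = 100\,\frac{S - \bar S_{pos}}{\bar S_{neg} - \bar S_{pos}},$$

then replicate wells are averaged per (treatment, concentration).
Choices worth stating:

* **No clipping.** Normalized viability slightly above 100% or below 0%
  is legitimate noise and is preserved; clipping happens only inside
  formulas that require a bounded range (the DSS integrand, Bliss
  inhibition fractions), documented there.
* **Per-well first.** Wells are normalized individually and then
  averaged. Because the transform is affine, this equals normalizing
  the replicate-mean signal; per-well-first is kept because controls
  belong to plates.
* **Control summary.** Controls are pooled per sample and summarized by
  the arithmetic mean (a median option exists for heavy-tailed control
  wells). Mean matches the linearity of the formula.
* **Degenerate controls** (negative mean not above positive mean)
  signal assay failure and raise an error rather than producing
  nonsense scores.

## Four-parameter logistic fitting

`fit_logistic()` minimizes squared error of

$$v(x) = b + \frac{t - b}{1 + 10^{\,h (x - e)}},
  \qquad x = \log_{10}(\mathrm{conc\ nM}),$$

with $t$ the top asymptote, $b$ the bottom, $e$ the log10 IC50 and $h
\ge 0$ the Hill slope, so every admissible curve is monotone
non-increasing in dose — the geometry the sensitivity score assumes.

* **Bounds.** $0 \le b \le t \le 120$ (viability can overshoot 100%),
  $h \in [0, 10]$, $e$ within the tested range padded by 2 log10 units.
  Internally the pair $(t, b)$ is parameterized as $(t, b/t)$ so the
  ordering constraint is a plain box.
* **Deterministic multi-start.** L-BFGS-B from a 5 × 5 grid over
  $(e, h)$; best residual sum of squares wins. No randomness, so fits
  are exactly reproducible and invariant to input point order.
* **Flat fallback.** A constant curve at the mean viability is always
  among the candidates, so the returned RSS never exceeds the flat
  fit's; if every refinement fails the flat curve is returned flagged
  `converged = FALSE`. The DSS of a flat fit is well defined, so a
  screen never aborts on one degenerate series.
* **Identifiability.** For flat or barely-responding series the
  individual parameters are not identifiable; predictions are. Tests
  therefore check prediction recovery (0.5% viability) rather than
  parameter equality in those regimes.

## The modified DSS3 score

`dss_score()` integrates inhibition $y(x) = 100 - v(x)$, clipped to the
activity band $[0,\, 100 - t_v]$ with viability floor $t_v = 10$%, over
the tested window $[x_{\min}, x_{\max}]$:

$$\mathrm{DSS} = \frac{100 \int_{x_{\min}}^{x_{\max}}
  \min(\max(y(x), 0),\, 100 - t_v)\, dx}
  {(100 - t_v)(x_{\max} - x_{\min})}.$$

A curve pinned at 100% viability scores 0; complete kill across the
window scores 100; scores are comparable across drug-specific
concentration ranges of equal log-width because the dose axis is
normalized by window length.

Two readings of the score's dose window are possible. Taken literally,
truncating the integral at the dose where viability reaches 10% would
drive the score of a maximally potent drug toward 0 — contradicting the
score's defining property that higher sensitivity gives a higher score
on a 0–100 scale. The default therefore integrates the capped
inhibition over the full tested window (geometrically: the area between
the curve and the 100% line, clipped to the 10–100% viability band),
which realizes both the 0–100 range and the monotonicity in potency and
efficacy. The literal dose-window truncation is available as
`dss_config(apply_window_factor = TRUE)` — it multiplies the score by
$(x_{stop} - x_{\min})/(x_{\max} - x_{\min})$ and labels the result —
so both variants are explicit rather than guessed. Likewise, the
asymptote-logarithm division that distinguishes DSS2-style scores is
omitted entirely; the metric label records the variant in use.

Numerics: the integrand's clip points are found in closed form (the
logistic's crossings of the 100% and $t_v$ levels), the integral is
adaptive quadrature on the smooth pieces (`rel.tol` $10^{-8}$), and a
dense-trapezoid oracle agrees to better than $10^{-3}$ DSS units over
the tested parameter space. Inhibition below zero (viability above
100%) contributes zero area, never negative, keeping the score floored
at 0.

## Target addiction scores

`compute_tas()` averages, per protein target, the experiment-mean DSS
of all scored treatments annotated to that target. Conventions:

* Combinations contribute their single combination DSS once to each
  target in their annotation (the union of their components' targets);
  no affinity weighting is attempted — the annotation table is the sole
  source of target assignments.
* Means are taken over experiment-level mean DSS, not pooled
  replicate-level scores, matching how per-experiment screens are
  reported.
* Treatments without a score for the sample are excluded, not imputed;
  a target with no scored annotated treatment is absent from the table
  rather than zero — absence of evidence is not evidence of
  insensitivity.
* `rank_targets()` breaks ties deterministically by target name.

## Bliss synergy

Viability is converted to inhibition fractions clipped to $[0, 1]$
(the Bliss expectation $E = f_A + f_B - f_A f_B$ is a probability
identity, so the inputs must be fractions), the expectation is formed
from the monotherapy row/column (or the monotherapy series of a 1:1
diagonal design), and the excess $(f_{obs} - E) \times 100$ is averaged
over combination cells only. Calls use the −10/+10 percentage-point
bounds with the boundaries counted as additive. The untreated cell is
renormalized to exactly 100 to define the zero-inhibition baseline, and
no baseline or outlier correction of the surface is applied.

Machine-learning completion of full matrices from measured diagonals is
out of scope; `bliss_diagonal()` scores the measured diagonal cells
directly, which is exact for the cells actually measured. Published
figure scores computed on model-completed matrices are therefore not a
reproducibility contract for this package.

## Differential transcription filter

For each cell line separately, replicate counts are collapsed to one
parental and one resistant value per transcript, and a transcript is
called altered iff all three clauses hold, with the strictness of each
inequality exactly as stated:

* CPM $> 0.5$ (strict), where CPM is the collapsed count divided by the
  condition's collapsed library sum times $10^6$;
* MC $\ge 10$ (non-strict), the mean of the parental and resistant
  values;
* $|$L2FC$| > 2$ (strict), with $\mathrm{L2FC} = \log_2(r + 1) -
  \log_2(p + 1)$; the +1 pseudocount keeps zero counts finite.

Two conventions were genuinely open and are config-exposed via
`diff_thresholds()`:

* **Replicate collapsing** defaults to averaging (the filter describes
  one parental and one resistant value per transcript); summing is the
  alternative.
* **Which condition's CPM is thresholded** defaults to *either* (max of
  the two), the permissive standard for expression filters; *both* is
  the alternative.

This is a deterministic filter, not a statistical test: no dispersion
modeling and no p-values, by design. Downstream pathway enrichment is
out of scope.

## MFI transforms

Flow-cytometry median fluorescence intensities are noise-corrected by
isotype-control subtraction (negative results are flagged, not
clipped), log10-transformed above a 1 AU floor when not normalized to a
control, and expressed relative to DMSO as a linear difference — the
DMSO control maps to exactly zero, which a difference realizes and a
ratio would not. Whether figure-style DMSO-relative values should be
computed on linear or logged MFI was open; linear is chosen because of
the set-to-zero anchor.

## Synthetic generators

The generators produce data with the statistical structure each stage
assumes, so the whole chain is testable without any download. They are
pure functions of their parameters and seed (the caller's RNG state is
saved and restored), and their defaults *are* the study conditions the
rest of the package is tested under:

* **Screens** (`simulate_screen`): five-point log-spaced series,
  1–10,000 nM; additive Gaussian viability noise, sd 5%, chosen to
  resemble triplicate luminescence scatter; control separation 100,000
  vs 2,000 AU with 16 control wells per kind; signals truncated at 0.
  With zero noise the construction is exactly invertible through
  normalization. The default library (`synthetic_treatment_library`)
  mirrors the screen design: 93 single agents and 87 pairwise 1:1
  combinations.
* **Ground truth** (`random_screen_truth`): top 100%, bottom uniform on
  0–20%, log10 IC50 uniform on 1–3 (inside the tested window, as screen
  series are designed to bracket the IC50), Hill slope uniform on
  1–2.5, typical of cytotoxic dose-response slopes.
* **Combination surfaces** (`simulate_combination`): combination
  inhibition is $\mathrm{clip}(f_A + f_B - f_A f_B + \delta +
  \varepsilon,\, 0,\, 1)$, so $\delta = 0$ yields Bliss-independent
  surfaces and a nonzero $\delta$ injects exactly that excess before
  clipping.
* **Counts** (`simulate_counts`): log-normal baseline means (median
  200 counts, sdlog 1), negative-binomial replicates with dispersion
  0.05 — ordinary RNA-seq overdispersion — two replicates per
  condition, and a spiked subset at a configurable fold-change.

What they deliberately do **not** emulate: plate spatial artifacts and
edge effects, batch effects, liquid-handler dialects, library-size
imbalance between conditions, and clinical time courses. Passing tests
on synthetic data therefore demonstrate the correctness of the
computations under the stated noise models, not robustness to those
real-data artifacts.

## Problem sizes used by the test suite

The suite exercises: 200 random parameter sets against a 10,001-point
trapezoid oracle and 1,000 random pairs for DSS monotonicity; 100
simulated treatments at 5% noise and 3 replicates for IC50 recovery
(±0.3 log10 units for ≥ 90%); 100 seeded surfaces for Bliss null and
injected-excess calibration; 1,000 random toy tables for TAS
brute-force equality; a full 93 + 87 treatment screen for the
target-ranking check; and 5,000-transcript matrices with 25 spiked
8-fold changes for filter recovery. These sizes make the whole suite
run in about a minute while keeping the Monte-Carlo margins far from
their thresholds.

## Known limitations

* The dose-window reading of the sensitivity score is a documented
  interpretation (both variants shipped and labeled); scores from other
  implementations of the DSS family may differ by the window factor or
  asymptote division.
* Bliss scoring assumes the monotherapy row/column (or series) is
  measured; it does not impute unmeasured matrix cells.
* The logistic model is monotone by construction: biphasic or
  bell-shaped responses are fitted as their best monotone
  approximation, flagged only through residuals.
* The transcript filter with two replicates per condition has no error
  control; it is the screen's published definition, not a statistical
  test.
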