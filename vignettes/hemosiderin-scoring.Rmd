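---
title: "Scoring hemosiderophages: the THS, its interobserver error, and a simulated scoring study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring hemosiderophages: the THS, its interobserver error, and a simulated scoring study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The score and the diagnosis

Exercise-induced pulmonary hemorrhage (EIPH) in sport horses is diagnosed
cytologically from bronchoalveolar lavage fluid (BALF): after an iron stain
(Perl's Prussian blue, or the modified Turnbull's blue/Quincke reaction),
alveolar macrophages that have degraded erythrocytes carry blue hemosiderin
pigment. In the Doucet & Viel system each enumerated macrophage receives a
discrete grade $g_i \in \{0,\dots,4\}$ — from 0, no intracytoplasmic
hemosiderin, to 4, a cell filled with it — and the total hemosiderin score of
a slide scored by one rater is the grade sum expressed per 100 cells,

$$\mathrm{THS} = \frac{100}{n}\sum_{i=1}^{n} g_i \in [0, 400],$$

with the protocol requiring $n \ge 300$ enumerated macrophages. EIPH is
called positive at the published cut-off $\mathrm{THS} \ge 75$.

Two conventions in `compute_ths()` and `classify_eiph()` deserve note:

* **Tie at the cut-off.** A score of exactly 75 is positive (the rule is
  "$<75$" versus "$\ge 75$"). The cut-off is an argument, not a constant.
* **All annotated cells count.** Raters typically pass 300 before stopping;
  the THS uses every annotated cell rather than truncating to the first 300.
  Truncation would discard information and make the score depend on
  annotation order.

Grades are validated as integers; fractional grades are rejected rather than
rounded, because a fractional grade indicates a data error, not a
measurement.

## Cells as a continuum, grades as bins

Intracytoplasmic hemosiderin is physically a continuum. The package
represents it as a pigment fraction $p \in [0,1]$ — the fraction of the
cytoplasm occupied by blue pigment — and cuts it into grades with four
ascending thresholds via `grade_from_content()`. The default thresholds
$(0.02, 0.25, 0.50, 0.75)$ are a package convention (the published grade
definitions are verbal), chosen so that grade 0 tolerates trace staining
(below 2% coverage), and grades 1–4 split the remaining range with a wider
grade-1 band, matching how the verbal anchors cluster. The bins are
lower-inclusive: a cell exactly at a threshold takes the higher grade. All
three users of the convention — the ground-truth generator, the simulated
annotators, and the image grader — share the same function and default, and
every entry point exposes the thresholds as an argument.

## The simulated scoring study

`generate_study()` emulates the structure of a two-stain interobserver
study: by default 26 BALF samples, each contributing one Prussian-blue and
one Turnbull-blue slide (52 slides), with every alveolar macrophage present
as a ground-truth annotation and 596–8954 macrophages per slide. Choices the
source material does not fix, made once and documented here:

* **Severity.** Each sample draws a severity $s \sim U(0.02, 0.85)$ shared
  by its two slides. The range spans near-clean slides (whose simulated BALF
  iron falls under the 0.4 µmol/L detection limit, as a minority of real
  cases does) through heavily pigmented, clearly positive slides.
* **Cell content.** Content is a two-component mixture indexed by severity:
  with probability $1-s$ a "clean" component $0.02 \cdot
  \mathrm{Beta}(1,3)$ — always grade 0, so a severity-0 slide has THS 0
  exactly — and with probability $s$ a pigmented component
  $\mathrm{Beta}(1.8, 1.2)$ spread over the full range. Severity 1 gives an
  expected grade ≈ 2.4, i.e. a clearly positive THS.
* **Geometry.** Cells sit on a jittered grid (pitch 140 px, jitter ±15 px)
  guaranteeing center spacing ≥ 110 px — more than twice the 50 px matching
  radius, so cell matching is unambiguous at defaults. Coordinates are
  0-based pixels at the study's 0.25 µm/px scan resolution. The spacing can
  be relaxed via `study_config()` to stress-test the matcher.
* **Stains.** The two stains differ by pigment hue only; an optional
  `stain_content_offset` can push Turnbull-stained contents up to reproduce
  stain-dependent score offsets, but defaults to 0 rather than asserting a
  magnitude.

### Simulated annotators

`simulate_annotator()` reproduces the two error sources a rater panel
exhibits:

* **Systematic error** — a signed `threshold_shift` applied to all four
  grade thresholds. A negative shift lowers every boundary, so the rater
  grades systematically higher; this is the dominant real-world mechanism
  (raters' divergent labels are overwhelmingly one grade *higher* than the
  reference). Default panel shifts are mostly negative, mean ≈ −0.04.
* **Random error** — per-cell perception noise on the content
  (`perception_sd`, default 0.06) and a fresh cell selection per rater.

Selection follows one of three patterns observed in practice
(`uniform_random`, `clustered_fields`, `meander`), the spot placement
jitters by `jitter_sd` (default 10 px — real coordinate error is not
quantified anywhere, so this is our choice), truncated strictly inside the
matching radius so a selected cell always remains matchable. A binomial
`misid_rate` fraction of annotations (default 0.23, calibrated to the ~77%
matched fraction of real panels) lands on non-macrophage locations at least
one matching radius away from every true cell and receives grade 0–1,
emulating unpigmented leukocytes mistaken for macrophages.

One default panel consequence worth knowing: misidentified spots carry low
grades, which *deflates* the THS on heavily pigmented slides, partially
offsetting the threshold-shift inflation. The grade-inflation property
(panel mean THS above the ground truth on nearly every slide) is therefore a
statement about the grading mechanism, demonstrated with shift-only panels;
the full default panel mixes both mechanisms, as real raters do.

### Chemistry

`simulate_chemistry()` fills per-slide BALF laboratory values. Iron tracks
chronic hemorrhage: `baseline + slope × (THS/400) × density + lognormal
noise`, censored at the 0.4 µmol/L detection limit (censored values are
recorded *at* the limit with a flag — no emitted value lies strictly between
0 and the limit — and enter rank correlations as ties there). RBC count and
hemoglobin are acute-bleeding markers drawn independently of the THS, so
their rank correlations with any THS hover near zero by construction.

## Matching and grade standardization

Two spot-annotation sets of one slide are matched by `match_annotations()`
when centers are ≤ 50 px apart. Whether the original analyses used
one-to-one assignment or nearest-within-radius is not documented; we use the
stricter convention — the maximum-cardinality, minimum-total-distance
one-to-one assignment over candidate pairs — because it cannot double-count
a reference cell. Numerical care:

* Feasibility at the radius is decided on *squared* distances
  ($d^2 \le 2500$), so behaviour at exactly 50 px is not at the mercy of a
  square root.
* At default cell spacing the candidate graph decomposes into single edges
  and the assignment is immediate; otherwise the Hungarian solver
  (`clue::solve_LSAP`) runs on the reduced candidate sets with a dummy-node
  construction, and an infinitesimal index-ordered cost perturbation makes
  the selected optimum deterministic (preferring low set-a, then set-b
  indices among exact ties).

`standardize_grades()` then exchanges each matched annotation's grade for
the reference grade, keeping the rater's coordinates and cell selection;
unmatched annotations are excluded. The grade confusion
(`grade_confusion()`) is tabulated over matched pairs only, since unmatched
spots have no comparable label.

## Agreement: variance components, ICC, uncertainty interval

THS tables are fully crossed (every rater scores every slide, single
measurement), modelled as

$$y_{sa} = \mu + \text{slide}_s + \text{annotator}_a + \varepsilon_{sa}.$$

The reference estimator (`method = "anova_mom"`) equates observed and
expected mean squares — $\hat\sigma^2_e = \mathrm{MSE}$,
$\hat\sigma^2_a = (\mathrm{MSA} - \mathrm{MSE})/S$,
$\hat\sigma^2_s = (\mathrm{MSS} - \mathrm{MSE})/A$ — because on balanced
tables it is closed-form, fast, and testable against algebraic identities
(the components reconstruct the grand variance). Negative estimates are
truncated to zero with a warning rather than propagated. A REML fit through
`lme4` is available as `method = "reml"` and agrees with the moment
estimator to numerical tolerance on balanced tables; it is the secondary
route, not the reference.

Two ratio summaries are reported side by side, deliberately labelled:

* `icc_agreement` $= \sigma^2_s / (\sigma^2_s + \sigma^2_a + \sigma^2_e)$,
  the conventional agreement ICC for this design;
* `error_partition` $= \sigma^2_a / (\sigma^2_a + \sigma^2_e)$, the share of
  the *measurement error* that is systematic.

Published interobserver narratives sometimes quote a single "ICC" that
matches the second reading (systematic share of error), so both are computed
and neither is presented as "the" ICC.

`error_reduction()` refits the model on the raw and the grade-standardized
tables and reports percentage reductions of the overall error
($\sigma^2_a + \sigma^2_e$), its systematic and its residual part, with a
reduction over a zero raw component reported as undefined rather than a
number.

The **uncertainty interval** maps rater error onto the diagnosis: per-slide
measurement errors $e_{sa} = y_{sa} - \bar y_{s\cdot}$
(`measurement_errors()`), whose 10% and 90% quantiles, added to the cut-off,
bound the THS band within which an individual rater's diagnosis is not
reproducible at 80% probability. Quantiles interpolate order statistics
(`stats::quantile` type 7); the convention is an argument because interval
bounds at fixed data depend on it. Errors from all slides (both stains) are
pooled by default, with per-stain computation available upstream by
subsetting the table.

## The rule-based image grader

`classify_pixels()` / `segment_cells()` / `score_image()` form a
transparent, deterministic stand-in for a learned cell detector, built to
exercise the full pipeline on rendered images (it is explicitly *not* a
reproduction of any trained model). Pixels are classified by HSV windows
(blue-cyan saturated → pigment, red saturated → nucleus, bright unsaturated
→ background, else cytoplasm); cell candidates are connected components of
non-background pixels after morphological closing, with components lacking a
nucleus rejected — non-macrophage distractors are anucleate in the renderer,
standing in for the real difficulty of distinguishing cell types under iron
staining. Components above `max_area` are split by watershed on the distance
transform; at default spacing this path is idle, chosen for simplicity over
segmentation fidelity. Per-cell grade comes from the pigment fraction
(pigment pixels over non-nucleus component pixels — the same denominator the
renderer's registry records), so generator and grader share one content
convention end to end, and the "algorithm" annotation set enters matching,
agreement and diagnostics exactly like a human rater's.

## Determinism and seeding

Every stochastic operation takes an explicit seed; a master seed expands
into independent substreams per slide, annotator, and stage through a string
hash (`substream_seed()`), so any single artifact can be regenerated without
replaying the study, and a full `run_pipeline()` under one seed is
byte-for-byte reproducible, including the JSON report. RNG state of the
caller is restored after every seeded operation.

## Problem sizes used in the tests and analyses

The test suite and the `analysis/` drivers run at desk scale, chosen as the
smallest sizes at which each property is meaningfully exercised: matching is
verified against a brute-force assignment oracle on 500 instances of ≤ 8
points per set; variance-component recovery uses 500 simulated 52 × 10
tables at known truth (the real design's shape); interval coverage uses
10^5 simulated errors; standardization and inflation properties use 5–12
slide studies with 300-cell annotators; the image round-trip renders six
80-cell slides across both stains and severities. The `analysis/` scripts
run the full 52-slide, 10-annotator emulation.

## What passing does and does not show

The generator reproduces the *structure* the analysis assumes — crossed
design, threshold-shift bias, selection variability, unmatched annotations,
censored chemistry — not the appearance or error magnitudes of any real
panel. Known gaps between simulation and reality:

* Real random error is dominated by within-rater grading inconsistency; the
  generator's per-cell perception noise largely averages out over ≥ 300
  cells, so its residual component is mostly cell-selection sampling. One
  visible consequence: grade standardization (which drops unmatched cells,
  shrinking each rater's cell sample) can *increase* the residual component
  in simulation while real panels saw it fall — the systematic component
  still collapses to ~0, which is the property standardization is for.
* Rendered cells are schematic (ellipse, one nucleus, uniform granules);
  scanner color variation, focus artifacts, overlapping cells and fungal
  contaminants are absent, so the image grader's near-perfect round-trip is
  an upper bound, not a claim about real whole-slide images.
* Simulated iron calibrates to a plausible 0.4–4.7 µmol/L range; assay
  mechanics are not modelled.

Real-data headline figures from rater panels (specific ICCs, accuracies,
interval bounds) depend on those panels' error magnitudes and are therefore
not reproduction targets of the simulation; the package's claims are the
protocol constants and the directional/structural properties above.
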