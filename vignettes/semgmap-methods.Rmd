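---
title: "Methods: spatial activation mapping for HD surface EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial activation mapping for HD surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgmap)
```

## The problem and the measurement model

The extensor digitorum communis (EDC) is a multi-tendinous forearm muscle
whose finger-specific compartments are believed to be driven by separate
motoneuron pools. With a high-density electrode grid wrapped around the
forearm, the spatial pattern of surface-EMG amplitude becomes a picture
of which compartment is active. `semgmap` implements the analysis chain
for such recordings: amplitude (RMS) maps per task condition, an
amplitude-weighted map centroid, a normalized map-difference statistic
(SSD), and repeated-measures group statistics, together with a synthetic
generator that emulates compartmentalized activation so every stage can
be tested without human data.

## Coordinate conventions

All analysis happens in relative forearm coordinates:

* **y (longitudinal)** — percent of forearm length from the olecranon
  process (0%) to the ulnar styloid (100%). Row *j* of *R* rows sits at
  the center of the *j*-th of *R* equal segments,
  `y_j = 100 (j − ½)/R`; row 1 is proximal.
* **x (circumferential)** — percent of forearm circumference on a
  *linear* axis with the seam (0% = 100%) on the medial side; values
  increase across the flexor side, then the extensor side, back to the
  seam. When the configured span covers the full circumference, the
  `n_cols` electrodes are spaced `span/n_cols` apart (wrap convention —
  no electrode duplicated at the seam); partial spans are spaced
  end-inclusively.

No circular arithmetic is applied anywhere: the centroid is a plain
linear weighted mean in x. This is a deliberate simplification — extensor
activity sits mid-axis, far from the seam, so the linear and circular
means coincide for realistic maps. Maps whose mass hugs the seam would
need a circular treatment that this package intentionally does not offer.

Although the physical inter-electrode distance differs between rows
(the forearm tapers), the analysis frame is the relative one; physical
geometry can be attached as metadata (`forearm_geometry`) but never
enters the statistics.

## Preprocessing

* **Filtering**: 2nd-order Butterworth band-pass (20–400 Hz default),
  applied forward and backward (zero net phase). Coefficients come from
  an analog prototype via the band-pass transform and the bilinear
  transform with prewarping; the design is validated in the test suite
  against an independently computed reference to machine precision. The
  double pass squares the magnitude response, so each band edge sits at
  half power. Filtering is applied to the continuous record, never to
  excised windows, so short-segment transients cannot sit inside an
  analysis window; 0.25 s at each record end is excluded from every
  window (`edge_trim_s`), several times the filter's longest time
  constant at the 20 Hz edge.
* **Window RMS**: the full 5-s steady contraction window, minus the RMS
  of a 2-s rest window. The rest window is taken from the rest period
  immediately preceding each contraction, ending 0.25 s before
  contraction onset, and each repetition is paired with its own rest
  before averaging — the pairing is a package decision; published
  protocols typically leave it unstated.
* **Flooring**: negative rest-subtracted values are floored at 0 by
  default (`floor_at_zero = TRUE`). Negative "activation" is physically
  meaningless and would corrupt the centroid weights (which must be
  non-negative); the flag exists so the unfloored behaviour remains
  testable and inspectable.
* **Repetitions** are averaged elementwise; the scalar effort measure is
  the mean RMS across all grid channels, and per-subject effort
  normalization divides by the subject's four-finger/high-effort value.

## The centroid

For a map `RMS_ij` on grid coordinates `(x_i, y_j)`:

$$C_x = \frac{\sum_{ij} RMS_{ij}\,x_i}{\sum_{ij} RMS_{ij}},\qquad
  C_y = \frac{\sum_{ij} RMS_{ij}\,y_j}{\sum_{ij} RMS_{ij}}.$$

It is invariant to global rescaling, always lies in the bounding box of
the strictly positive channels, and is undefined (an explicit error, not
`NaN`) for an all-zero map. All 63 channels enter the computation —
including flexor-side channels — so low-level co-activation of other
muscles is part of the measurement by design; an active-channel mask is
deliberately not applied.

## The SSD statistic

Maps are first normalized to unit maximum. For two normalized maps
`nRMS_A`, `nRMS_B`:

$$SSD = 100\cdot\frac{\sum_{ij}\,(nRMS_A - nRMS_B)^2}
  {\sum_{ij}\,(nRMS_A^2 + nRMS_B^2)}\ \%.$$

The denominator is a package decision: the common printed form of this
statistic is typographically degenerate (numerator and denominator
identical, which would force 100 everywhere). The sum-of-squares
denominator used here is the unique simple quadratic normalization that
satisfies both anchor behaviours — identical maps give 0, and maps with
*disjoint support* give exactly 100 (the cross term
`Σ nRMS_A·nRMS_B` vanishes). "Two unrelated maps give 100" is therefore
interpreted as disjoint/orthogonal support: genuinely i.i.d. random maps
have a positive cross term and score below 100 under any quadratic
normalization. The denominator is isolated in one internal function
(`ssd_denominator`) so alternatives can be swapped in and compared.
For non-negative maps the statistic is symmetric and bounded in
[0, 100]; all-zero maps are flagged degenerate and refused.

## Display interpolation

`interpolate_for_display()` performs tensor-product (bilinear) linear
upsampling by an integer factor per axis (default 6), reproducing the
original lattice exactly. It exists only for visualization: centroid and
SSD always operate on the un-interpolated 7 × 9 grid, which the test
suite asserts. "Interpolated six times" is read as a per-axis factor of
6, not six successive doublings; the factor is a parameter.

## Group statistics

`rm_anova()` implements the univariate repeated-measures ANOVA for
balanced, fully within-subject factorials (1–3 factors), computing each
effect's sum of squares by Möbius inversion over marginal means and
testing it against its own effect × subject interaction — the
conventional error-term choice for this design family. For effects with
more than one numerator degree of freedom, Mauchly's sphericity test is
computed from the covariance of orthonormal-contrast scores (p-value via
the Box two-term chi-square approximation), and when it is significant at
α = 0.05 the degrees of freedom are multiplied by the Greenhouse–Geisser
epsilon — correction *conditional* on the sphericity test, not always-on.
Replicate observations within a subject × cell (e.g. over factors not in
the requested design) are averaged first.

The test suite validates F statistics, p-values and Mauchly's W against
base R's independent multivariate-model machinery (`anova.mlm`,
`mauchly.test`); the only disagreement is in the tiny second-order term
of Mauchly's p (base R's expression uses the raw cell count where the
published formula has the contrast dimension), bounded below 5 × 10⁻³ in
the oracle test.

`tukey_pairwise()` compares all level pairs of one factor on
subject × level means with studentized-range adjusted p-values, using the
factor × subject mean square as error. With two levels this reduces
exactly to the unadjusted paired comparison. Simple-effects follow-ups
across condition combinations use `cell_contrast()` (a paired t-test
between two cells): published analyses of this kind rarely state their
exact simple-effects procedure, so the package exposes a generic facility
rather than guessing one.

## The synthetic generator: what it emulates, what it does not

Each finger compartment is a 2-D Gaussian amplitude territory on the grid
plane, `w(ch) = gain · exp(−Δx²/2σx² − Δy²/2σy²)`. The default layout
encodes the qualitative compartment geography reported for the EDC —
index territory most distal (~60% length), middle most proximal (~30%),
ring and little in between (~44–50%) and mutually close, all centered on
the extensor side — so end-to-end demos behave like real maps. Defaults
chosen where no published value exists, each fixed once:

| parameter | default | rationale |
|---|---|---|
| territory spread (σx, σy) | 12, 10 % | territories span a few electrodes of the 7 × 9 grid without covering the forearm |
| low-effort gain | 0.5 | half the high-effort drive (~30° vs ~60° extension) |
| enslaving | 0.15 adjacent, 0.05 non-adjacent | order-of-magnitude: low-level co-activation, strongest for neighbours; no quantitative published levels exist for this muscle |
| dynamic shift | (0, −3) % | small proximal territory displacement when the finger moves freely, emulating muscle-belly shortening |
| baseline noise RMS | 0.05 | 5% of a unit-gain compartment peak |
| protocol | 3 × (4 s rest + 5 s contraction) + 0.5 s tail, 2 kHz | the standard task protocol; the tail keeps the last window clear of the edge trim |
| cohort jitter | center ± 2%, gain × e^N(0,0.1), enslaving ± 0.03 | between-subject anatomical and drive variability |

Channel signals are independent Gaussian carriers, band-limited to
20–400 Hz with an inner 60–250 Hz shaping stage so that the spectrum
concentrates mid-band like real surface EMG. The shaping also matters
numerically: a carrier shaped by the analysis filter itself loses ~9% RMS
when the pipeline filters it again (the band edges are soft), while the
mid-band carrier passes with ~1% loss, keeping noise-free parameter
recovery accurate. Amplitude contributions from multiple compartments
combine root-sum-of-squares (independent sources add in power), and the
active-window RMS equals
`sqrt(Σ_c (effort · enslaving · w_c)² + noise²)` by construction.

Not modelled, on purpose: motor-unit action-potential trains, shared
sources across channels (the analysis consumes only per-channel RMS,
which is insensitive to inter-channel correlation), volume-conductor
physics, electrode artifacts, fatigue. A green end-to-end test therefore
establishes that the *pipeline* recovers the *stated amplitude model* —
it says nothing about volume conduction or motor-unit behaviour in real
tissue, and nothing about the magnitudes of real between-condition
differences.

Cohorts are generated lazily: `generate_cohort()` returns per-subject
parameter sets (a materialized 10-subject cohort would be several
gigabytes of signal), and `analyze_cohort()` streams
simulate → filter → map with flat memory.

## Numerical choices and degenerate inputs

* Baseline subtraction of root-sum-of-squares amplitudes is biased low
  when activation is comparable to noise
  (`sqrt(a² + n²) − n < a`); this is a property of the rest-subtraction
  method itself, reproduced faithfully, not corrected.
* Flooring at zero biases near-zero channels slightly positive; with the
  default noise level this moves recovered centroids by well under one
  percentage point (the parameter-recovery tests bound it).
* All-zero maps: centroid errors out; normalization flags the map
  degenerate; SSD refuses degenerate inputs.
* Seeds: every stochastic step (carriers, cohort jitter) derives its
  stream deterministically from the configured seed, the subject index
  and the condition labels via a small string hash, so recordings are
  reproducible individually, not only in generation order.
* Repeated-measures designs must be complete and balanced; unbalanced
  tables are refused rather than approximated.

## Known limitations

* Linear (non-circular) circumferential axis, as discussed above.
* The SSD denominator, while the unique choice consistent with both
  published anchor behaviours, is not guaranteed identical to every
  published implementation of "normalized SSD".
* The ANOVA layer offers no mixed-effects or between-subject extensions.
* The generator's enslaving levels are plausibility choices, not
  measurements; treat absolute SSD magnitudes from synthetic cohorts as
  illustrative only (directional orderings are the tested claims).
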