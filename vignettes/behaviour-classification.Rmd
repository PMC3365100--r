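---
title: "From sensor data to behaviour: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sensor data to behaviour: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelbehav)
```

## The problem

Bio-logging devices on free-living birds record position, instantaneous
GPS speed and short bursts of tri-axial body acceleration. To turn such
records into ecology — where, when and for how long an individual flies,
forages or rests — each sensor record must be classified into a
behaviour. `accelbehav` implements a supervised workflow built around a
shorebird field design: a GPS fix every 10 (or 30) minutes, each followed
by a 3 s acceleration segment sampled at 20 Hz (60 samples per axis, in
g) on the surge (X, anterior–posterior), sway (Y, lateral) and heave (Z,
dorso-ventral) body axes, with simultaneous visual observations of the
tagged birds providing the training labels.

The pipeline has five stages, each a package module:

1. **Synthetic study generation** — emulates the full field campaign so
   every downstream stage is testable without field data.
2. **Merging** — joins sensor records to time-stamped visual
   observations, allowing for a bounded recording delay, and filters
   records that cannot be linked unambiguously.
3. **Feature extraction** — 16 predictors per record (Table-2 style):
   GPS speed; posture angles; per-axis mean and maximum dynamic body
   acceleration and their sum (ODBA); per-axis dominant power spectral
   density and its frequency.
4. **Classification trees** — CART with maximal growth, cost-complexity
   pruning, 10-fold cross-validation and one-standard-deviation tree
   selection; three model configurations (S3, SA3, SA8).
5. **Time budgets** — a fitted model applied to an unlabeled deployment,
   stratified by diel phase (NOAA sunrise/sunset) and habitat
   (territory / salt marsh / mudflats).

## Feature definitions and numerical choices

**Static/dynamic separation.** The static (gravity) component is the
per-axis mean over the whole 3 s segment; the dynamic component is the
remainder, so `static + dynamic` reconstructs the raw signal exactly. A
centred running mean is available (`method = "running-mean"`) for longer
segments; for a 3 s window the segment mean is the standard choice and
keeps the spectral features independent of an arbitrary smoothing
bandwidth.

**Posture.** Angles come from the *normalized* static vector, which
makes them robust to calibration gain offsets: `pitchX = asin(sx)`,
`rollY = asin(sy)`, `pitchZ = acos(sz)` (degrees). A horizontal logger
gives all zeros; the mounting convention is fixed so that an anterior-up
(standing) posture gives negative `pitchX`. A zero static vector is a
degenerate posture and raises an error rather than returning an
arbitrary angle.

**ODBA.** `odba_axis` is the mean absolute dynamic acceleration per
axis, `mdba_axis` the maximum, and `odba = odbaX + odbaY + odbaZ`. These
satisfy `0 <= odba_axis <= mdba_axis`, scale linearly under amplitude
scaling, and for a sinusoid of amplitude *a* over whole cycles
`odba_axis -> 2a/pi`.

**Spectra.** The dominant power spectrum `dps` is the maximum of a
one-sided rectangular-window periodogram on the grid `k * rate / 60`,
`k = 1..30` (DC excluded), normalized so that `sum(PSD) * df` equals the
series variance (Parseval, enforced to 1e-9 in tests). `fdps` is the
frequency at that maximum; ties, which arise only to numerical
precision, break to the lower frequency. An all-constant series reports
`dps = 0` with a degenerate flag rather than an undefined frequency.
Units are g² Hz⁻¹ throughout.

## The tree engine

Trees are grown by greedy binary partitioning on continuous predictors,
minimizing weighted Gini impurity (entropy is available). Candidate
thresholds are midpoints between consecutive distinct observed values,
which makes fitted thresholds deterministic and comparable across
engines to within the resolution of the data. Ties in impurity go to the
earlier predictor column, then the lower threshold — a deterministic
convention that matters when several predictors separate the classes
equally well (see below). Missing predictor values are routed down the
branch that received the majority of the node's observed values; full
surrogate-split machinery is deliberately out of scope.

The maximal tree (`min_split = 2`, `min_leaf = 1`) is pruned by
weakest-link cost-complexity pruning; on trees with up to four internal
nodes the path is verified against exhaustive enumeration of all pruned
subtrees. Each complexity on the full-data path is scored by k-fold
cross-validation (unstratified uniform fold assignment from a stored
seed; stratified assignment available), with each fold's tree evaluated
at the geometric-mean representative of the alpha interval — the
standard device for comparing pruning sequences across trees. The
reported SE is the standard deviation of the n held-out 0/1 losses over
`sqrt(n)`. Tree selection follows the one-standard-deviation rule: the
smallest subtree whose CV error is within one SE of the minimum.

Because printed per-class accuracies in field studies can come either
from refitting on all data or from pooled held-out predictions, fitted
bundles report both resubstitution and CV-pooled confusion matrices.

## Model configurations

* **S3** — speed only, 3 classes (`Fly`, `Terrestrial locomotion`,
  `No locomotion`). Records without a speed measurement are excluded
  (`n_used` reports this).
* **SA3** — all 16 predictors, 3 classes. Records with missing speed are
  kept; a split on speed would route them by the majority branch.
* **SA8** — all 16 predictors, 8 main-behaviour classes.

Reclassification into the 3-class scheme operates at *sub-behaviour*
level because two main behaviours (Aggression, Handle) contain both
locomotory and stationary sub-behaviours; the 8-class scheme maps each
sub-behaviour to its main behaviour. All individuals are pooled and
weighted equally.

## What the synthetic generator emulates — and what it does not

Each behaviour's 3 s segment is generated as: static gravity from a
behaviour-specific pitch (with between-segment jitter, sd 4°), one
sinusoid per axis, optional brief 8 Hz transients ("bursts": prey
handling, pecking), and white noise. Defaults encode the qualitative
contrasts reported for shorebirds: flight has high-amplitude dynamics on
all axes with a fast (6 Hz) heave periodicity; foraging is slower
(2 Hz), variable in intensity, with occasional bursts; body care moves
the sway/heave axes but barely the surge axis; standing and sitting are
still and differ only in pitch sign (−20° vs 0°).

Four variability terms are as important as the means, because a greedy
tree will latch onto *any* perfectly separating feature:

* **GPS speed error.** Reported speed = true speed + N(0, 0.3 m/s),
  truncated at zero, plus an 8% chance of a gross outlier (uniform
  0–5 m/s). Instantaneous GPS speed cannot resolve slow terrestrial
  movement, and occasional dropouts corrupt even flight speeds — the 8%
  rate matches the observed misclassification of flight by a pure speed
  threshold in shorebird field data. Without this, speed would be a
  perfect classifier and the speed-only model could not be worse than
  the acceleration model, inverting the qualitative structure the
  generator is meant to emulate.
* **Posture jitter** (sd 4°), so that pitch separates genuinely postural
  contrasts (sit vs stand) but not locomotion modes.
* **Per-segment movement intensity** (uniform scale on all amplitudes,
  e.g. 0.5–1.5 for foraging), so dynamic-magnitude features of flight
  and foraging overlap as they do in real data.
* **Surge/sway frequency jitter** with a fixed heave frequency: the
  flapping / body-bob periodicity is most consistent dorso-ventrally, so
  heave spectral features are the reliable flight discriminator.

With these defaults the fitted 3-class acceleration model splits on a
surge dynamic-magnitude predictor (moving vs not moving) and a heave
spectral predictor (fly vs terrestrial locomotion) — the same decision
geometry as the field-calibrated reference trees
(`reference_speed_tree()`, `reference_accel_tree()`). Note that the
engine's tie-break may select `mdbaX` rather than `odbaX`, and `fdpsZ`
rather than `dpsZ`: under the synthetic signal model several members of
each family separate equally well, and the earliest column wins.

Behaviour sequences follow a first-order Markov chain. The default
transition matrix is the *independence chain* (every row equals the
stationary law, default 2% fly / 40% forage / 13% body care / 25% stand
/ 20% sit), so the self-transition probability of foraging is 0.40
(mean bout ≈ 17 min at 10-min fixes) and recovered time budgets track
the stationary frequencies closely over a month-long deployment —
sampling fluctuations stay within about ±2 percentage points per diel
phase. Stickier matrices give more realistic long roosting bouts but
inflate that sampling variance several-fold; pass one via `transition`
if bout structure matters more than budget-recovery precision.
Movement is a correlated random walk (step = speed × fix interval,
capped and reflected at the landscape boundary) over a two-polygon
coastal strip: terrestrial salt marsh with the nests to the north,
intertidal mudflats to the south. Stationary behaviours drift the bird
back to its nest.

Things the generator deliberately does **not** emulate: biomechanically
realistic wingbeat waveforms, tidal forcing of habitat use, diel
behaviour modulation, GPS position error beyond additive noise, and
within-segment behaviour changes (one behaviour per 3 s segment;
transitions happen at fix boundaries). Consequently, passing tests show
that the *pipeline* recovers structure that is present; they do not show
that real oystercatcher data are this separable — field CV errors are
an order of magnitude larger than the synthetic ones.

## Merging rules

An observation log is a sequence of behaviour-change times. Each record
opens an interval lasting until the next record, or until the session
ends (last record + 30 min, the length of an observation session). A
segment is labeled when exactly one interval contains it entirely.
Because the handheld logger could record a change up to 10 s late, every
interval is widened by `max_delay_s` on both sides; if more than one
widened interval could cover a segment, the true behaviour during that
segment is uncertain and the record is flagged ambiguous. Filtering
removes ambiguous and unlabeled records, duplicate `(bird, time)` keys
and malformed segments, reports counts per reason, and is idempotent.

## Time budgets

Habitat: a fix within 150 m (haversine) of the bird's nest is
*territory*; otherwise the polygon class decides (*salt marsh* for
terrestrial, *mudflats* for intertidal), with territory taking
precedence and out-of-map fixes flagged `unclassified` rather than
dropped. Diel phase uses NOAA solar sunrise/sunset at the fixed study
coordinates (53.47 N, 6.23 E) — not per-fix positions — with the
half-open convention that a fix exactly at sunrise is day and exactly at
sunset is night. Budgets are count-based: each fix carries equal weight
regardless of fix interval, so mixing 10- and 30-min regimes biases
budgets toward the denser regime — a known limitation of count-based
proportions.

## Problem sizes used in the automated checks

The test-suite fits use 80–100 segments per class; the acceptance
analysis uses 300 segments per class for the 3-class models, 150 per
class for the 8-class model, and one bird over 31 days at 10-min fixes
(4,464 records) for the deployment stage. These sizes keep the full
protocol (maximal growth + pruning + 10 extra fits for cross-validation
per model) comfortably fast while leaving the sampling error of recovered
budgets well inside the ±3-point recovery bound.
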