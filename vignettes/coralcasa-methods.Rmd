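---
title: "Methods: how coralcasa measures coral sperm motility and concentration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how coralcasa measures coral sperm motility and concentration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralcasa)
```

## The measurement problem

Computer-assisted sperm analysis (CASA) films a thin, fixed-depth counting
chamber at high frame rate, detects sperm heads in every frame, links the
detections into per-cell tracks, and summarises each track into velocities
and a motility class. For coral sperm — assessed in field labs during brief
spawning windows, often on darkfield rather than phase optics — the settings
that make this work differ substantially from mammalian defaults, and a
handful of capture artefacts (dust blooms, chamber drift, stale wells) can
silently corrupt the numbers. `coralcasa` implements that measurement chain
as an open, testable pipeline, together with a ground-truthed simulator so
every stage can be validated without a microscope.

The default configuration describes a 60 Hz, 0.75 s capture (45 frames) of a
20 µm-deep chamber at 1 µm/px, with a 5–150 µm² head-area gate, a
maximum inter-frame travel ("Cell Travel Max") of 10 µm, a static rule of
0.8 × head diameter, and slow/motile/progressive velocity bins split at
20 and 80 µm/s.

## Detection

Each frame is thresholded and 8-connected bright components become candidate
heads; components outside the head-area gate are discarded, and centroids
are intensity-weighted. Tails are never segmented (the equivalent of keeping
the instrument's *Static Tail Filter* off): if detection required a visible
tail, tail-less static heads would vanish, under-counting concentration and
inflating motility percentages. The settings object therefore refuses
`static_tail_filter = TRUE` outright.

Thresholding is Otsu's method per frame by default, with a fixed override
(`fixed_threshold`). A caveat that matters for absolute head sizes: on a
Gaussian intensity spot, the area enclosed by a threshold depends strongly
on where the threshold sits. Otsu on a background-dominated darkfield frame
settles well below the half-maximum level, so measured areas run roughly
1.5–2× the half-maximum area. Counting and tracking are unaffected, but the
static rule scales with the measured head diameter, so a calibrated fixed
threshold (as an operator would set against their optics) is preferred when
absolute sizes matter; the end-to-end tests do exactly that.

### Bloom masking

Dust or salt on a cassette produces saturated static blooms that seed false
tracks. A pixel whose *temporal minimum* intensity reaches the
`mask_percentile` (default 0.9999) quantile of the global intensity
distribution is masked, and the mask is dilated by one maximum head
diameter. The logic: a saturated bloom sits at the very top of the intensity
distribution in *every* frame, while even the slowest swimming cell falls
below its own peak at some point of a 45-frame capture, and a static cell's
jittering core dips below the brightest cell peaks. The rule deliberately
catches only saturation-level artefacts; static dirt dimmer than the
brightest cells is not caught and will instead surface as extra static
tracks. In the simulator, saturated pixels carry no noise (a clipped sensor
does not fluctuate), which is what keeps a bloom's temporal minimum at the
ceiling.

## Tracking

For each consecutive frame pair the linker computes an exact
minimum-total-distance one-to-one assignment (Hungarian algorithm on a
padded square matrix) among detection pairs within `cell_travel_max_um`.
The bound is closed — a step exactly equal to it links (with a 1e-9
relative epsilon so exact arithmetic survives floating point). Unassigned
detections open new tracks; there is no gap closing, so a missed frame
always starts a new track. This reproduces the documented failure mode of
the parameter: at 60 Hz with a 5 µm bound, 300 µm/s is the last unsplit
speed, and `split_risk_report()` computes that ceiling and warns when it
falls below the fastest velocity expected for the species profile.

An exact assignment was chosen over greedy nearest-neighbour because it is
deterministic and verifiable: the tests compare it against exhaustive
enumeration over all partial matchings on hundreds of small instances.
Whether commercial trackers close one-frame gaps is unknown; this
implementation never does, which keeps behaviour predictable and the oracle
simple (a documented divergence).

## Kinematics and classification

For each track of at least `min_track_frames` (default 30 of 45):

* **VCL** — raw point-to-point path length / duration;
* **VAP** — path length of the trajectory smoothed by a centred moving
  average (window `smoothing_frames = 5`, odd, endpoints preserved by
  window shrinkage) / duration;
* **VSL** — net first-to-last displacement / duration.

Endpoint-preserving smoothing guarantees VSL ≤ VAP ≤ VCL (tested to
1e-9 µm/s on thousands of random tracks). A track is **static** when its
maximum excursion from its first position stays below
0.8 × head diameter for the whole capture (head diameter is the
circular-equivalent `2·sqrt(area/π)` of the track's mean detected area).
Non-static tracks are binned on VAP: `< 20` µm/s slow, `20–80` inclusive
motile, `> 80` progressive.

Three decisions here were genuinely open:

* *Which velocity the bins apply to.* The 20/80 cut-offs are stated without
  naming a metric; VAP is the conventional CASA binning basis and is the
  default, but `classification_velocity` accepts `"vcl"` or `"vsl"`.
* *Whether 80 µm/s is motile or progressive.* "Between 20 and 80" is read
  as closed at both ends, forced by "less than 20" and "greater than 80"
  for the neighbouring bins.
* *`min_track_frames` = 30.* No minimum is stated; tracks covering less
  than two-thirds of the capture give noisy class calls (a slow cell
  observed briefly looks static), so they are excluded from motility
  percentages while still counting toward concentration. Configurable.

## Concentration and aggregation

The imaged field observes `area × depth` of suspension, so sample
concentration is mean detections per frame divided by that volume, times
the dilution factor. The mean per-frame *detection* count is used rather
than the track count because it is invariant to track fragmentation. Field
concentrations are averaged per sample; total motility is the non-static
percentage of classified tracks; **motile concentration** — total
concentration × total motility — is the headline metric, because a motility
percentage means little without the density of cells behind it.

Cross-instrument formulas are implemented as printed protocols:
the haemocytometer equation literally as `CC × N × CD × D` cells/mL — the
multiplication by `N` (number of chamber cells counted) is unusual for a
total count, so the conventional mean-per-cell reading `CC / N × CD × D` is
available behind `mode = "mean_per_cell"`, and neither is silently
corrected — and the flow-cytometer conversion as gated events × dilution
× 100 per mL for the standard 10 µL acquisition.
`dilution_plan()` finds the smallest serial ten-fold dilution landing in a
target band (the 1 : 100 answer for 10⁹ cells/mL into 1–3 × 10⁷); a
continuous factor is available with `series = NULL`, and a sample below
range is reported as such since it cannot be concentrated.

## Quality control

All QC rules are pure functions that return flags plus the diagnostics that
justify them: fewer than 5 fields or 200 cells (`insufficient_*`);
concentration outside the 8 × 10⁶–5 × 10⁷ cells/mL working range or the
1 × 10⁷–3 × 10⁷ ideal band; uniform chamber flow; stale wells (capture more
than 120 s after loading — no number is published for the edge-migration
time-scale, so the default is deliberately conservative and configurable);
and tracking split risk.

Drift is estimated as the component-wise **median** of all per-step
displacement vectors × frame rate — median, not mean, so a genuinely motile
subpopulation cannot masquerade as flow — and flagged above 10 µm/s (half
the slow/motile bound; the artefact is described only qualitatively).
Because steps within one persistent track are highly correlated, the
estimator needs a full sample's worth of tracks (hundreds of cells across
fields, which the capture protocol guarantees) for a stable null; on single
sparse fields the median can wander by several µm/s.

## The simulator: what it emulates and what it does not

`simulate_tracks()` places cells as a homogeneous Poisson process at the
requested concentration and moves each by its class model: static cells
jitter (sd 0.3 µm/frame, rejection-sampled inside 0.8 × head diameter);
slow and motile cells follow a persistent random walk; progressive cells
swim near-straight. Heading increments are Gaussian with sd
`2 × (1 − persistence)` rad/frame (defaults 0.85 / 0.85 / 0.95 for
slow / motile / progressive). Uniform drift can be injected, and saturated
bloom discs (larger than the head gate) can be added.

Choices worth recording:

* **Speed ranges** default to 8–18 / 25–75 / 85–150 µm/s — at least 5 µm/s
  inside the classification bins, so a cell's intended class and its
  classified class coincide; no per-class speed distributions are published
  for coral species, so these are stated placeholders, configurable per
  species, and were fixed before the recovery tests were run.
* **Head areas** default to 10–25 µm² (heads ~3.6–5.6 µm across), inside
  the detection gate and sized so that a slow cell's travel exceeds its own
  0.8 × head-diameter static radius.
* **Buffered spawning.** Cells spawn in a margin around the imaged field
  (margin = max speed × duration + drift), so cells enter as well as leave
  and the in-field count at every frame stays Poisson with mean
  concentration × field volume. Without entrants, per-frame counts decay
  ~4 % over 0.75 s at the default speed mix and concentration estimates
  would carry a bias that is an artefact of the simulation, not of the
  pipeline. A truth track is still a maximal run of consecutive in-field
  frames — cells leaving the field end their track.
* **Rendering** draws each head as a 2-D Gaussian whose area at the
  half-maximum level equals its head area
  (`sigma = sqrt(area/π)/sqrt(2 ln 2)`), on a uniform background with
  additive Gaussian noise. There is no point-spread function, no depth
  blur across the 20 µm chamber, and no photon/shot statistics — darkfield
  optics are out of scope. Rendering errors out if the calibration makes a
  spot sigma smaller than one pixel.
* **Drift and the static invariant.** Drift is added to *all* positions
  (it is a bulk-flow artefact); a static-labelled cell under drift will
  exceed its 0.8 rule and be classified as moving — intended behaviour,
  which is exactly why drifting captures must be flagged and retaken.

A green recovery test therefore establishes that the pipeline measures the
stated world correctly — not that the stated world is coral sperm. Real
captures add out-of-focus swimmers, intensity flicker, tail visibility,
wall interactions and species idiosyncrasies that the simulator does not
model.

`synth_fert_dataset()` emulates fertilisation trials: log10(motile cells
per egg) uniform over a configurable range (default 10^2.9–10^4.6,
spanning published cryo-to-fresh dosing), success linear in the log dose
(default slope 32 points per decade, intercept −52, residual sd 12 points,
clipped to [0, 100]), egg counts 28–90 per bowl, and sperm volumes
back-solved so each record's dose is exact. `fert_theoretical_r()` gives
the generator's population correlation in closed form, which the tests
compare against the sample Pearson r through a Fisher-z interval.

## Numerical conventions

Frames are 0-based; coordinates are µm from the top-left pixel corner with
y downward (pixel centres at half-integers); durations use `(n−1)/rate`.
Percentages are reported to 0.1, concentrations to 3 significant figures.
Ties at classification bin edges go to motile; a step exactly at the
linking bound links. All simulator randomness flows through explicit seeds
and `.Random.seed` is restored afterwards, so the same seed is
bit-reproducible without disturbing the caller's RNG.

## Known limitations

* TIFF stacks and detection CSVs are the supported inputs; AVI decoding is
  out of scope (no suitable decoder available as an R dependency).
* The TIFF layer is a minimal baseline implementation (uncompressed 8/16-bit
  grayscale), cross-checked against an independent reference reader in the
  tests; compressed or multi-channel files are rejected, not guessed at.
* The bloom mask only catches saturation-level artefacts.
* Gap closing, collision disambiguation beyond optimal assignment, ALH/BCF
  and hyperactivation metrics are deliberately absent.
* The haemocytometer equation's published form is ambiguous; both readings
  are implemented and the literal one is the default (see above).
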