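---
title: "Models and methods behind smadtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smadtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

smadtrace studies how a destabilised fluorescent transcriptional reporter
— superfolder GFP fused to a PEST degron ("dynGFP"), driven by multimerised
SMAD3/4-binding CAGA elements — reads out TGF-β/SMAD3 signalling dynamics
in single living cells, and how well such dynamics can be recovered from
two-channel time-lapse microscopy by Gaussian-model nuclei tracking.  This
vignette explains the models, the defaults, and the design decisions; the
analysis scripts under `analysis/` run the pipeline end to end.

## The reporter expression model

Per cell, reporter expression is a linear three-pool system driven by a
pathway-activity input $S(t) \in [0, 1]$:

$$
\frac{dm}{dt} = \alpha\,S(t) - \delta_m m, \qquad
\frac{dp}{dt} = \beta(t)\, m - (\kappa + \delta_p)\, p, \qquad
\frac{df}{dt} = \kappa\, p - \delta_p f,
$$

with mRNA $m$, immature (non-fluorescent) protein $p$ and mature
fluorophore $f$, all zero at $t = 0$.  This is the minimal structure in
which the two protein-engineering knobs of a destabilised reporter appear
as separate rates: superfolding mutations accelerate maturation
($\kappa$), and the PEST degron accelerates proteasomal turnover
($\delta_p$).  We apply $\delta_p$ to the immature and mature pools alike
— whether the degron acts on unfolded protein is not observable in the
data this model is built for, and the symmetric choice keeps the decay of
total protein single-exponential once translation stops; users probing
this assumption can scale the two contributions through custom
`reporter_params()`.

Perturbations are timed events with distinct semantics:

* `ligand_on(t, level)` / `ligand_off(t)` set $S(t)$ (ligand addition and
  washout); `ligand_on` events are shifted by a cell-intrinsic
  `onset_delay`.
* `kinase_inhibitor_on(t)` models a TGF-β type I receptor kinase inhibitor
  (SB505124-like): transcription stops ($S = 0$ thereafter) but existing
  mRNA persists, decaying at $\delta_m$, and keeps being translated — so
  fluorescence falls slowly at first.
* `translation_block_on(t)` models a cycloheximide chase: $\beta = 0$
  immediately, the immature pool drains at $\kappa + \delta_p$, and the
  mature pool then decays at $\delta_p$ — the cleanest window on the
  protein half-life.

The system is integrated with `deSolve::lsoda` restarted at every event
boundary (relative tolerance $10^{-10}$); because the system is linear
with piecewise-constant coefficients, the solution is also checked in the
test suite against closed-form steady states at $10^{-6}$ and against a
fixed-step explicit Euler reference at Euler's own accuracy level
($10^{-3}$ at step 0.01 min — a first-order method cannot be used as a
$10^{-6}$ oracle, so the tighter comparisons use the closed forms).

**Presets.** `reporter_preset()` encodes three variants sharing
$\alpha = 1$, $\beta = 1$, $\delta_m = \ln 2/120$ min⁻¹: dynGFP
(maturation half-time 6 min, protein half-life 227 min = 3.78 h), GFP
(40 min, 30 h) and TdTomato (60 min, 30 h).  With these values a 4-h
translation chase from steady state leaves ≈ 49% of the dynGFP signal
(the single-exponential tail alone gives 48%), receptor-kinase inhibition
leaves ≈ 75% at the same time point, an 8-h chase drops dynGFP by ≈ 77%
versus ≈ 17% for the stable variants, and the rise/decay orderings across
the three variants follow the destabilised-reporter design.  The
half-life numbers reported by the package are always computed, not
stored: `estimate_half_life()` fits $\ln(\text{fraction remaining})$
versus chase time through the origin (for a single point $(t, q)$ this is
$t \ln 2 / \ln(1/q)$; 48% at 4 h gives 3.78 h, which rounds to the
reported ~4 h).

## The synthetic population

`simulate_population()` generates the ground truth the imaging pipeline
is benchmarked against: a clonal population with early, late and
non-responding subpopulations (default fractions 0.45 / 0.35 / 0.20 —
such assays show all three groups clearly populated but do not pin
down fractions, so these were fixed once so that every cluster is well
represented).  Responder onset delays are normal, truncated at zero,
centred at 300 min (early, SD 25 min) and 700 min (late, SD 40 min);
non-responders never activate.

**The trace model of the movie population.** For the movie simulations
the per-cell pathway input is a transcriptional burst: $S$ jumps to 1 at
the cell's onset delay, stays for 18 min, then relaxes to a sustained
3% of the burst level; reporter transcript turnover in this context is
fast (half-life 4 min).  This parameterisation was fixed by forward
calculation against what the generator must emulate: measured trace
onsets (first sustained half-range crossing) within a few frames of the
generating delays at 300/700 min, single-cell traces that peak shortly
after onset (so early responders peak before late responders), and a
sustained well-level signal at 24 h for the screening statistics.  A
slowly-decaying mRNA (the 2-h preset value, appropriate for bulk chase
experiments) would smear the trace half-rise hundreds of minutes past
the activation time and make the generative onset unidentifiable from
the movie — the defining feature of the fast reporter is precisely that
it does not do this.  All three knobs are exposed in
`population_reporter()`.

**Motion.** Cells perform a reflecting-boundary Gaussian random walk
(default step SD 1 px/frame at 1 frame / 3 min) with soft excluded
volume: after every step, nucleus pairs closer than `exclusion_radius`
(default 10 px, about one nuclear diameter for the default σ = 3 px
nuclei) are pushed apart symmetrically.  Independent walks would let two
nuclei sit exactly superimposed for tens of frames — a configuration
real nuclei cannot adopt and that no tracker could disambiguate even in
principle; the interaction is the minimal correction and can be disabled
(`exclusion_radius = 0`).

**Rendering.** The nuclear-marker channel sums isotropic 2D Gaussians
(width `nucleus_sigma`, cell-to-cell lognormal variation of width and
amplitude) on a uniform background; the reporter channel renders a
Gaussian spot at the nucleus position (traces are read through nuclear
masks, which is where this assay design reads the reporter) with peak
amplitude `photons_per_unit ×` the true trace.  Every pixel's expected
value is replaced by Poisson counts plus Gaussian read noise, clipped
and quantised to 16 bits.  Noiseless renders skip the quantisation so
they can serve as exact oracles for detection and extraction tests.  The
defaults (250 cells on 512 × 512 px, 480 frames) are a proportional
scale-down of a wide-field acquisition (a ~2.5 × 3.5 mm field holding
thousands of cells); full-scale settings remain valid configuration.

What the generator deliberately does not emulate: cell division and
death, confluency growth, photobleaching, cytoplasmic reporter
localisation (an annulus read-out would need a cytoplasm model), uneven
illumination, and focus drift.  Passing tests therefore demonstrate
correctness of the algorithms under the stated imaging model, not
robustness to every artefact of real microscopy.

## Nuclei detection and tracking

Detection models each nucleus as an axis-aligned 2D Gaussian plus local
background.  Candidates are local maxima above the frame median plus
`min_amplitude` (default 50 counts ≈ 5 noise SDs), suppressed within
`min_separation` px (default 4); each is refined by Levenberg–Marquardt
least squares over a window of ~6× the initial width.  Two mixture
refinements make this a Gaussian-mixture detector in the regimes that
matter: a fitted width inflated beyond 1.2× the nominal width — the
signature of two sub-resolution nuclei blending into one unimodal spot —
triggers a two-component re-fit seeded along the principal axis of the
local intensity moments, accepted only when it clearly reduces the
residual (merged pairs reduce it several-fold; genuine single nuclei do
not); and overlapping accepted detections are re-fitted jointly with a
shared background, with sanity bounds so a failed joint fit can never
degrade good single fits.

Linking realises Bayesian frame-forwarding as maximum-a-posteriori
assignment.  The transition prior factorises over displacement
(per-axis SD `pos_sd`, default 2 px), log-width change (SD 0.2) and
log-amplitude change (SD 0.3); minus its log gives the link cost, gated
at 9 (a combined ~3σ excursion).  Each frame solves the gated linear
assignment problem exactly (Hungarian algorithm on the dummy-augmented
matrix, decomposed over connected components of the gated graph); the
objective — matched costs plus one gate penalty per unmatched detection —
is the standard formulation, and the test suite verifies optimality
against exhaustive enumeration for small frames.

`build_tracks()` chains the assignments with two recovery mechanisms.
Tracks may re-claim a detection after up to `max_gap` frames (default
10) with the positional prior widened by √gap.  And when the image stack
is available, every track left unmatched *forwards its Gaussian*: the
model is re-fitted on the new frame seeded at the last position, and the
guided fit is adopted (with the track's reference shape and a clamped
amplitude) when the displacement is plausible and the fit still looks
like a nucleus.  This keeps both identities alive while two nuclei
transiently blend into one spot.  Identity cues are protected by keeping
per-track reference amplitude and shape as slow exponential averages
over real detections only, so that at the end of an encounter the
assignment can redistribute the two reappearing detections by amplitude
rather than by coin flip.  Tracks whose completeness — detections per
movie frame — falls below 0.8 are discarded; the same 80%-coverage rule
defines "successfully tracked" in `tracking_fraction()` (a cell counts
as tracked when a single track stays within the 5-px match radius in at
least 80% of its frames, so a mid-movie identity swap fails both cells
involved).

## Traces, clustering, classification

Reporter traces are the mean pixel value over each track's elliptical
nuclear mask (half-axes 2σ, using the track's median fitted widths)
minus the per-frame background (median of all mask-free pixels).  Gap
frames are linearly interpolated.  Per-cell min–max normalisation maps
each trace to [0, 1] (a constant trace maps to zero), and whole
normalised traces are clustered agglomeratively under Euclidean distance
(average linkage by default — the robust choice for time-series shapes
when no linkage criterion is otherwise dictated; Ward and complete are
available), cut at k = 3.

Classification deliberately does not trust the clustering for the
non-responder call: a cell is a non-responder when the dynamic range of
its smoothed trace (9-frame running mean) does not exceed 3× the median
frame-to-frame absolute difference of its raw trace, or when it never
sustains a half-range crossing for 2 consecutive frames.  The smoothing
matters: over 480 frames the raw range of pure noise is ~6.6σ and would
defeat the 3×-median-difference floor, while the smoothed range (~2.2σ)
sits safely below it, and genuine responses are two orders of magnitude
larger.  Remaining clusters are ranked by median onset — first sustained
crossing of half the normalised range, the operational form of a trace
"going up" at some time — and mapped to early/late against the midpoint
of the extreme clusters' medians, which handles any k ≥ 2.  Peak times
are argmax of the smoothed trace at or after onset.

## Screening statistics

The assay-quality module mirrors plate-level practice: the positivity
cut-off is the 99.5th percentile of matched unstimulated controls
(interpolated order statistic), percent positive counts strict
exceedances, time-course areas use the trapezoid rule, and
signal-over-background divides stimulated by control mean intensity.
Z′ is the standard screening factor
$1 - 3(\sigma_+ + \sigma_-)/|\mu_+ - \mu_-|$ on replicate well-level
readouts (sample SDs); the quality bar for an excellent assay is
s/b > 2 together with Z′ > 0.5.  Z′ is meaningful only on well
replicates — on per-cell values the 20% non-responding subpopulation
alone caps Z′ below zero — so `simulate_screen()` simulates replicate
wells (default 8 per condition) whose readout is the confluency-corrected
field intensity (mean per-cell intensity including background) under a
4% lognormal well-to-well technical factor, a typical plate-assay
variation.  With the package defaults the simulated 24-h screen gives
s/b ≈ 2.9 and Z′ ≈ 0.7.

## Numerical and testing choices

Problem sizes in the test suite were chosen at desk scale: unit tests
run on fields of ≤ 220 px and ≤ 60 frames where analytic oracles are
exact, and the end-to-end checks run the full default movie (250 cells,
480 frames) for a handful of seeds.  Determinism is strict: every stage
draws from a named substream of one base seed, so any stage reproduces
bit-exactly in isolation.  Degenerate inputs follow explicit
conventions — constant traces normalise to zero, empty schedules mean no
induction, merge ties in clustering follow `stats::hclust`'s
lowest-index rule, and quantiles use the type-7 interpolated order
statistic throughout.

Known limitations worth restating: the tracker assumes nuclei are
Gaussian-like blobs without division or disappearance; the classifier
assumes responses are monotone-rise-then-decay at the trace level;
the mask-mean photometry wobbles by a few percent with sub-pixel mask
position (exact proportionality to the true trace holds only to that
level); and all acceptance-level results are statements about the
simulated imaging model, not about any particular microscope.
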