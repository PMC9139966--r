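# smadtrace

Single-cell analysis of dynamic TGF-β/SMAD3 transcriptional reporters.

Destabilised fluorescent reporters — superfolder GFP fused to a PEST
degron ("dynGFP") downstream of multimerised SMAD3/4-binding CAGA
elements — make TGF-β-induced transcription visible in single living
cells with hour-scale resolution, because the fluorophore both matures
quickly and is degraded quickly (half-life ~4 h, versus >24 h for
conventional GFP/TdTomato reporters).  smadtrace implements the
computational side of such an assay end to end:

* **Reporter kinetics** — a deterministic three-pool model
  (mRNA → immature protein → mature fluorophore),
  `dm/dt = αS(t) − δ_m m`, `dp/dt = βm − (κ + δ_p)p`,
  `df/dt = κp − δ_p f`, with perturbation schedules for ligand
  addition/washout, receptor-kinase inhibition (transcription off, mRNA
  persists) and cycloheximide chase (translation off), plus half-life
  estimation from chase measurements.
* **Synthetic microscopy** — a ground-truth generator for motile cell
  populations with early (~300 min onset), late (~700 min) and
  non-responding subpopulations, rendered into noisy two-channel
  16-bit time-lapse stacks (nuclear marker + reporter; Poisson and read
  noise).
* **Nuclei tracking** — per-frame 2D Gaussian detection (with mixture
  splitting of blended nuclei), Bayesian frame-forwarding realised as
  optimal gated assignment under continuity priors on position, shape
  and intensity, gap closing, and guided Gaussian forwarding through
  close encounters.
* **Trace analysis** — extraction through nuclear masks, min–max
  normalisation, Euclidean hierarchical clustering, early/late/non
  responder classification with onset and peak statistics, heatmaps.
* **Screening metrics** — positivity cut-offs, percent positive, AUC,
  signal-over-background and the Z′ factor
  (`1 − 3(σ₊+σ₋)/|μ₊−μ₋|`).

## Worked example

```r
library(smadtrace)

# half-life from a single chase point: 48% of signal left after 4 h
estimate_half_life(4, 0.48)
#> [1] 3.777527        # reported as ~4 h

# simulate, render and track the default movie (250 cells, 24 h at 3 min)
pp  <- population_params(seed = 7)
pop <- simulate_population(pp)
stk <- render_frames(pop, imaging_params())
det <- detect_stack(stk, channel = 1)
trk <- build_tracks(det, link_priors(), stack = stk, channel = 1)
tracking_fraction(trk, pop)
#> [1] 0.964           # fraction of cells covered >=80% by a single track

# classify responders from the extracted traces
tr    <- extract_traces(trk, stk, gfp_channel = 2, frame_interval = 3)
cl    <- cluster_traces(tr$norm, k = 3)
feats <- classify_responders(tr, cl)
table(feats$responder_class)
#> early  late   non
#>    99    96    49
median(feats$onset_min[feats$responder_class == "early"], na.rm = TRUE)
#> [1] 315             # generating early-onset mean: 300 min

# screening quality of the simulated 24-h assay
sc <- simulate_screen(population_params(n_cells = 150))
z_prime(sc$value[sc$condition == "stimulated"],
        sc$value[sc$condition == "unstimulated"])
#> screen stats: avg+ 297.4 (sd 15.8), avg- 103.6 (sd 2.79), s/b 2.87, Z' 0.712
```

The numbers mean: a single 4-h chase measurement pins the dynGFP
half-life at 3.78 h; on the default synthetic movie 96% of cells are
followed by a single track through ≥80% of the frames; the classifier
recovers the three designed response groups with onset medians within a
few frames of the generating 300/700-min means; and the simulated
well-level screen clears the usual assay-quality bar (s/b > 2,
Z′ > 0.5).

The numbered scripts under `analysis/` run these steps as a narrative
workflow (kinetics → render → track → cluster → metrics) and write their
tables under `results/`; large intermediates (the rendered TIFF stack)
go under `scratch/`.  The methods vignette
(`vignettes/smadtrace-methods.Rmd`) documents the models, defaults and
design decisions.

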