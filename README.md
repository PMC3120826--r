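# adcue

Random-dot kinetic-occlusion stimuli and an ideal-observer analysis of the
accretion-deletion depth cue, with Horn–Schunck optic flow and simulated
psychophysics.

## The problem

When a textured surface moves behind a stationary occluder, its texture is
progressively deleted at the leading occlusion boundary and accretes at the
trailing one.  Geometrically the surface undergoing accretion-deletion (AD)
is always the farther one, so the AD cue has long been considered
self-sufficient for depth-order-from-motion.  The classic counterexample is
a display with a central disc of coherently translating random dots inside
an annulus of random dots: with a *static* surround the center looks like a
far surface seen through a hole, but once the surround dots *flicker* the
center appears to slide over the surround as the near surface — a reversal
produced entirely by the context, since the center's pixels are identical in
both conditions.

This package provides the computational pieces of that argument for vision
scientists: a seeded stimulus generator with exact ground truth, a
Bayes-optimal observer that decides depth order from the AD evidence alone
(and is provably indifferent to the surround), an optic-flow analysis
showing the flicker leaves the center's motion information intact, and a
psychophysics simulator with the standard statistical analyses.

## The ideal observer in brief

Evidence lives in *area 3*: the center pixels `p` whose content has no
destination inside the center on the next frame (`p + d·û` leaves the
center mask — a band along the leading edge of motion, `d` pixels wide for
per-frame displacement `d`).  Over those pixels the observer accumulates

    LLR = Σ_i  log P(x_i^{t+1} | x_i^t, F)  −  log P(x_i^{t+1} | x_i^t, N)

where under **F** (center far) the evidence dot is deleted and replaced by
a fresh Bernoulli(density) draw, and under **N** (center near) the dot
persists, switching state only with probability `r`.  `LLR > 0` decides F.
Because the evidence region contains center pixels only, the cumulative LLR
is bit-identical across surround flicker levels — the formal statement that
the AD information does not depend on the surround.

## Worked example

```r
library(adcue)

spec <- default_stimulus_spec(rng_seed = 1)   # 256x256 px, 6.2 deg disc,
seq_static  <- generate_sequence(spec)        # 50% dots, 6 deg/s, 300 frames
seq_flicker <- generate_sequence(
  default_stimulus_spec(rng_seed = 1, surround_temporal_coherence = 0.5))

measure_density(seq_static)     # 0.5007  (configured: 50% dot density)
measure_michelson(seq_static)   # 1       (Michelson contrast 1.0, exact)
measure_survival(seq_static)    # 1       (static surround)
measure_survival(seq_flicker)   # 0.50008 (random flicker, survival 0.5)
estimate_center_speed(seq_static)$speed_deg_per_s   # 6 (deg/s, exact)

decide_depth_order(seq_static)
#> llr_trace: 299 frame pairs, 364 evidence px/pair
#>   cumulative LLR 55956.56 -> decision F

decide_depth_order(seq_flicker)
#> llr_trace: 299 frame pairs, 364 evidence px/pair
#>   cumulative LLR 55956.56 -> decision F
```

The two movies differ in every surround pixel, yet the observer's evidence
trace is bit-identical (55956.56 in both), and it answers **F** — the
center is the far, occluded surface — regardless of the flicker that
reverses the human percept.  The optic-flow comparison tells the same
story from the motion-energy side:

```r
compare_flow_conditions(seq_static, seq_flicker)
#> flow_comparison: center interior EPE 0.017 px/frame, surround EPE 2.739 px/frame
```

and the contrast-gating experiment (`run_experiment_2(seed = 22)`) shows
simulated observers reporting "center far" in 0.45% of flickering-surround
trials without a segmentation cue, but in ~99% once either region's dot
contrast is lowered — while the ideal observer answers F in all six
conditions.

The numbered scripts under `analysis/` run these stages in order
(`Rscript analysis/01_stimuli.R` … `04_psychophysics.R`) and write their
tables and figures under `results/`.

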