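# Small stimulus specs used across the unit tests: same physical parameters
# (25 px/deg, 75 Hz, 2 px/frame) but a reduced field and duration so each
# movie builds in milliseconds.

small_spec <- function(...) {
  args <- list(
    frame_size_px = c(96L, 96L),
    stimulus_diameter_deg = 2.4,
    surround_outer_diameter_deg = 3.6,
    duration_s = 0.2
  )
  do.call(default_stimulus_spec, utils::modifyList(args, list(...)))
}

# Frozen self-calibrated bounds (see the methods vignette): 5th percentile of
# the zone-vs-area-3 Jaccard over 50 seeds at the default stimulus scale.
J_MIN <- 0.048
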