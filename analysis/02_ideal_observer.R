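#!/usr/bin/env Rscript
# Stage 2: the ideal observer decides depth order from accretion-deletion
# evidence alone, and its evidence is unaffected by surround flicker.

suppressPackageStartupMessages(library(adcue))
dir.create("results", showWarnings = FALSE)

spec <- default_stimulus_spec(rng_seed = 1)
params <- params_from_spec(spec)

conds <- list(static = 1, mid = 0.75, flicker = 0.5)
traces <- lapply(conds, function(coh) {
  sp <- spec
  sp$surround_temporal_coherence <- coh
  decide_depth_order(generate_sequence(sp), params)
})

tab <- data.frame(
  condition = names(conds),
  coherence = unlist(conds),
  decision = vapply(traces, `[[`, character(1), "decision"),
  cumulative_llr = vapply(traces, function(tr) {
    tr$cumulative[length(tr$cumulative)]
  }, numeric(1))
)
write.csv(tab, "results/ideal_observer_decisions.csv", row.names = FALSE)
print(tab, row.names = FALSE)
cat("cumulative LLR bit-identical across all coherences:",
    all(tab$cumulative_llr == tab$cumulative_llr[1]), "\n")

tr <- traces$static
write.csv(data.frame(pair_index = seq_along(tr$per_pair), llr = tr$per_pair,
                     cumulative_llr = tr$cumulative),
          "results/llr_trace_static.csv", row.names = FALSE)

# Monte-Carlo flicker invariance of the evidence strength
inv <- llr_flicker_invariance(default_stimulus_spec(rng_seed = 100),
                              coherences = c(0.5, 0.75, 1), n_reps = 5)
write.csv(inv, "results/llr_flicker_invariance.csv", row.names = FALSE)
print(inv, row.names = FALSE)
cat("flicker-invariance violation flag:", attr(inv, "violation"), "\n")
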