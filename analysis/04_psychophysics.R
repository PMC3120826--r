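#!/usr/bin/env Rscript
# Stage 4: simulated psychophysics -- the flicker-dependent reversal of the
# depth-order report (with its logistic fit and residual checks) and the
# contrast-gating experiment in which segmentation cues restore the percept
# the accretion-deletion cue predicts.

suppressPackageStartupMessages(library(adcue))
dir.create("results", showWarnings = FALSE)

# Experiment 1: far-report proportion vs surround temporal coherence
model <- psychometric_model()
design <- experiment_design()  # 11 subjects, 6 coherence levels, 20/cell
trials <- simulate_responses(model, design, seed = 11)
write.csv(trials, "results/exp1_trials.csv", row.names = FALSE)

fit <- fit_logistic(trials, by_subject = TRUE)
print(fit)

hi <- trials[trials$coherence_pct == 100, ]
lo <- trials[trials$coherence_pct == 50, ]
p_hi <- binomial_proportions_test(sum(hi$report == "far"), nrow(hi))
p_lo <- binomial_proportions_test(sum(lo$report == "far"), nrow(lo))
cat(sprintf("static surround: %.1f%% far reports (binomial p = %.3g)\n",
            100 * mean(hi$report == "far"), p_hi))
cat(sprintf("full flicker:    %.1f%% far reports (binomial p = %.3g)\n",
            100 * mean(lo$report == "far"), p_lo))

resid_ok <- fit$residuals[fit$fitted$normal_ok]
chisq <- residual_normality_chisq(resid_ok)
cat(sprintf("residual normality (chi-square, %d cells): p = %.3f\n",
            length(resid_ok), chisq$p_value))

jsonlite::write_json(
  list(coefficients = as.list(fit$coefficients),
       r_squared = fit$r_squared, r_squared_method = fit$r_squared_method,
       binomial_p_static = p_hi, binomial_p_flicker = p_lo,
       residual_normality_p = chisq$p_value),
  "results/exp1_fit.json", auto_unbox = TRUE, digits = NA
)

# per-level summary for plotting
far <- trials$report == "far"
lvl <- aggregate(far, by = list(coherence_pct = trials$coherence_pct),
                 FUN = mean)
names(lvl)[2] <- "prop_far"
write.csv(lvl, "results/exp1_proportions.csv", row.names = FALSE)

pdf("results/exp1_psychometric.pdf", width = 5, height = 4.5)
plot(lvl$coherence_pct, lvl$prop_far, pch = 19, ylim = c(0, 1),
     xlab = "surround temporal coherence (%)",
     ylab = "proportion 'center far' reports")
cc <- seq(50, 100, 0.5)
lines(cc, plogis(fit$coefficients[1] + fit$coefficients[2] * cc),
      col = "red", lwd = 2)
dev.off()

# Experiment 2: contrast gating
e2 <- run_experiment_2(seed = 22)
print(e2)
write.csv(e2$proportions, "results/exp2_proportions.csv", row.names = FALSE)
write.csv(e2$io_decisions, "results/exp2_ideal_observer.csv",
          row.names = FALSE)
cat("ideal observer decides F in all six conditions:",
    all(e2$io_decisions$decision == "F"), "\n")
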