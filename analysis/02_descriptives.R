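#!/usr/bin/env Rscript

# Stage 2: per-state descriptives and completion checks.
#
# Reproduces the descriptive layer of the analysis on the simulated year:
# the severity-by-state table, Welch contrasts of each symptom between
# the stable state and the relapse states, day-level mean series for
# plotting, and the two ANOVAs (answered beeps/day across states; within-
# day sd across states).

suppressPackageStartupMessages(library(esmnet))

series <- read_esm_csv("results/series.csv")
series <- derive_states(series)

ss <- state_summary(series)
utils::write.csv(ss, "results/state_summary.csv", row.names = FALSE, na = "")
cat("Per-state symptom means:\n")
print(reshape(ss[c("state", "symptom", "mean")], idvar = "symptom",
              timevar = "state", direction = "wide"), digits = 3)

contrasts <- do.call(rbind, lapply(esm_symptoms(), function(s) {
  rbind(compare_states(series, s, "stable", "impending_relapse"),
        compare_states(series, s, "stable", "full_relapse"))
}))
utils::write.csv(contrasts, "results/contrasts.csv", row.names = FALSE)
sig <- contrasts[contrasts$p_value < 0.05, ]
cat("\nSignificant state contrasts (Welch, two-sided, alpha 0.05):\n")
print(sig[c("symptom", "state_b", "statistic", "p_value", "direction")],
      digits = 3)

utils::write.csv(day_level_series(series), "results/day_series.csv",
                 row.names = FALSE, na = "")

bpd <- beeps_per_day_anova(series)
cat(sprintf("\nAnswered beeps/day across states: F = %.2f, p = %.2f\n",
            bpd$F, bpd$p_value))
print(bpd$per_state, digits = 3)

sd_anova <- day_sd_by_state_anova(series)
utils::write.csv(sd_anova, "results/day_sd_anova.csv", row.names = FALSE)
cat("\nWithin-day sd across states (per symptom):\n")
print(sd_anova, digits = 3)
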