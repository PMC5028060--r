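#!/usr/bin/env Rscript

# Stage 1: generate the study-frame ESM year.
#
# One synthetic patient-year under the study's sampling frame: 201
# monitored days (4/week), 10 random beeps/day between 7:30 and 22:30
# with 10-180 min gaps, ~47% completion, five Likert symptoms driven by
# state-dependent lag-1 dynamics, and a clozapine dose trajectory over
# {350, 400, 450} mg defining 2 impending- and 4 full-relapse episodes.
# Writes the beep-level series and the generator ground truth.

suppressPackageStartupMessages(library(esmnet))

out_dir <- "results"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(seed = 42)
sim <- simulate_series(cfg)

write_esm_csv(sim$series, file.path(out_dir, "series.csv"))
write_ground_truth(sim$truth, file.path(out_dir, "ground_truth.json"))

cs <- completion_stats(sim$series)
cat(sprintf("Simulated %d beeps over %d monitored days\n",
            cs$n_scheduled, cs$n_days))
cat(sprintf("Answered: %d (%.0f%%), mean %.1f beeps/day (sd %.2f, range %d-%d)\n",
            cs$n_answered, 100 * cs$fraction, cs$per_day_mean, cs$per_day_sd,
            cs$per_day_min, cs$per_day_max))
ep <- segment_episodes(sim$series)
print(ep$summary)
cat("Wrote", file.path(out_dir, "series.csv"), "and ground_truth.json\n")
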