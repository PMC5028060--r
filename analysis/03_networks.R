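#!/usr/bin/env Rscript

# Stage 3: state-stratified symptom networks.
#
# Five lagged regressions per state (each symptom on all five symptoms at
# the previous answered beep of the same day, de-trended with calendar
# day) assemble the 25-coefficient directed network; the Spearman
# partial-correlation networks are the rank-based sensitivity analysis.

suppressPackageStartupMessages(library(esmnet))

series <- derive_states(read_esm_csv("results/series.csv"))

for (m in c("regression", "spearman_partial")) {
  for (st in esm_states()) {
    net <- estimate_network(series, st, method = m)
    base <- file.path("results", paste0("network_", m, "_", st))
    write_network_json(net, paste0(base, ".json"))
    write_graphml(net, paste0(base, ".graphml"))
  }
}

cat("Regression networks (W[i, j] = edge j(t-1) -> i(t)):\n\n")
for (st in esm_states()) {
  net <- estimate_network(series, st)
  cat("--", st, "(n =", unique(net$n)[1], "rows):\n")
  print(round(net$W, 2))
  cat("mean |edge| =", round(mean(abs(net$W)), 3), "\n\n")
}
cat("Wrote network JSON + GraphML per state and method under results/\n")
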