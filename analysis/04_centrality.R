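#!/usr/bin/env Rscript

# Stage 4: centrality indices per network.
#
# Betweenness, closeness, inward/outward strength and node strength
# (self-loop counted in both directions, hence twice in node strength)
# for each state's network, both estimation methods. The question the
# table answers: which symptom is the strategic hub of the network in
# each severity state?

suppressPackageStartupMessages(library(esmnet))

for (m in c("regression", "spearman_partial")) {
  cat("==", m, "networks\n")
  for (st in esm_states()) {
    net <- read_network_json(
      file.path("results", paste0("network_", m, "_", st, ".json")))
    ct <- centrality_table(net)
    utils::write.csv(ct, file.path("results",
                                   paste0("centrality_", m, "_", st, ".csv")),
                     row.names = FALSE)
    hub <- ct$symptom[which.max(ct$node_strength)]
    cat(sprintf("%-18s most central (node strength): %s\n", st, hub))
    if (st == "full_relapse") print(ct, digits = 3)
  }
  cat("\n")
}
cat("Wrote centrality tables under results/\n")
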