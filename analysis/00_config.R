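# Shared configuration for the analysis scripts. Every script sources this
# file, re-derives the simulated world from the same seed (generation is
# cheap and deterministic), and writes its tables under results/analysis/.

library(caronet)

ANALYSIS_SEED <- 2026L
OUT <- "results/analysis"
dir.create(OUT, showWarnings = FALSE, recursive = TRUE)

analysis_world <- function(seed = ANALYSIS_SEED) {
  # 64 tips keeps every script interactive-fast while preserving the
  # dynamics of the 152-tip default world
  cfg <- sim_config(tips = 64L, seed = seed)
  global <- generate_global_network(cfg)
  tree <- generate_phylogeny(cfg)
  sim <- simulate_network_evolution(global, tree, cfg)
  list(cfg = cfg, global = global, tree = tree, sim = sim)
}
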