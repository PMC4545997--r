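# Degree-preserving randomization: compare each species' maximum-network
# structure (pathway length from diet to plumage, modularity, average
# path length) with the expectation under double-edge-swap rewiring.

source("analysis/00_config.R")

w <- analysis_world()
nets <- suppressWarnings(build_species_networks(w$global, w$sim$inventories,
                                                kind = "maximum"))
maxs <- lapply(nets, `[[`, "maximum")
eligible <- names(maxs)[vapply(maxs, function(n) nrow(n$reactions) >= 6L,
                               TRUE)]
eligible <- head(eligible, 12L)   # null models dominate run time

tab <- null_comparison_table(maxs[eligible], B = 200L,
                             seed = ANALYSIS_SEED + 100L)
write.csv(tab, file.path(OUT, "null_comparisons.csv"), row.names = FALSE)

cat(sprintf("%d species x 3 metrics, B = 200 rewired replicates each\n",
            length(eligible)))
agg <- aggregate(z ~ metric, tab[!tab$degenerate, ], mean)
cat("mean z across species (observed - null, SD units):\n")
print(agg, row.names = FALSE)
cat("negative z for pathway metrics = observed pathways shorter/more\n")
cat("compact than degree-matched random wirings\n")
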