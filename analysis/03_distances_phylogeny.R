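# Metabolic distances, the metabolic NJ phylogeny versus the dated tree,
# divergence-versus-time regressions in 20-My bins per role subnetwork,
# and the robustness-elongation association with independent contrasts.

source("analysis/00_config.R")

w <- analysis_world()
nets <- suppressWarnings(build_species_networks(w$global, w$sim$inventories))
mins <- lapply(nets, `[[`, "minimum")
maxs <- lapply(nets, `[[`, "maximum")

d <- pairwise_matrix(mins)
write.csv(d, file.path(OUT, "distance_matrix.csv"))
write_phylip(d, file.path(OUT, "distance_matrix.phy"))

mtree <- neighbor_joining(d)
ape::write.tree(mtree, file.path(OUT, "metabolic_tree.nwk"))
rf <- robinson_foulds(w$tree, mtree)
cat(sprintf("metabolic vs molecular topology: RF = %d of max %d (%d tips)\n",
            rf$rf, rf$rf_max, rf$n))
write.csv(data.frame(rf = rf$rf, rf_max = rf$rf_max, n = rf$n),
          file.path(OUT, "tree_comparison.csv"), row.names = FALSE)

roles <- list(all = d,
              dietary = pairwise_matrix(mins, "dietary"),
              intermediate = pairwise_matrix(mins, "intermediate"),
              expressed = pairwise_matrix(mins, "expressed"))
reg <- divergence_time_regression(roles, w$tree, bin_width = 20)
write.csv(reg$bins, file.path(OUT, "divergence_bins.csv"), row.names = FALSE)
write.csv(reg$overall, file.path(OUT, "divergence_overall.csv"),
          row.names = FALSE)
cat("metabolic divergence vs patristic distance (Spearman, by role):\n")
print(reg$overall, row.names = FALSE)

metrics <- read.csv(file.path(OUT, "species_metrics.csv"))
ok <- metrics$species_id[!is.na(metrics$elongation) & !is.na(metrics$robustness)]
ctr <- contrasts_regression(
  ape::keep.tip(w$tree, ok),
  setNames(metrics$robustness[match(ok, metrics$species_id)], ok),
  setNames(as.numeric(metrics$elongation[match(ok, metrics$species_id)]), ok))
cat(sprintf("robustness ~ elongation (independent contrasts): b_ST = %.2f, p = %.2g\n",
            ctr$b_st, ctr$p))
write.csv(data.frame(slope = ctr$slope, b_st = ctr$b_st, p = ctr$p,
                     n_contrasts = ctr$n_contrasts),
          file.path(OUT, "robustness_contrasts.csv"), row.names = FALSE)
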