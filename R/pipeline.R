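#' Run the full analysis pipeline
#'
#' Orchestrates every stage over either real inputs (a global network,
#' species inventories and a dated tree) or a simulated world from
#' [sim_config()]: species network construction, metabolic distances and
#' the metabolic NJ phylogeny, tree comparison, divergence-versus-time
#' regressions, degree-preserving null models, robustness/elongation
#' contrasts, biochemical scope profiles, and gain/loss ancestral
#' reconstruction with the dietary-rescue transition analysis. All tables
#' are written as CSV/TSV/Newick under `out_dir` together with a manifest
#' recording the configuration and the per-stage seeds (derived from the
#' master seed by fixed offsets).
#'
#' @param out_dir output directory (created if missing).
#' @param global,inventory,tree real inputs (a `caro_network`, an
#'   inventory data.frame, a dated `phylo`); all `NULL` when simulating.
#' @param config a [sim_config()]; required when real inputs are absent.
#' @param B null-model replicates per species.
#' @param null_species cap on the number of species run through the null
#'   models (they dominate run time); `Inf` for all.
#' @param bin_width divergence-regression bin width (My).
#' @param seed master seed.
#' @return the output directory, invisibly; the run summary is returned as
#'   attribute `summary`.
#' @export
run_full_analysis <- function(out_dir, global = NULL, inventory = NULL,
                              tree = NULL, config = NULL, B = 200L,
                              null_species = 10L, bin_width = 20,
                              seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  simulated <- is.null(global)
  if (simulated) {
    if (is.null(config)) stop("either real inputs or a sim_config is required")
    global <- generate_global_network(config)
    tree <- generate_phylogeny(config)
    sim <- simulate_network_evolution(global, tree, config)
    inventory <- sim$inventories
  } else if (is.null(inventory)) {
    stop("real inputs require an inventory")
  }
  write_edge_tsv(global, file.path(out_dir, "global_edges.tsv"))
  utils::write.table(data.frame(compound_id = global$dietary),
                     file.path(out_dir, "global_dietary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(inventory, file.path(out_dir, "inventories.csv"),
            row.names = FALSE)
  if (!is.null(tree)) ape::write.tree(tree, file.path(out_dir, "tree.nwk"))

  nets <- build_species_networks(global, inventory)
  mins <- lapply(nets, `[[`, "minimum")
  maxs <- lapply(nets, `[[`, "maximum")

  # per-species descriptive metrics: elongation on the minimum network
  # (the descriptive network of the analyses), robustness/vulnerability on
  # the maximum network (redundant pathways included)
  metrics <- do.call(rbind, lapply(names(mins), function(sp) {
    net <- mins[[sp]]
    el <- tryCatch(longest_elongation(net), error = function(e) NA)
    rb <- tryCatch(robustness(maxs[[sp]])$R, error = function(e) NA)
    vl <- tryCatch(vulnerability(maxs[[sp]])$vulnerability,
                   error = function(e) NA)
    data.frame(species_id = sp, n_compounds = nrow(net$compounds),
               n_reactions = nrow(net$reactions),
               n_dietary = length(net$dietary),
               elongation = el, robustness = rb, vulnerability = vl,
               stringsAsFactors = FALSE)
  }))
  write.csv(metrics, file.path(out_dir, "species_metrics.csv"),
            row.names = FALSE)

  dmat <- pairwise_matrix(mins)
  write.csv(dmat, file.path(out_dir, "distance_matrix.csv"))
  write_phylip(dmat, file.path(out_dir, "distance_matrix.phy"))
  met_tree <- if (nrow(dmat) >= 3L && !anyNA(dmat)) neighbor_joining(dmat)
  if (!is.null(met_tree))
    ape::write.tree(met_tree, file.path(out_dir, "metabolic_tree.nwk"))

  summary <- list()
  if (!is.null(tree)) {
    if (!is.null(met_tree) && length(intersect(tree$tip.label,
                                               met_tree$tip.label)) >= 4L) {
      rf <- robinson_foulds(tree, met_tree)
      write.csv(data.frame(rf = rf$rf, rf_max = rf$rf_max, n = rf$n),
                file.path(out_dir, "tree_comparison.csv"), row.names = FALSE)
      summary$tree_comparison <- rf
    }
    roles_mats <- list(
      all = dmat,
      dietary = pairwise_matrix(mins, "dietary"),
      intermediate = pairwise_matrix(mins, "intermediate"),
      expressed = pairwise_matrix(mins, "expressed"))
    reg <- divergence_time_regression(roles_mats, tree, bin_width = bin_width)
    if (!is.null(reg$bins))
      write.csv(reg$bins, file.path(out_dir, "divergence_bins.csv"),
                row.names = FALSE)
    if (!is.null(reg$overall))
      write.csv(reg$overall, file.path(out_dir, "divergence_overall.csv"),
                row.names = FALSE)
    summary$divergence <- reg$overall
    # robustness vs elongation with independent contrasts
    ok <- metrics$species_id[!is.na(metrics$elongation) &
                               !is.na(metrics$robustness)]
    ok <- intersect(ok, tree$tip.label)
    if (length(ok) >= 3L) {
      sub <- ape::keep.tip(tree, ok)
      ctr <- contrasts_regression(
        sub,
        stats::setNames(metrics$robustness[match(ok, metrics$species_id)], ok),
        stats::setNames(as.numeric(metrics$elongation[match(ok, metrics$species_id)]), ok))
      write.csv(data.frame(slope = ctr$slope, b_st = ctr$b_st, p = ctr$p,
                           n_contrasts = ctr$n_contrasts),
                file.path(out_dir, "robustness_contrasts.csv"),
                row.names = FALSE)
      summary$contrasts <- ctr[c("slope", "b_st", "p")]
    }
  }
  grp <- metrics[!is.na(metrics$elongation), ]
  if (length(unique(grp$n_dietary > 2)) == 2L &&
      all(table(grp$n_dietary > 2) >= 2L)) {
    f <- elongation_vs_diet_groups(grp)
    write.csv(data.frame(F = f$F, df1 = f$df1, df2 = f$df2, p = f$p),
              file.path(out_dir, "elongation_vs_diet.csv"), row.names = FALSE)
    summary$elongation_vs_diet <- f[c("F", "df1", "df2", "p")]
  }

  # degree-preserving null models on the maximum networks, whose redundant
  # pathways are the structure under test (the expensive stage; capped)
  eligible <- names(maxs)[vapply(maxs, function(n) nrow(n$reactions) >= 4L, TRUE)]
  eligible <- head(eligible, null_species)
  if (length(eligible)) {
    nulls <- null_comparison_table(maxs[eligible], B = B, seed = seed + 100L)
    write.csv(nulls, file.path(out_dir, "null_comparisons.csv"),
              row.names = FALSE)
    agg <- stats::aggregate(z ~ metric, nulls[!nulls$degenerate, ], mean)
    summary$null_mean_z <- agg
  }

  # biochemical scope per dietary entry point
  scope_rows <- NULL
  for (d in global$dietary) {
    sc <- scope_expansion(global, d)
    scope_rows <- rbind(scope_rows,
                        cbind(seed_compound = d, sc$profile))
  }
  write.csv(scope_rows, file.path(out_dir, "scope_profiles.csv"),
            row.names = FALSE)
  write.csv(data.frame(max_possible_elaboration =
                         max_possible_elaboration(global)),
            file.path(out_dir, "max_elaboration.csv"), row.names = FALSE)

  # ancestral reconstruction and the dietary-rescue transition analysis
  if (!is.null(tree) && length(maxs) >= 2L) {
    usable <- intersect(names(maxs), tree$tip.label)
    if (length(usable) >= 4L) {
      sub <- ape::keep.tip(tree, usable)
      cm <- build_character_matrix(maxs[usable])
      rates <- fit_gain_loss_rates(cm, sub, "pooled", seed = seed + 200L)
      write.csv(data.frame(alpha = rates$alpha, beta = rates$beta,
                           loglik = rates$loglik),
                file.path(out_dir, "gain_loss_rates.csv"), row.names = FALSE)
      recon <- reconstruct_states(cm, sub, rates)
      anc <- assemble_ancestral_networks(recon, global)
      br <- branch_rates(recon$tree, anc)
      write.csv(br, file.path(out_dir, "branch_rates.csv"), row.names = FALSE)
      tr <- dietary_transitions(recon$tree, br, anc)
      write.csv(data.frame(n = tr$n, k = tr$k, n_bust = tr$n_bust,
                           z = as.numeric(tr$z)),
                file.path(out_dir, "transitions.csv"), row.names = FALSE)
      wt <- waiting_times_by_distance(recon$tree, anc, global, B = 200L,
                                      seed = seed + 300L)
      write.csv(wt, file.path(out_dir, "waiting_times.csv"), row.names = FALSE)
      summary$rates <- rates[c("alpha", "beta", "loglik")]
      summary$transitions <- tr[c("n", "k", "n_bust", "z")]
    }
  }

  manifest <- c(
    sprintf("caronet_version: %s",
            as.character(utils::packageVersion("caronet"))),
    sprintf("simulated: %s", simulated),
    sprintf("master_seed: %d", seed),
    "stage_seeds: null_models=seed+100, rates=seed+200, waiting=seed+300",
    sprintf("B: %d", B),
    sprintf("bin_width_my: %s", bin_width),
    sprintf("n_species: %d", length(mins)))
  if (simulated)
    manifest <- c(manifest, sprintf("sim_%s: %s",
                                    names(config)[!vapply(config, is.null, TRUE)],
                                    unlist(lapply(config[!vapply(config, is.null, TRUE)],
                                                  paste, collapse = ","))))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(structure(out_dir, summary = summary))
}

#' Summarise a completed run directory
#'
#' Reads the tables written by [run_full_analysis()] and prints a single
#' human-readable summary of the figure-level quantities: divergence
#' correlations, null-model z-scores, the robustness/elongation contrast,
#' the dietary-rescue transition table and scope coverage.
#'
#' @param run_dir a directory produced by [run_full_analysis()].
#' @return list of summary tables, invisibly; printed as a side effect.
#' @export
report <- function(run_dir) {
  if (!file.exists(file.path(run_dir, "manifest.txt")))
    stop("not a completed run directory: ", run_dir)
  grab <- function(f) {
    p <- file.path(run_dir, f)
    if (file.exists(p)) read.csv(p) else NULL
  }
  out <- list(metrics = grab("species_metrics.csv"),
              divergence = grab("divergence_overall.csv"),
              divergence_bins = grab("divergence_bins.csv"),
              nulls = grab("null_comparisons.csv"),
              contrasts = grab("robustness_contrasts.csv"),
              elongation_vs_diet = grab("elongation_vs_diet.csv"),
              transitions = grab("transitions.csv"),
              waiting_times = grab("waiting_times.csv"),
              scope = grab("scope_profiles.csv"),
              tree_comparison = grab("tree_comparison.csv"))
  cat("== caronet run summary:", run_dir, "==\n")
  if (!is.null(out$metrics))
    cat(sprintf("%d species; elongation 0-%s reactions; mean robustness %.2f\n",
                nrow(out$metrics),
                max(out$metrics$elongation, na.rm = TRUE),
                mean(out$metrics$robustness, na.rm = TRUE)))
  if (!is.null(out$divergence)) {
    cat("metabolic vs patristic distance (Spearman):\n")
    print(out$divergence)
  }
  if (!is.null(out$nulls)) {
    agg <- stats::aggregate(z ~ metric, out$nulls[!out$nulls$degenerate, ],
                            mean)
    cat("null-model mean z by metric:\n")
    print(agg)
  }
  if (!is.null(out$contrasts))
    cat(sprintf("robustness~elongation contrasts: b_ST = %.2f (p = %.3g)\n",
                out$contrasts$b_st, out$contrasts$p))
  if (!is.null(out$elongation_vs_diet))
    cat(sprintf("elongation vs >2 dietary compounds: F(%d,%d) = %.2f\n",
                out$elongation_vs_diet$df1, out$elongation_vs_diet$df2,
                out$elongation_vs_diet$F))
  if (!is.null(out$transitions))
    cat(sprintf("elevated->elevated transitions: k = %d of n = %d gained a dietary compound (z = %.2f)\n",
                out$transitions$k, out$transitions$n, out$transitions$z))
  if (!is.null(out$tree_comparison))
    cat(sprintf("RF distance metabolic vs dated tree: %d / %d\n",
                out$tree_comparison$rf, out$tree_comparison$rf_max))
  invisible(out)
}
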