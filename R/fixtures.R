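#' Built-in worked-example fixtures
#'
#' A small synthetic stand-in for a curated carotenoid network (13 real
#' carotenoid reactions, 4 dietary entry points) plus three species
#' inventories: a pair of distantly related species with identical plumage
#' carotenoids (lutein, zeaxanthin, alpha-doradexanthin, astaxanthin,
#' adonirubin, canthaxanthin -- the classic quelea/woodpecker convergence
#' example, so their metabolic distance is exactly 0), and a lutein-only
#' species whose longest elongation cannot exceed two reactions. Also
#' bundles the elevated-to-elevated transition counts (k = 32 dietary
#' gains out of n = 33 transitions) used by the sign-test worked example.
#'
#' @return list with `global` (a `caro_network`), `inventory` (data.frame),
#'   `networks` (built minimum networks per species), and `transitions`
#'   (list with `k`, `n`).
#' @export
bundled_fixtures <- function() {
  dir <- system.file("extdata", package = "caronet")
  global <- load_global_network(file.path(dir, "synthetic_avian_edges.tsv"),
                                file.path(dir, "synthetic_avian_dietary.tsv"))
  inventory <- read_inventory(file.path(dir, "synthetic_inventories.csv"))
  nets <- build_species_networks(global, inventory, kind = "minimum")
  list(global = global,
       inventory = inventory,
       networks = lapply(nets, `[[`, "minimum"),
       transitions = list(k = 32L, n = 33L))
}
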