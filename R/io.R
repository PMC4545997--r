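#' Load a global carotenoid network from edge and dietary tables
#'
#' The edge table is tab-separated with columns `reaction_id`, `substrate`,
#' `product`; the dietary table is tab-separated with a `compound_id`
#' column. Duplicate (substrate, product) edges are collapsed with a
#' warning; a self-loop or an endpoint missing from the implied compound
#' set is a load error naming the row.
#'
#' @param edge_table path to the reaction edge TSV.
#' @param dietary_table path to the dietary compound TSV.
#' @param compound_table optional TSV with columns `compound_id` (and
#'   `name`) enumerating compounds; default is the union of edge endpoints
#'   and dietary compounds.
#' @return a validated [caro_network()].
#' @export
load_global_network <- function(edge_table, dietary_table,
                                compound_table = NULL) {
  edges <- read.delim(edge_table, stringsAsFactors = FALSE)
  need <- c("reaction_id", "substrate", "product")
  if (!all(need %in% names(edges)))
    stop("edge table must have columns ", paste(need, collapse = ", "))
  diet <- read.delim(dietary_table, stringsAsFactors = FALSE)
  if (!"compound_id" %in% names(diet))
    stop("dietary table must have a compound_id column")
  loops <- edges$substrate == edges$product
  if (any(loops))
    stop("self-loop in edge table at row ", which(loops)[1L],
         " (", edges$substrate[which(loops)[1L]], ")")
  key <- paste(edges$substrate, edges$product, sep = "\r")
  if (anyDuplicated(key)) {
    warning("collapsed ", sum(duplicated(key)), " duplicate edge(s)")
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  if (is.null(compound_table)) {
    comp <- unique(c(edges$substrate, edges$product, diet$compound_id))
  } else {
    ct <- read.delim(compound_table, stringsAsFactors = FALSE)
    comp <- ct$compound_id
    missing <- setdiff(c(edges$substrate, edges$product), comp)
    if (length(missing))
      stop("reaction endpoint not in compound table: ",
           paste(missing, collapse = ", "))
  }
  caro_network(comp,
               data.frame(id = edges$reaction_id, substrate = edges$substrate,
                          product = edges$product, stringsAsFactors = FALSE),
               dietary = diet$compound_id)
}

#' Read a species compound inventory
#'
#' Inventory CSV with columns `species_id`, `compound_id`, `evidence`;
#' evidence is one of the closed tissue/role vocabulary (diet, plumage,
#' plasma, liver, gut, fat, faeces, seminal_fluid, integument).
#'
#' @param path CSV path.
#' @return data.frame of records.
#' @export
read_inventory <- function(path) {
  inv <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "compound_id", "evidence")
  if (!all(need %in% names(inv)))
    stop("inventory must have columns ", paste(need, collapse = ", "))
  bad <- setdiff(unique(inv$evidence), evidence_vocabulary())
  if (length(bad))
    stop("unknown evidence token: ", paste(bad, collapse = ", "))
  unique(inv[need])
}

#' @rdname read_inventory
#' @export
evidence_vocabulary <- function() {
  c("diet", "plumage", "plasma", "liver", "gut", "fat", "faeces",
    "seminal_fluid", "integument")
}

#' Export a network as GraphML (for visualisation) or edge-list TSV
#' @param net a `caro_network`.
#' @param path output path.
#' @export
write_graphml <- function(net, path) {
  g <- as_igraph(net)
  g <- igraph::set_vertex_attr(g, "dietary",
                               value = net$compounds$id %in% net$dietary)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_edge_tsv <- function(net, path) {
  utils::write.table(net$reactions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix in square PHYLIP format
#' @param d symmetric numeric matrix with row/col names.
#' @param path output path.
#' @export
write_phylip <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(formatC(rownames(d)[i], width = -10),
                     paste(formatC(d[i, ], format = "f", digits = 6),
                           collapse = " ")), con)
  invisible(path)
}
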