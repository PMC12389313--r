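## Heterogeneous drug-gene interaction network (DGIN): risk-annotated
## drug nodes ("name_RiskLevel"), shared gene nodes, undirected
## drug-gene edges. Built on igraph.

DGIN_COLORS <- c(High = "red", Moderate = "orange", Low = "gold",
                 Unknown = "gray", None = "white", gene = "green")

#' Node color map of the drug-gene interaction network
#'
#' @return Named character vector: risk level (drug nodes) or `"gene"`
#'   to color.
#' @export
dgin_colors <- function() DGIN_COLORS

#' Build the risk-annotated drug-gene interaction network
#'
#' Traverses the labeled combination table, creating one drug node per
#' observed (drug, risk level) pair - keyed `"name_RiskLevel"`, so the
#' same drug appears as distinct nodes under distinct risks - and
#' connecting each drug node to every target gene of the underlying drug.
#' Gene nodes are shared across all drug nodes; drugs with no mapped
#' genes become isolated drug nodes. Node attributes: `kind`
#' (drug/gene), `drug` (underlying name), `risk` (drug nodes), `color`
#' per [dgin_colors()]; edges carry a `risk` attribute copied from their
#' drug node.
#'
#' @param labeled `data.frame` with `combination` and `risk_level`
#'   columns ([label_combinations()]).
#' @param genes a [drug_gene_map()].
#' @return An undirected [igraph::graph] of class `dgin`.
#' @export
build_dgin <- function(labeled, genes) {
  stopifnot(is.data.frame(labeled),
            all(c("combination", "risk_level") %in% names(labeled)),
            inherits(genes, "drug_gene_map"))
  tuples <- combo_drugs(labeled$combination)
  drug <- unlist(tuples, use.names = FALSE)
  risk <- rep(labeled$risk_level, lengths(tuples))
  pairs <- unique(data.frame(drug = as.character(drug),
                             risk = as.character(risk),
                             stringsAsFactors = FALSE))
  if (nrow(pairs) > 0L) {
    pairs <- pairs[order_c(pairs$drug, pairs$risk), , drop = FALSE]
  }
  drug_nodes <- paste(pairs$drug, pairs$risk, sep = "_")
  target_sets <- lapply(pairs$drug, gene_targets, map = genes)
  gene_nodes <- unlist(target_sets, use.names = FALSE)
  gene_nodes <- if (is.null(gene_nodes)) character(0) else {
    sort_c(unique(gene_nodes))
  }

  g <- igraph::make_empty_graph(directed = FALSE)
  if (length(drug_nodes) > 0L) {
    g <- igraph::add_vertices(g, length(drug_nodes), name = drug_nodes,
                              kind = "drug", drug = pairs$drug,
                              risk = pairs$risk,
                              color = unname(DGIN_COLORS[pairs$risk]))
  }
  if (length(gene_nodes) > 0L) {
    g <- igraph::add_vertices(g, length(gene_nodes), name = gene_nodes,
                              kind = "gene", drug = NA_character_,
                              risk = NA_character_,
                              color = unname(DGIN_COLORS[["gene"]]))
  }
  n_edges <- sum(lengths(target_sets))
  if (n_edges > 0L) {
    ends <- rbind(rep(drug_nodes, lengths(target_sets)),
                  unlist(target_sets, use.names = FALSE))
    g <- igraph::add_edges(g, as.vector(ends),
                           risk = rep(pairs$risk, lengths(target_sets)))
  }
  class(g) <- c("dgin", class(g))
  g
}

#' Summarize a drug-gene interaction network
#'
#' @param g a `dgin` graph from [build_dgin()].
#' @return Named list: `drug_nodes` (risk-variant node count),
#'   `distinct_drugs` (underlying drug names, risk variants collapsed),
#'   `gene_nodes`, `edges`.
#' @export
network_stats <- function(g) {
  kind <- igraph::vertex_attr(g, "kind")
  is_drug <- !is.na(kind) & kind == "drug"
  list(
    drug_nodes = sum(is_drug),
    distinct_drugs = length(unique(igraph::vertex_attr(g, "drug")[is_drug])),
    gene_nodes = sum(!is.na(kind) & kind == "gene"),
    edges = igraph::ecount(g)
  )
}

#' Export a drug-gene interaction network
#'
#' Writes GraphML (default) or GEXF-compatible GML; the GraphML
#' round-trip through [read_dgin()] preserves node/edge counts and the
#' kind/risk/color attributes.
#'
#' @param g a `dgin` graph.
#' @param path output path.
#' @param format `"graphml"` (default) or `"gml"`.
#' @export
export_dgin <- function(g, path, format = c("graphml", "gml")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write network: no such directory ", dir)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Re-import an exported drug-gene interaction network
#'
#' @param path a GraphML file written by [export_dgin()].
#' @return The `dgin` graph.
#' @export
read_dgin <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  class(g) <- c("dgin", class(g))
  g
}
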