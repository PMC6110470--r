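# Brain-specific interaction network construction and the per-sample
# compound-heterozygote screen (gene deletion on one allele plus a
# deleterious small variant in the same gene or a first-order interaction
# partner).

#' Restrict an interaction network to valid, brain-expressed genes
#'
#' Nodes are restricted to the intersection of `valid_symbols` (e.g.
#' nomenclature-valid genes) and `brain_genes`; edges survive only when both
#' endpoints survive. No transitive closure: removing a node disconnects its
#' former neighbours.
#'
#' @param network An `exodel_network` (list with `nodes` and `edges`
#'   tibbles).
#' @param valid_symbols Character vector of acceptable symbols (`NULL` keeps
#'   all).
#' @param brain_genes Character vector of brain-expressed symbols (`NULL`
#'   uses the network's own `brain_expressed` flags).
#' @return The filtered `exodel_network`, with `n_dropped_nodes` and
#'   `n_dropped_edges` attributes.
#' @export
build_brain_network <- function(network, valid_symbols = NULL,
                                brain_genes = NULL) {
  nodes <- network$nodes
  keep <- rep(TRUE, nrow(nodes))
  if (!is.null(valid_symbols)) keep <- keep & nodes$gene %in% valid_symbols
  if (is.null(brain_genes)) {
    keep <- keep & nodes$brain_expressed
  } else {
    keep <- keep & nodes$gene %in% brain_genes
  }
  kept_nodes <- nodes[keep, , drop = FALSE]
  edges <- network$edges %>%
    filter(.data$from %in% kept_nodes$gene, .data$to %in% kept_nodes$gene)
  out <- new_network(kept_nodes, edges)
  attr(out, "n_dropped_nodes") <- sum(!keep)
  attr(out, "n_dropped_edges") <- nrow(network$edges) - nrow(edges)
  out
}

network_adjacency <- function(network) {
  if (nrow(network$edges) == 0) {
    g <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(network$nodes$gene)
  } else {
    g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                       vertices = network$nodes$gene)
  }
  g
}

#' Screen samples for deletion + deleterious-variant concurrence
#'
#' For every sample, emits a `same_gene` hit when a deleted gene also
#' carries a deleterious variant in that sample, and a `first_order` hit
#' when the variant gene is adjacent in the network to one of the sample's
#' deleted genes. Variant genes absent from the network are still eligible
#' for `same_gene` hits. Output is ordered by sample, variant gene, deleted
#' gene.
#'
#' @param deleted_genes Tibble (sample, gene): per-sample deleted genes
#'   (case-only filtered, gene-annotated deletions).
#' @param deleterious_variants Tibble (sample, gene, and optionally chrom,
#'   pos, ref, alt, effect): per-sample deleterious variants
#'   (rare + classifier-positive).
#' @param network `exodel_network` (typically [build_brain_network()]
#'   output).
#' @return Tibble of hits: sample, variant_gene, deleted_gene, relation and
#'   any variant identity columns present.
#' @export
find_comphet_hits <- function(deleted_genes, deleterious_variants, network) {
  id_cols <- intersect(c("chrom", "pos", "ref", "alt", "effect"),
                       names(deleterious_variants))
  empty <- tibble(sample = character(), variant_gene = character(),
                  deleted_gene = character(), relation = character())
  if (nrow(deleted_genes) == 0 || nrow(deleterious_variants) == 0) {
    return(empty)
  }
  g <- network_adjacency(network)
  known <- igraph::V(g)$name
  hits <- purrr::map(seq_len(nrow(deleterious_variants)), function(i) {
    v <- deleterious_variants[i, ]
    dels <- deleted_genes$gene[deleted_genes$sample == v$sample]
    if (length(dels) == 0) return(NULL)
    same <- intersect(v$gene, dels)
    first <- character(0)
    if (v$gene %in% known) {
      nb <- igraph::neighbors(g, v$gene)$name
      first <- setdiff(intersect(nb, dels), same)
    }
    rel_genes <- c(same, sort(first))
    if (length(rel_genes) == 0) return(NULL)
    out <- tibble(sample = v$sample, variant_gene = v$gene,
                  deleted_gene = rel_genes,
                  relation = c(rep("same_gene", length(same)),
                               rep("first_order", length(first))))
    for (col in id_cols) out[[col]] <- v[[col]]
    out
  })
  out <- bind_rows(hits)
  if (nrow(out) == 0) return(empty)
  arrange(out, .data$sample, .data$variant_gene, .data$deleted_gene)
}
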