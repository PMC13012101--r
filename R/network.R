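#' Focal-protein proteostasis network
#'
#' Container for the assembled network: the focal gene, the member nodes with
#' their aggregation-role sign and tier, and the interaction edges restricted
#' to the member set (edges touching the focal gene are retained too).
#'
#' @param focal Focal gene symbol (e.g. `"SNCA"`).
#' @param nodes Tibble with columns `gene`, `role` (`"promoter"`,
#'   `"attenuator"` or `NA`), `sign` (+1/-1) and `tier` (`"first_degree"` or
#'   `"upstream"`).
#' @param edges Tibble with columns `source`, `target`, `directed`.
#' @return An object of class `pn_network`.
#' @export
pn_network <- function(focal, nodes, edges) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("gene", "sign", "tier") %in% names(nodes)))
  if (!"role" %in% names(nodes)) nodes$role <- NA_character_
  if (anyDuplicated(nodes$gene)) abort("Duplicate network nodes.")
  if (focal %in% nodes$gene) abort("The focal gene is not a network node.")
  if (!all(nodes$sign %in% c(-1, 1))) abort("Node signs must be +1 or -1.")
  member <- c(nodes$gene, focal)
  if (nrow(edges) > 0 &&
      !all(edges$source %in% member & edges$target %in% member)) {
    abort("Edge endpoints must lie in the node set (plus the focal gene).")
  }
  structure(
    list(focal = focal, nodes = nodes, edges = edges, K = nrow(nodes)),
    class = "pn_network"
  )
}

#' @export
print.pn_network <- function(x, ...) {
  cat(sprintf(
    "<pn_network> focal %s: K = %d nodes (%d first-degree, %d upstream), %d edges\n",
    x$focal, x$K, sum(x$nodes$tier == "first_degree"),
    sum(x$nodes$tier == "upstream"), nrow(x$edges)
  ))
  invisible(x)
}

#' @export
tidy.pn_network <- function(x, ...) x$nodes

#' @export
glance.pn_network <- function(x, ...) {
  tibble::tibble(
    focal = x$focal,
    K = x$K,
    n_first_degree = sum(x$nodes$tier == "first_degree"),
    n_upstream = sum(x$nodes$tier == "upstream"),
    n_promoter = sum(x$nodes$sign == 1),
    n_attenuator = sum(x$nodes$sign == -1),
    n_edges = nrow(x$edges)
  )
}

# named sign vector a_i over network genes
network_signs <- function(network) {
  setNames(network$nodes$sign, network$nodes$gene)
}

# undirected simple adjacency over the network nodes plus focal gene
network_adjacency <- function(network, include_focal = TRUE) {
  genes <- network$nodes$gene
  if (include_focal) genes <- c(network$focal, genes)
  A <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  e <- network$edges
  if (nrow(e) > 0) {
    keep <- e$source %in% genes & e$target %in% genes
    e <- e[keep, , drop = FALSE]
    for (k in seq_len(nrow(e))) {
      A[e$source[k], e$target[k]] <- 1
      A[e$target[k], e$source[k]] <- 1
    }
  }
  diag(A) <- 0
  A
}
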