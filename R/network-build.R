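#' First-degree interactors of the focal gene
#'
#' Returns the unique proteostasis-network members with a functional
#' interaction pointing into the focal gene. Directed edges count when the
#' focal gene is the target; undirected edges incident to the focal gene
#' count as inward from the other endpoint.
#'
#' @param edges Edge tibble (`source`, `target`, `directed`).
#' @param pn_members Character vector of proteostasis-network member genes.
#' @param focal Focal gene symbol.
#' @return Sorted character vector of first-degree interactors.
#' @export
first_degree_interactors <- function(edges, pn_members, focal) {
  edges <- as_edge_tbl(edges)
  inward <- c(
    edges$source[edges$directed & edges$target == focal],
    edges$source[!edges$directed & edges$target == focal],
    edges$target[!edges$directed & edges$source == focal]
  )
  sort(unique(inward[inward %in% pn_members & inward != focal]))
}

#' Relative expression with respect to a reference gene
#'
#' Subtracts the reference gene's log2 value from every gene within each
#' sample: `log2(gene) - log2(reference)`. Linear-scale input must be
#' converted with [to_log2()] first.
#'
#' @param matrix A log2-scale [expr_mat].
#' @param reference Reference gene symbol (the focal gene).
#' @return A `rel_expr_mat` (an [expr_mat] subclass carrying the reference).
#' @export
relative_expression <- function(matrix, reference = "SNCA") {
  stopifnot(inherits(matrix, "expr_mat"))
  if (matrix$scale != "log2") {
    abort("Relative expression needs log2-scale input; see to_log2().")
  }
  if (!reference %in% rownames(matrix$values)) {
    abort(sprintf("Reference gene '%s' absent from the matrix.", reference))
  }
  ref <- matrix$values[reference, ]
  vals <- sweep(matrix$values, 2, ref, `-`)
  out <- expr_mat(vals, scale = "log2", sample_meta = matrix$sample_meta)
  out$reference <- reference
  class(out) <- c("rel_expr_mat", class(out))
  out
}

#' Per-gene differential relative expression between two groups
#'
#' For each gene, computes the case-minus-control mean difference of the
#' relative expression (the "fold change", in log2-ratio units), a two-sided
#' Wilcoxon rank-sum p-value ([wilcoxon_p]: exact enumeration for small
#' groups, normal approximation with tie correction otherwise) and a
#' multiplicity-adjusted q-value across the genes of the dataset.
#'
#' @param rel A `rel_expr_mat` from [relative_expression()].
#' @param case_label,control_label Values of `sample_meta$group` defining the
#'   two groups.
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @param dataset_id Label stored with the results.
#' @param fc_stat `"mean"` (default) or `"median"` group summary for the fold
#'   change.
#' @return A tibble with columns `dataset_id`, `gene`, `fc`, `p`, `q`,
#'   `direction`.
#' @export
differential_relative_expression <- function(rel, case_label = "case",
                                             control_label = "control",
                                             adjust = c("BH", "bonferroni"),
                                             dataset_id = "dataset",
                                             fc_stat = c("mean", "median")) {
  adjust <- match.arg(adjust)
  fc_stat <- match.arg(fc_stat)
  stopifnot(inherits(rel, "rel_expr_mat"))
  grp <- rel$sample_meta$group
  if (is.null(grp)) abort("sample_meta must carry a `group` column.")
  case_idx <- which(grp == case_label)
  ctrl_idx <- which(grp == control_label)
  if (length(case_idx) < 2 || length(ctrl_idx) < 2) {
    abort("Both groups need at least 2 samples.")
  }
  if (length(case_idx) < 5 || length(ctrl_idx) < 5) {
    warn("Fewer than 5 samples in a group; the test is underpowered.")
  }
  summ <- if (fc_stat == "mean") rowMeans else function(m) apply(m, 1, median)
  case_m <- rel$values[, case_idx, drop = FALSE]
  ctrl_m <- rel$values[, ctrl_idx, drop = FALSE]
  fc <- summ(case_m) - summ(ctrl_m)
  p <- vapply(seq_len(nrow(rel$values)), function(i) {
    wilcoxon_p(case_m[i, ], ctrl_m[i, ])
  }, numeric(1))
  tibble::tibble(
    dataset_id = dataset_id,
    gene = rownames(rel$values),
    fc = unname(fc),
    p = unname(p),
    q = p.adjust(p, method = adjust),
    direction = sign(fc)
  )
}

#' Consensus perturbed genes across datasets
#'
#' A gene is a consensus gene when, in at least `ceil(min_fraction *
#' n_datasets)` datasets, it is significant (`q < q_cut`), has
#' `|fc| > fc_cut`, and shows the same direction. The reference gene is never
#' included (its relative expression is identically zero).
#'
#' @param results A tibble of per-dataset differential results (rows from
#'   [differential_relative_expression()], stacked), or a list of such
#'   tibbles.
#' @param fc_cut Absolute fold-change cutoff (strict `>`); default 0.3.
#' @param q_cut Adjusted-p cutoff (strict `<`); default 0.05.
#' @param min_fraction Fraction of datasets that must agree; default 0.5.
#' @param reference Reference gene, excluded from the output.
#' @return A tibble with columns `gene`, `direction`, `n_support`,
#'   `n_datasets`, sorted by gene.
#' @export
consensus_genes <- function(results, fc_cut = 0.3, q_cut = 0.05,
                            min_fraction = 0.5, reference = "SNCA") {
  if (is.list(results) && !is.data.frame(results)) {
    results <- dplyr::bind_rows(results)
  }
  n_datasets <- dplyr::n_distinct(results$dataset_id)
  if (n_datasets < 2) abort("Consensus needs results from >= 2 datasets.")
  need <- ceiling(min_fraction * n_datasets)
  results |>
    dplyr::filter(.data$gene != reference,
                  .data$q < q_cut,
                  abs(.data$fc) > fc_cut,
                  .data$direction != 0) |>
    dplyr::count(.data$gene, .data$direction, name = "n_support") |>
    dplyr::filter(.data$n_support >= need) |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice_max(.data$n_support, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(n_datasets = n_datasets) |>
    dplyr::arrange(.data$gene)
}

#' Upstream integration of consensus genes
#'
#' Consensus genes with at least one functional interaction (either
#' direction) with a first-degree interactor are integrated as upstream
#' network members. Consensus genes whose only interaction is with the focal
#' gene itself are reported separately via the `focal_only` attribute.
#'
#' @param consensus Tibble from [consensus_genes()].
#' @param edges Edge tibble.
#' @param first_degree Character vector of first-degree genes.
#' @param focal Focal gene symbol.
#' @return Sorted character vector of upstream genes, with attribute
#'   `focal_only` listing consensus genes interacting only with the focal
#'   gene.
#' @export
integrate_upstream <- function(consensus, edges, first_degree, focal) {
  if (length(first_degree) == 0) abort("`first_degree` must be non-empty.")
  edges <- as_edge_tbl(edges)
  partners <- function(g) {
    unique(c(edges$target[edges$source == g], edges$source[edges$target == g]))
  }
  cand <- setdiff(consensus$gene, c(first_degree, focal))
  hits <- character(0)
  focal_only <- character(0)
  for (g in cand) {
    pr <- partners(g)
    if (any(pr %in% first_degree)) {
      hits <- c(hits, g)
    } else if (length(pr) > 0 && all(pr == focal)) {
      focal_only <- c(focal_only, g)
    }
  }
  structure(sort(hits), focal_only = sort(focal_only))
}

#' Assemble the proteostasis network
#'
#' Combines first-degree interactors and upstream consensus genes into a
#' [pn_network]. Signs: an annotated role always wins (promoter +1,
#' attenuator -1); upstream genes without a role take their consensus
#' direction (up in disease relative to the reference is +1). Every
#' first-degree gene must be role-annotated.
#'
#' @param first_degree Character vector of first-degree genes.
#' @param upstream Character vector of upstream genes.
#' @param roles Tibble with columns `gene`, `role` in
#'   `{"promoter", "attenuator"}`.
#' @param consensus Tibble from [consensus_genes()] (used for upstream signs).
#' @param edges Edge tibble; restricted to the node set plus the focal gene.
#' @param focal Focal gene symbol.
#' @return A [pn_network].
#' @export
assemble_network <- function(first_degree, upstream, roles, consensus, edges,
                             focal = "SNCA") {
  roles <- tibble::as_tibble(roles)
  if (nrow(roles) > 0) {
    bad <- setdiff(unique(roles$role), c("promoter", "attenuator"))
    if (length(bad) > 0) {
      abort(paste0("Unknown role(s): ", paste(bad, collapse = ", ")))
    }
    if (anyDuplicated(roles$gene)) abort("One role per gene, please.")
  }
  missing_roles <- setdiff(first_degree, roles$gene)
  if (length(missing_roles) > 0) {
    abort(paste0("First-degree gene(s) without a role annotation: ",
                 paste(missing_roles, collapse = ", ")))
  }
  role_sign <- setNames(ifelse(roles$role == "promoter", 1, -1), roles$gene)
  cons_dir <- setNames(consensus$direction, consensus$gene)

  upstream <- setdiff(upstream, first_degree)
  node_sign <- function(g, tier) {
    if (g %in% names(role_sign)) return(role_sign[[g]])
    if (tier == "upstream" && g %in% names(cons_dir)) return(cons_dir[[g]])
    abort(sprintf("No sign available for gene '%s'.", g))
  }
  nodes <- tibble::tibble(
    gene = c(first_degree, upstream),
    tier = c(rep("first_degree", length(first_degree)),
             rep("upstream", length(upstream)))
  )
  nodes$sign <- vapply(seq_len(nrow(nodes)), function(i) {
    node_sign(nodes$gene[i], nodes$tier[i])
  }, numeric(1))
  nodes$role <- dplyr::if_else(nodes$gene %in% roles$gene,
                               roles$role[match(nodes$gene, roles$gene)],
                               NA_character_)
  edges <- as_edge_tbl(edges)
  member <- c(nodes$gene, focal)
  edges <- edges[edges$source %in% member & edges$target %in% member, ,
                 drop = FALSE]
  pn_network(focal, nodes[, c("gene", "role", "sign", "tier")], edges)
}
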