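#' Heat-diffusion influence scores
#'
#' On the undirected simple projection of the network (focal gene included),
#' computes the Laplacian heat kernel `H = exp(-t L)` with `L = D - A` via
#' symmetric eigendecomposition. A node's influence is `1 - H_ii`: the
#' fraction of a unit of heat placed on the node that has left it after
#' diffusion time `t`. Isolated nodes score 0.
#'
#' @param network A [pn_network].
#' @param t Diffusion time, > 0; default 0.1.
#' @param include_focal Include the focal gene as a graph node (default TRUE).
#' @return A tibble with columns `gene`, `heat`, sorted by gene.
#' @export
heat_diffusion_scores <- function(network, t = 0.1, include_focal = TRUE) {
  if (t <= 0) abort("Diffusion time `t` must be positive.")
  A <- network_adjacency(network, include_focal = include_focal)
  if (nrow(A) < 2) abort("Need at least 2 nodes.")
  L <- diag(rowSums(A)) - A
  eig <- eigen(L, symmetric = TRUE)
  H <- eig$vectors %*% (exp(-t * eig$values) * t(eig$vectors))
  tibble::tibble(gene = rownames(A), heat = 1 - diag(H)) |>
    dplyr::arrange(.data$gene)
}

#' Personalized PageRank influence scores
#'
#' Random walk with restart on the undirected simple projection:
#' `r = (1 - alpha) * s + alpha * W^T r` with `s` the indicator of the seed
#' node and `W` row-stochastic. Rows of isolated (dangling) nodes teleport
#' their mass back to the seed. Iterated to an L1 change below `tol`.
#'
#' @param network A [pn_network].
#' @param damping Restart-complement alpha in (0, 1); default 0.85.
#' @param seed_node Seed gene; defaults to the focal gene.
#' @param include_focal Include the focal gene as a graph node (default TRUE).
#' @param tol L1 convergence tolerance; default 1e-12.
#' @return A tibble with columns `gene`, `ppr`, sorted by gene; scores sum
#'   to 1.
#' @export
ppr_scores <- function(network, damping = 0.85, seed_node = NULL,
                       include_focal = TRUE, tol = 1e-12) {
  if (damping <= 0 || damping >= 1) abort("`damping` must lie in (0, 1).")
  A <- network_adjacency(network, include_focal = include_focal)
  genes <- rownames(A)
  seed_node <- seed_node %||% network$focal
  if (!seed_node %in% genes) abort("Seed node is not in the graph.")
  n <- length(genes)
  deg <- rowSums(A)
  s <- as.numeric(genes == seed_node)
  W <- A / ifelse(deg == 0, 1, deg)  # row-stochastic where degree > 0
  r <- s
  repeat {
    walk <- as.vector(crossprod(W, r))
    dangling <- sum(r[deg == 0])
    r_new <- (1 - damping) * s + damping * (walk + dangling * s)
    if (sum(abs(r_new - r)) < tol) {
      r <- r_new
      break
    }
    r <- r_new
  }
  tibble::tibble(gene = genes, ppr = r / sum(r)) |>
    dplyr::arrange(.data$gene)
}

#' Classify network proteins into influence quadrants
#'
#' Splits each axis at its threshold (median by default; or a quantile) with
#' `>=` counting as high. high/high = master regulator; high heat, low PPR =
#' signal modulator; low heat, high PPR = hub; low/low = peripheral.
#'
#' @param heat Tibble `gene`, `heat` from [heat_diffusion_scores()].
#' @param ppr Tibble `gene`, `ppr` from [ppr_scores()].
#' @param split `"median"` or a quantile in (0, 1).
#' @return A tibble `gene`, `heat`, `ppr`, `category`.
#' @export
classify_quadrants <- function(heat, ppr, split = "median") {
  if (!setequal(heat$gene, ppr$gene)) {
    abort("Heat and PPR score sets cover different genes.")
  }
  df <- dplyr::inner_join(heat, ppr, by = "gene")
  thr <- function(x) {
    if (identical(split, "median")) median(x) else stats::quantile(x, split)
  }
  hi_heat <- df$heat >= thr(df$heat)
  hi_ppr <- df$ppr >= thr(df$ppr)
  df$category <- dplyr::case_when(
    hi_heat & hi_ppr ~ "master_regulator",
    hi_heat & !hi_ppr ~ "signal_modulator",
    !hi_heat & hi_ppr ~ "hub",
    TRUE ~ "peripheral"
  )
  df
}

#' Influence scores and quadrant classification in one call
#'
#' @inheritParams heat_diffusion_scores
#' @inheritParams ppr_scores
#' @inheritParams classify_quadrants
#' @return A tibble `gene`, `heat`, `ppr`, `category`.
#' @export
influence_scores <- function(network, t = 0.1, damping = 0.85,
                             seed_node = NULL, split = "median",
                             include_focal = TRUE) {
  classify_quadrants(
    heat_diffusion_scores(network, t = t, include_focal = include_focal),
    ppr_scores(network, damping = damping, seed_node = seed_node,
               include_focal = include_focal),
    split = split
  )
}
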