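# Shared fixtures and independent oracles used across the test files.

# A small hand-built network: 3 promoters, 2 attenuators, a couple of edges.
make_test_network <- function() {
  nodes <- tibble::tibble(
    gene = c("P1", "P2", "P3", "A1", "A2"),
    role = c("promoter", "promoter", "promoter", "attenuator", "attenuator"),
    sign = c(1, 1, 1, -1, -1),
    tier = "first_degree"
  )
  edges <- tibble::tibble(
    source = c("P1", "P2", "P3", "A1", "A2", "P1"),
    target = c("SNCA", "SNCA", "SNCA", "SNCA", "SNCA", "P2"),
    directed = TRUE
  )
  pn_network("SNCA", nodes, edges)
}

# Random network over k genes with random +/-1 signs (no edges needed for
# scoring tests).
random_network <- function(k) {
  genes <- sprintf("G%03d", seq_len(k))
  nodes <- tibble::tibble(
    gene = genes,
    role = NA_character_,
    sign = sample(c(-1, 1), k, replace = TRUE),
    tier = "first_degree"
  )
  pn_network("SNCA", nodes, tibble::tibble(source = character(0),
                                           target = character(0),
                                           directed = logical(0)))
}

# Independent PAS oracle: explicit loop over genes, no linear algebra.
brute_force_pas <- function(zvals, signs) {
  genes <- intersect(names(signs), rownames(zvals))
  vapply(seq_len(ncol(zvals)), function(j) {
    acc <- 0
    for (g in genes) acc <- acc + signs[[g]] * zvals[g, j]
    acc / length(genes)
  }, numeric(1))
}

# Independent exact Wilcoxon oracle: enumerates all assignments of the pooled
# observations to the first group and counts via the Mann-Whitney U statistic
# (pairwise comparisons with 0.5 for ties), avoiding the rank-sum route the
# implementation takes.
oracle_wilcoxon_enum <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_stat <- function(a, b) {
    s <- 0
    for (ai in a) for (bi in b) {
      s <- s + (ai > bi) + 0.5 * (ai == bi)
    }
    s
  }
  u_obs <- u_stat(x, y)
  idx <- utils::combn(length(pooled), n)
  us <- apply(idx, 2, function(ii) u_stat(pooled[ii], pooled[-ii]))
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# Brute-force consensus rule: direct set comprehension over the stated rule.
brute_force_consensus <- function(diff_list, fc_cut = 0.3, q_cut = 0.05,
                                  min_fraction = 0.5, reference = "SNCA") {
  all <- dplyr::bind_rows(diff_list)
  n_ds <- length(unique(all$dataset_id))
  need <- ceiling(min_fraction * n_ds)
  out <- list()
  for (g in setdiff(unique(all$gene), reference)) {
    rows <- all[all$gene == g & all$q < q_cut & abs(all$fc) > fc_cut &
                  all$direction != 0, ]
    for (dirn in c(1, -1)) {
      k <- sum(rows$direction == dirn)
      if (k >= need) {
        out[[length(out) + 1]] <- tibble::tibble(gene = g, direction = dirn,
                                                 n_support = k)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(gene = character(0), direction = numeric(0),
                          n_support = integer(0)))
  }
  res <- dplyr::bind_rows(out)
  # keep the better-supported direction if (pathologically) both qualify
  res <- res[order(res$gene, -res$n_support), ]
  res[!duplicated(res$gene), ]
}

# Textbook Cohen's d, written independently of the package helper.
oracle_cohens_d <- function(x, y) {
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2)
}

# Small expr_mat from a matrix literal.
quick_mat <- function(vals, genes, samples, scale = "log2") {
  m <- matrix(vals, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  expr_mat(m, scale = scale)
}
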