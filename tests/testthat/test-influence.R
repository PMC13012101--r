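# Small networks for graph-score tests: build a pn_network from an edge list
# over generic genes, all signs +1 (signs are irrelevant to influence).
graph_net <- function(edges, genes = NULL) {
  if (is.null(genes)) genes <- unique(c(edges$source, edges$target))
  genes <- setdiff(genes, "SNCA")
  pn_network("SNCA",
             tibble::tibble(gene = genes, role = NA_character_, sign = 1,
                            tier = "first_degree"),
             edges)
}

test_that("heat diffusion matches the dense matrix-exponential oracle", {
  # star S4: hub H with leaves L1..L3
  star <- graph_net(tibble::tibble(
    source = "H", target = c("L1", "L2", "L3"), directed = TRUE
  ))
  heat <- heat_diffusion_scores(star, t = 0.5, include_focal = FALSE)

  A <- matrix(0, 4, 4, dimnames = list(c("H", "L1", "L2", "L3"),
                                       c("H", "L1", "L2", "L3")))
  A["H", c("L1", "L2", "L3")] <- 1
  A[c("L1", "L2", "L3"), "H"] <- 1
  L <- diag(rowSums(A)) - A
  H_or <- as.matrix(Matrix::expm(-0.5 * L))
  oracle <- 1 - diag(H_or)
  expect_equal(heat$heat[match(rownames(A), heat$gene)], unname(oracle),
               tolerance = 1e-10)
  expect_gt(heat$heat[heat$gene == "H"], heat$heat[heat$gene == "L1"])
})

test_that("heat diffusion respects symmetry, isolation and conservation", {
  # complete graph K4: all influences equal
  pairs <- t(combn(c("a", "b", "c", "d"), 2))
  k4 <- graph_net(tibble::tibble(source = pairs[, 1], target = pairs[, 2],
                                 directed = FALSE))
  h <- heat_diffusion_scores(k4, t = 0.3, include_focal = FALSE)
  expect_equal(max(h$heat) - min(h$heat), 0, tolerance = 1e-12)

  # isolated node keeps all its heat
  iso <- graph_net(tibble::tibble(source = "a", target = "b", directed = TRUE),
                   genes = c("a", "b", "c"))
  hi <- heat_diffusion_scores(iso, include_focal = FALSE)
  expect_equal(hi$heat[hi$gene == "c"], 0)

  # row conservation of the kernel and monotonicity in t
  set.seed(4)
  g <- gen_edgelist(6, 5, 3, seed = 4)
  net <- assemble_network(g$truth$first_degree, character(0), g$roles,
                          tibble::tibble(gene = character(0),
                                         direction = numeric(0)),
                          g$edges, "SNCA")
  A <- pasnet:::network_adjacency(net)
  L <- diag(rowSums(A)) - A
  for (tt in c(0.1, 1)) {
    eig <- eigen(L, symmetric = TRUE)
    H <- eig$vectors %*% (exp(-tt * eig$values) * t(eig$vectors))
    expect_true(all(abs(rowSums(H) - 1) < 1e-10))
  }
  h1 <- heat_diffusion_scores(net, t = 0.1)$heat
  h2 <- heat_diffusion_scores(net, t = 0.5)$heat
  expect_true(all(h2 - h1 > -1e-12))

  expect_error(heat_diffusion_scores(net, t = 0), "positive")
})

test_that("personalized PageRank matches closed forms and conserves mass", {
  # two-node closed form at alpha = 0.85
  two <- graph_net(tibble::tibble(source = "u", target = "v", directed = FALSE))
  r <- ppr_scores(two, damping = 0.85, seed_node = "u", include_focal = FALSE)
  expect_equal(r$ppr[r$gene == "u"], 0.15 / (1 - 0.85^2), tolerance = 1e-4)
  expect_equal(r$ppr[r$gene == "v"], 0.85 * 0.15 / (1 - 0.85^2),
               tolerance = 1e-4)
  expect_equal(sum(r$ppr), 1, tolerance = 1e-10)

  # symmetric leaves of a star get identical scores
  star <- graph_net(tibble::tibble(source = "H", target = c("L1", "L2", "L3"),
                                   directed = FALSE))
  rs <- ppr_scores(star, seed_node = "H", include_focal = FALSE)
  leaves <- rs$ppr[rs$gene %in% c("L1", "L2", "L3")]
  expect_equal(max(leaves) - min(leaves), 0, tolerance = 1e-12)

  expect_error(ppr_scores(star, damping = 1.2), "damping")
})

test_that("PPR equals the direct linear solve on random graphs", {
  set.seed(31)
  for (rep in 1:5) {
    n_fd <- sample(5:15, 1)
    g <- gen_edgelist(n_fd, 5, 3, seed = rep * 17)
    net <- assemble_network(g$truth$first_degree, character(0), g$roles,
                            tibble::tibble(gene = character(0),
                                           direction = numeric(0)),
                            g$edges, "SNCA")
    r <- ppr_scores(net, damping = 0.85)
    A <- pasnet:::network_adjacency(net)
    deg <- rowSums(A)
    s <- as.numeric(rownames(A) == "SNCA")
    # dangling rows teleport to the seed
    W <- A / ifelse(deg == 0, 1, deg)
    if (any(deg == 0)) {
      W[deg == 0, ] <- matrix(s, sum(deg == 0), length(s), byrow = TRUE)
    }
    sol <- solve(diag(length(s)) - 0.85 * t(W), 0.15 * s)
    sol <- sol / sum(sol)
    expect_equal(r$ppr, unname(sol[order(rownames(A))]), tolerance = 1e-10)
    expect_equal(sum(r$ppr), 1, tolerance = 1e-10)
  }
})

test_that("relabeling nodes permutes influence scores identically", {
  g <- gen_edgelist(8, 5, 3, seed = 9)
  net <- assemble_network(g$truth$first_degree, character(0), g$roles,
                          tibble::tibble(gene = character(0),
                                         direction = numeric(0)),
                          g$edges, "SNCA")
  ren <- function(x) sub("^FD", "ZZ", x)
  net2 <- pn_network(net$focal,
                     dplyr::mutate(net$nodes, gene = ren(.data$gene)),
                     dplyr::mutate(net$edges, source = ren(.data$source),
                                   target = ren(.data$target)))
  for (fn in list(heat_diffusion_scores,
                  function(n) ppr_scores(n, seed_node = "SNCA"))) {
    s1 <- fn(net)
    s2 <- fn(net2)
    s2$gene <- sub("^ZZ", "FD", s2$gene)
    s2 <- s2[order(s2$gene), ]
    expect_equal(s1[[2]], s2[[2]], tolerance = 1e-12)
  }
})

test_that("quadrant classification follows the >= split convention", {
  heat <- tibble::tibble(gene = c("a", "b", "c", "d"),
                         heat = c(0.9, 0.9, 0.1, 0.1))
  ppr <- tibble::tibble(gene = c("a", "b", "c", "d"),
                        ppr = c(0.9, 0.1, 0.9, 0.1))
  cls <- classify_quadrants(heat, ppr)
  expect_equal(cls$category[match(c("a", "b", "c", "d"), cls$gene)],
               c("master_regulator", "signal_modulator", "hub", "peripheral"))

  # a gene exactly at both medians is high/high
  eq <- tibble::tibble(gene = c("a", "b", "c"), heat = c(1, 2, 3))
  pq <- tibble::tibble(gene = c("a", "b", "c"), ppr = c(1, 2, 3))
  expect_equal(classify_quadrants(eq, pq)$category[2], "master_regulator")

  # degenerate: all identical scores -> all master_regulator
  same <- tibble::tibble(gene = c("a", "b"), heat = 1)
  samep <- tibble::tibble(gene = c("a", "b"), ppr = 1)
  expect_true(all(classify_quadrants(same, samep)$category ==
                    "master_regulator"))

  expect_error(classify_quadrants(heat, ppr[1:3, ]), "different genes")
})
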