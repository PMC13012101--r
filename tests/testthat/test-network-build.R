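test_that("first-degree membership follows direction and membership rules", {
  edges <- tibble::tibble(
    source = c("A", "B", "SNCA", "D", "E"),
    target = c("SNCA", "SNCA", "C", "SNCA", "SNCA"),
    directed = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  # direction rule: only inward edges count
  expect_equal(first_degree_interactors(edges, c("A", "B", "C"), "SNCA"),
               c("A", "B"))
  # membership rule: D is not a PN member
  expect_false("D" %in% first_degree_interactors(edges, c("A", "B"), "SNCA"))
  # undirected edges incident to the focal count as inward
  expect_true("E" %in%
                first_degree_interactors(edges, c("A", "B", "E"), "SNCA"))

  # order-independence and idempotence under edge permutation
  for (s in 1:5) {
    set.seed(s)
    perm <- edges[sample(nrow(edges)), ]
    expect_equal(first_degree_interactors(perm, c("A", "B", "E"), "SNCA"),
                 first_degree_interactors(edges, c("A", "B", "E"), "SNCA"))
  }
})

test_that("relative expression subtracts the reference within each sample", {
  m <- quick_mat(c(5, 7, 4, 3, 3, 2), c("G1", "G2", "SNCA"), c("s1", "s2"))
  rel <- relative_expression(m, "SNCA")
  expect_equal(rel$values["G1", "s1"], 2)
  expect_equal(unname(rel$values["SNCA", ]), c(0, 0))

  lin <- quick_mat(c(8, 8, 2, 2), c("G1", "SNCA"), c("s1", "s2"),
                   scale = "linear")
  expect_error(relative_expression(lin, "SNCA"), "log2")
  rel2 <- relative_expression(to_log2(lin, pseudocount = 0), "SNCA")
  expect_equal(rel2$values["G1", "s1"], 2)

  expect_error(relative_expression(m, "ABSENT"), "ABSENT")
})

test_that("Wilcoxon p-values match exact enumeration and handle edge cases", {
  expect_equal(wilcoxon_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_p(c(2, 2, 2), c(2, 2, 2)), 1)

  # random small-group instances against the independent U-statistic oracle
  set.seed(42)
  for (i in 1:50) {
    n <- sample(2:6, 1)
    m <- sample(2:6, 1)
    x <- round(rnorm(n), 1)  # rounding induces occasional ties
    y <- round(rnorm(m), 1)
    expect_equal(wilcoxon_p(x, y), oracle_wilcoxon_enum(x, y),
                 tolerance = 1e-12)
  }
})

test_that("differential relative expression reports fc, p and q per gene", {
  vals <- rbind(
    SNCA = rep(5, 6),
    G1 = c(1, 2, 3, 4, 5, 6),   # case {1,2,3} vs control {4,5,6}
    G2 = c(7, 8, 9, 7, 8, 9)    # identical groups
  )
  colnames(vals) <- sprintf("s%d", 1:6)
  m <- expr_mat(vals, "log2",
                sample_meta = tibble::tibble(sample = colnames(vals),
                                             group = rep(c("case", "control"),
                                                         each = 3)))
  res <- suppressWarnings(
    differential_relative_expression(relative_expression(m, "SNCA"))
  )
  expect_equal(res$p[res$gene == "G1"], 0.1)
  expect_equal(res$fc[res$gene == "G1"], -3)
  expect_equal(res$fc[res$gene == "G2"], 0)
  expect_equal(res$direction[res$gene == "G2"], 0)
  expect_true(all(res$q >= res$p - 1e-12 & res$q <= 1))

  # complete separation at n = 10/10: fc exact, p matches the tie-free
  # normal-approximation value computed independently
  set.seed(1)
  base <- rnorm(20)
  vals2 <- rbind(SNCA = rep(0, 20),
                 G1 = base + rep(c(1, 0), each = 10) + seq(0, 1e-3, length.out = 20))
  vals2["G1", 1:10] <- vals2["G1", 11:20] + 1.0  # case = control + 1 exactly
  colnames(vals2) <- sprintf("s%d", 1:20)
  m2 <- expr_mat(vals2, "log2",
                 sample_meta = tibble::tibble(sample = colnames(vals2),
                                              group = rep(c("case", "control"),
                                                          each = 10)))
  res2 <- differential_relative_expression(relative_expression(m2, "SNCA"))
  expect_equal(res2$fc[res2$gene == "G1"], 1.0)
  z <- (sum(rank(vals2["G1", ])[1:10]) - 10 * 11 / 2 - 10 * 10 / 2 - 0.5) /
    sqrt(10 * 10 * 21 / 12)
  expect_equal(res2$p[res2$gene == "G1"], 2 * pnorm(-abs(z)), tolerance = 1e-10)

  expect_error(
    differential_relative_expression(relative_expression(m, "SNCA"),
                                     case_label = "missing"),
    "at least 2"
  )
})

test_that("consensus rule counts directional support across datasets", {
  mk <- function(id, gene, fc, q) {
    tibble::tibble(dataset_id = id, gene = gene, fc = fc, p = q, q = q,
                   direction = sign(fc))
  }
  # up in 3 of 6 datasets: included with direction +1
  res <- lapply(1:6, function(d) {
    mk(paste0("ds", d), "G1", fc = if (d <= 3) 1 else 0.1,
       q = if (d <= 3) 0.01 else 0.5)
  })
  cons <- consensus_genes(res)
  expect_equal(cons$gene, "G1")
  expect_equal(cons$direction, 1)
  expect_equal(cons$n_support, 3L)

  # split 2 up / 2 down: excluded
  res2 <- lapply(1:6, function(d) {
    fc <- c(1, 1, -1, -1, 0.1, 0.1)[d]
    mk(paste0("ds", d), "G1", fc, q = if (abs(fc) > 0.3) 0.01 else 0.9)
  })
  expect_equal(nrow(consensus_genes(res2)), 0)

  # the reference gene is never included
  res3 <- lapply(1:2, function(d) mk(paste0("ds", d), "SNCA", 1, 0.001))
  expect_equal(nrow(consensus_genes(res3)), 0)
})

test_that("consensus equals the brute-force rule on random instances", {
  set.seed(11)
  for (rep in 1:10) {
    genes <- sprintf("G%02d", 1:20)
    res <- lapply(1:5, function(d) {
      tibble::tibble(
        dataset_id = paste0("ds", d),
        gene = genes,
        fc = round(rnorm(20, 0, 0.5), 2),
        p = runif(20),
        q = runif(20)^0.5,
        direction = 0
      ) |>
        dplyr::mutate(direction = sign(.data$fc))
    })
    got <- consensus_genes(res)
    want <- brute_force_consensus(res)
    expect_equal(got$gene, want$gene)
    expect_equal(got$direction, want$direction)
    expect_equal(as.integer(got$n_support), as.integer(want$n_support))
  }
})

test_that("upstream integration requires adjacency to the first-degree set", {
  edges <- tibble::tibble(
    source = c("U", "V", "W"),
    target = c("A", "B1", "SNCA"),
    directed = TRUE
  )
  cons <- tibble::tibble(gene = c("U", "V", "W"), direction = c(1, -1, 1),
                         n_support = 3L, n_datasets = 6L)
  up <- integrate_upstream(cons, edges, first_degree = c("A", "C"), "SNCA")
  expect_equal(as.character(up), "U")
  # a gene interacting only with the focal is reported separately
  expect_equal(attr(up, "focal_only"), "W")
})

test_that("network assembly applies sign precedence and validates roles", {
  fd <- c("F1", "F2", "F3", "F4", "F5")
  roles <- tibble::tibble(
    gene = fd,
    role = c("promoter", "promoter", "promoter", "attenuator", "attenuator")
  )
  cons <- tibble::tibble(gene = c("U1", "U2"), direction = c(1, 1),
                         n_support = 3L, n_datasets = 6L)
  edges <- tibble::tibble(source = fd, target = "SNCA", directed = TRUE)
  net <- assemble_network(fd, c("U1", "U2"), roles, cons, edges, "SNCA")
  expect_equal(net$K, 7)
  expect_equal(sum(net$nodes$sign == 1), 5)  # 3 promoters + 2 up-in-disease
  expect_equal(sum(net$nodes$sign == -1), 2)

  # annotation beats consensus direction
  roles2 <- dplyr::bind_rows(roles,
                             tibble::tibble(gene = "U1", role = "attenuator"))
  net2 <- assemble_network(fd, c("U1", "U2"), roles2, cons, edges, "SNCA")
  expect_equal(net2$nodes$sign[net2$nodes$gene == "U1"], -1)

  # empty upstream: K equals the first-degree count
  net3 <- assemble_network(fd, character(0), roles, cons[0, ], edges, "SNCA")
  expect_equal(net3$K, 5)

  # missing role annotations are an error naming the genes
  expect_error(assemble_network(c(fd, "F9"), character(0), roles, cons[0, ],
                                edges, "SNCA"),
               "F9")
})

test_that("planted consensus recovery is monotone in effect size", {
  genes <- c("SNCA", "GA", sprintf("N%02d", 1:20))
  sens <- vapply(c(0.2, 0.6, 1.2), function(eff) {
    hits <- vapply(1:5, function(s) {
      cc <- gen_case_control_sets(
        4, 6, 6, genes,
        tibble::tibble(gene = "GA", direction = 1, effect = eff),
        noise_sd = 0.4, n_consistent = 4, seed = s * 100
      )
      diffs <- lapply(seq_along(cc$datasets), function(i) {
        suppressWarnings(differential_relative_expression(
          relative_expression(cc$datasets[[i]], "SNCA"),
          dataset_id = paste0("ds", i)
        ))
      })
      "GA" %in% consensus_genes(diffs)$gene
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
})
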