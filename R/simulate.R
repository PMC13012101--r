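#' Generate a functional-interaction edge list with planted structure
#'
#' Builds a directed edge list around the focal gene `"SNCA"`: exactly
#' `n_first_degree` genes point into the focal gene, `n_upstream` genes
#' interact with first-degree genes but never with the focal gene, and
#' `n_background` genes interact only among themselves. First-degree genes
#' receive promoter/attenuator roles at the stated ratio.
#'
#' @param n_first_degree,n_background,n_upstream Gene counts (>= 1).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param promoter_frac Fraction of first-degree genes annotated as
#'   promoters; default 0.5.
#' @param p_cross Probability of an extra edge between two first-degree
#'   genes; default 0.3 (keeps the influence graph non-trivial).
#' @param focal Focal gene symbol.
#' @return A list with `edges` (tibble `source`, `target`, `directed`),
#'   `roles` (tibble `gene`, `role`) and `truth` (lists of first-degree,
#'   upstream and background genes).
#' @export
gen_edgelist <- function(n_first_degree, n_background, n_upstream, seed,
                         promoter_frac = 0.5, p_cross = 0.3, focal = "SNCA") {
  stopifnot(n_first_degree >= 1, n_background >= 1, n_upstream >= 1)
  set.seed(seed)
  fd <- sprintf("FD%02d", seq_len(n_first_degree))
  up <- sprintf("UP%02d", seq_len(n_upstream))
  bg <- sprintf("BG%03d", seq_len(n_background))

  edges <- tibble::tibble(source = fd, target = focal, directed = TRUE)
  if (n_first_degree >= 2) {
    pairs <- combn(fd, 2)
    keep <- runif(ncol(pairs)) < p_cross
    if (any(keep)) {
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        source = pairs[1, keep], target = pairs[2, keep], directed = TRUE
      ))
    }
  }
  edges <- dplyr::bind_rows(
    edges,
    tibble::tibble(source = up,
                   target = sample(fd, n_upstream, replace = TRUE),
                   directed = TRUE),
    tibble::tibble(
      source = bg,
      target = sample(bg, n_background, replace = TRUE),
      directed = TRUE
    )
  )
  edges <- as_edge_tbl(edges)

  n_prom <- round(promoter_frac * n_first_degree)
  promoters <- sample(fd, n_prom)
  roles <- tibble::tibble(
    gene = fd,
    role = ifelse(fd %in% promoters, "promoter", "attenuator")
  )
  list(
    edges = edges,
    roles = roles,
    truth = list(first_degree = fd, upstream = up, background = bg,
                 focal = focal, seed = seed)
  )
}

#' Generate case/control log2 expression datasets with planted effects
#'
#' Each dataset is Gaussian log2 noise around per-gene baselines. For each
#' planted gene, its gene:reference log-ratio is shifted by `direction *
#' effect` in the case samples of `n_consistent` randomly chosen datasets;
#' the reference gene `"SNCA"` itself is never perturbed.
#'
#' @param n_datasets Number of datasets (>= 2).
#' @param n_case,n_control Samples per group per dataset (>= 5).
#' @param genes Character vector of gene symbols; must contain `"SNCA"`.
#' @param planted Tibble with columns `gene`, `direction` (+1/-1), `effect`
#'   (log2 units, > 0).
#' @param noise_sd Per-value Gaussian noise sd in log2 units.
#' @param n_consistent Number of datasets carrying each planted effect.
#' @param seed Integer seed.
#' @param reference Reference gene; default `"SNCA"`.
#' @return A list with `datasets` (list of [expr_mat]) and `truth` (the
#'   planted table plus per-gene carrier datasets and the consensus
#'   expectation under the at-least-half rule).
#' @export
gen_case_control_sets <- function(n_datasets, n_case, n_control, genes,
                                  planted, noise_sd, n_consistent, seed,
                                  reference = "SNCA") {
  stopifnot(n_case >= 5, n_control >= 5, n_datasets >= 1,
            n_consistent <= n_datasets)
  planted <- tibble::as_tibble(planted)
  if (!reference %in% genes) abort("`genes` must contain the reference gene.")
  if (reference %in% planted$gene) {
    abort("The reference gene must stay unperturbed.")
  }
  if (!all(planted$gene %in% genes)) abort("Planted genes must be in `genes`.")
  set.seed(seed)
  carried <- lapply(seq_len(nrow(planted)), function(i) {
    sort(sample(n_datasets, n_consistent))
  })
  n_samp <- n_case + n_control
  datasets <- lapply(seq_len(n_datasets), function(d) {
    baseline <- runif(length(genes), 6, 10)
    vals <- matrix(rnorm(length(genes) * n_samp, mean = baseline, sd = noise_sd),
                   nrow = length(genes),
                   dimnames = list(genes, sprintf("D%d_S%02d", d, seq_len(n_samp))))
    group <- c(rep("case", n_case), rep("control", n_control))
    for (i in seq_len(nrow(planted))) {
      if (d %in% carried[[i]]) {
        g <- planted$gene[i]
        vals[g, group == "case"] <- vals[g, group == "case"] +
          planted$direction[i] * planted$effect[i]
      }
    }
    expr_mat(vals, scale = "log2",
             sample_meta = tibble::tibble(sample = colnames(vals), group = group))
  })
  truth <- planted
  truth$carried <- carried
  truth$expected_consensus <- n_consistent >= ceiling(n_datasets / 2)
  list(datasets = datasets, truth = truth)
}

#' Cycle-structured precision matrix with planted partial correlations
#'
#' Unit diagonal, and `-pcor` on the edges of a cycle over the genes, so
#' every cycle edge has true partial correlation exactly `pcor` and every
#' other pair exactly 0. Positive-definite for `|pcor| < 0.5`.
#'
#' @param genes Character vector of gene names (or an integer count).
#' @param pcor Planted partial correlation; default 0.3.
#' @return A named symmetric positive-definite matrix.
#' @export
planted_precision <- function(genes, pcor = 0.3) {
  if (is.numeric(genes) && length(genes) == 1) {
    genes <- sprintf("G%03d", seq_len(genes))
  }
  p <- length(genes)
  stopifnot(p >= 3, abs(pcor) < 0.5)
  omega <- diag(p)
  for (i in seq_len(p)) {
    j <- if (i == p) 1 else i + 1
    omega[i, j] <- omega[j, i] <- -pcor
  }
  dimnames(omega) <- list(genes, genes)
  omega
}

# true partial correlations implied by a precision matrix
precision_to_pcor <- function(omega) {
  d <- 1 / sqrt(diag(omega))
  pc <- -omega * tcrossprod(d)
  diag(pc) <- 1
  pc
}

#' Generate single-cell expression from a known precision matrix
#'
#' Cells are drawn independently from the zero-mean multivariate normal with
#' the given precision, then shifted by a constant (stored in the truth) so
#' values look like positive log2 expression. Optional independent
#' background genes emulate the bulk of a transcriptome around the network
#' block, so per-cell z-scoring across genes behaves as it does on real data.
#'
#' @param precision Symmetric positive-definite matrix with gene dimnames.
#' @param n_cells Number of cells.
#' @param seed Integer seed.
#' @param n_background Independent N(0, 1) genes appended; default 0.
#' @param shift Constant added to every value; default 10.
#' @return A list with `cells` (an [expr_mat], log2 scale) and `truth`
#'   (precision, true pcor matrix, transform, gene names).
#' @export
gen_single_cell <- function(precision, n_cells, seed, n_background = 0,
                            shift = 10) {
  ev <- eigen(precision, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) abort("`precision` must be positive-definite.")
  genes <- rownames(precision)
  if (is.null(genes)) abort("`precision` needs gene dimnames.")
  set.seed(seed)
  sigma <- solve(precision)
  raw <- MASS::mvrnorm(n_cells, mu = rep(0, nrow(precision)), Sigma = sigma)
  vals <- t(raw)
  if (n_background > 0) {
    bgn <- sprintf("BGN%04d", seq_len(n_background))
    vals <- rbind(vals, matrix(rnorm(n_background * n_cells), nrow = n_background,
                               dimnames = list(bgn, NULL)))
    genes <- c(genes, bgn)
  }
  vals <- vals + shift
  dimnames(vals) <- list(genes, sprintf("cell%05d", seq_len(n_cells)))
  cells <- expr_mat(vals, scale = "log2")
  list(
    cells = cells,
    truth = list(precision = precision,
                 pcor = precision_to_pcor(precision),
                 network_genes = rownames(precision),
                 transform = list(shift = shift, scale = 1),
                 seed = seed)
  )
}

#' Generate dose-dependent treatment signatures with planted slopes
#'
#' For every drug x cell line x concentration, the target change in network
#' activity is `slope * log10(concentration) + intercept + noise`; the
#' per-gene differential relative expression is then allocated as
#' `e_i = a_i * target + jitter_i` with the jitter centered so that the
#' recomputed delta-PAS equals the target exactly (the delta-PAS identity is
#' the generator's contract).
#'
#' @param slope_map Named numeric vector: drug id -> slope of delta-PAS per
#'   log10 concentration unit.
#' @param concentrations Ascending positive concentrations (>= 3).
#' @param cell_lines Character vector of cell-line ids.
#' @param network A [pn_network] supplying the signs.
#' @param noise_sd Gaussian noise sd on the per-condition delta-PAS target.
#' @param seed Integer seed.
#' @param intercept Delta-PAS at 1 concentration unit; default 0.
#' @param gene_jitter_sd Sd of the centered per-gene jitter; default 0.05.
#' @return A list with `signatures` (long tibble `drug`, `cell_line`,
#'   `concentration`, `gene`, `e`) and `truth` (tibble `drug`, `slope`).
#' @export
gen_dose_signatures <- function(slope_map, concentrations, cell_lines, network,
                                noise_sd, seed, intercept = 0,
                                gene_jitter_sd = 0.05) {
  stopifnot(length(concentrations) >= 3, all(concentrations > 0),
            all(is.finite(slope_map)), inherits(network, "pn_network"))
  if (network$K == 0) abort("The network is empty.")
  set.seed(seed)
  a <- network_signs(network)
  grid <- tidyr::expand_grid(
    drug = names(slope_map),
    cell_line = cell_lines,
    concentration = concentrations
  )
  sigs <- purrr::pmap(grid, function(drug, cell_line, concentration) {
    target <- slope_map[[drug]] * log10(concentration) + intercept +
      rnorm(1, 0, noise_sd)
    jitter <- rnorm(length(a), 0, gene_jitter_sd)
    e <- a * target + jitter - a * mean(a * jitter)
    tibble::tibble(drug = drug, cell_line = cell_line,
                   concentration = concentration,
                   gene = names(a), e = unname(e))
  }) |>
    dplyr::bind_rows()
  list(
    signatures = sigs,
    truth = tibble::tibble(drug = names(slope_map),
                           slope = unname(slope_map))
  )
}

#' Generate a cell-line baseline nTPM table with a planted activity gradient
#'
#' A stated fraction of lines gets detectable reference expression
#' (`SNCA` nTPM > 2); the rest fall at or below the cutoff. Detectable lines
#' carry a planted activity level: network genes are scaled by
#' `2^(sign * activity_gradient * level)`, so the line-level PAS ranking is
#' monotone in the planted level.
#'
#' @param n_lines Number of cell lines.
#' @param snca_detectable_fraction Fraction (0, 1] with detectable reference.
#' @param network A [pn_network].
#' @param activity_gradient Log2-scale strength of the planted gradient.
#' @param seed Integer seed.
#' @param n_background Background genes beyond the network; default 100.
#' @param noise_sd Per-value log2 jitter; default 0.
#' @param reference Reference gene; default `"SNCA"`.
#' @return A list with `ntpm` (tibble: `line` plus one column per gene) and
#'   `truth` (tibble `line`, `detectable`, `activity`, `planted_rank`).
#' @export
gen_cell_line_table <- function(n_lines, snca_detectable_fraction, network,
                                activity_gradient, seed, n_background = 100,
                                noise_sd = 0, reference = "SNCA") {
  stopifnot(snca_detectable_fraction > 0, snca_detectable_fraction <= 1)
  set.seed(seed)
  lines <- sprintf("L%03d", seq_len(n_lines))
  n_detect <- round(snca_detectable_fraction * n_lines)
  detectable <- c(rep(TRUE, n_detect), rep(FALSE, n_lines - n_detect))
  a <- network_signs(network)
  bg <- sprintf("BGL%03d", seq_len(n_background))
  genes <- c(names(a), bg)
  baseline <- 2^runif(length(genes), 1, 8)
  names(baseline) <- genes
  activity <- rep(NA_real_, n_lines)
  if (n_detect > 0) {
    activity[detectable] <- if (n_detect == 1) 0 else
      seq(-1, 1, length.out = n_detect)
  }
  vals <- matrix(rep(baseline, n_lines), nrow = length(genes),
                 dimnames = list(genes, lines))
  for (j in which(detectable)) {
    vals[names(a), j] <- vals[names(a), j] *
      2^(a * activity_gradient * activity[j])
  }
  if (noise_sd > 0) {
    vals <- vals * 2^matrix(rnorm(length(vals), 0, noise_sd), nrow = nrow(vals))
  }
  snca <- ifelse(detectable, runif(n_lines, 5, 50), runif(n_lines, 0.1, 2))
  ntpm <- tibble::as_tibble(t(vals))
  ntpm[[reference]] <- snca
  ntpm <- dplyr::bind_cols(tibble::tibble(line = lines), ntpm)
  truth <- tibble::tibble(
    line = lines, detectable = detectable, activity = activity
  )
  truth$planted_rank <- NA_integer_
  truth$planted_rank[detectable] <-
    rank(-truth$activity[detectable], ties.method = "first")
  list(ntpm = ntpm, truth = truth)
}
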