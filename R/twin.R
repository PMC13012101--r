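#' Per-cell z-score normalization with frozen statistics
#'
#' Identical to [zscore_within_sample()] but named for the single-cell arm:
#' each cell (column) is standardized over its genes and the per-cell
#' mean/sd are frozen in the result, so perturbation simulations can rescale
#' a modified cell with the baseline statistics.
#'
#' @param cells An [expr_mat] of single-cell expression (genes x cells).
#' @return A [zmat] carrying `norm_stats`.
#' @export
zscore_per_cell <- function(cells) {
  zscore_within_sample(cells)
}

#' Build the linear digital twin from a GGM fit
#'
#' For every ordered gene pair whose partial-correlation edge passes
#' `q < q_cut`, fits the ordinary least-squares slope of the target gene's
#' z-score on the query gene's z-score across cells. All other pairs carry
#' slope zero; there are no self-slopes.
#'
#' @param ggm A [fit_ggm()] result.
#' @param z The [zmat] (or matrix) the GGM was fitted on.
#' @param q_cut Edge significance threshold; default 0.05.
#' @return An object of class `linear_twin` with the slope matrix
#'   (`slopes[target, query]`), the gene set, `q_cut` and the frozen
#'   `norm_stats`.
#' @export
build_linear_twin <- function(ggm, z, q_cut = 0.05) {
  stopifnot(inherits(ggm, "ggm_fit"))
  norm_stats <- ggm$norm_stats
  if (inherits(z, "zmat")) {
    norm_stats <- norm_stats %||% z$norm_stats
    z <- z$values
  }
  z <- z[ggm$genes, , drop = FALSE]
  p <- length(ggm$genes)
  sig <- ggm$q < q_cut
  diag(sig) <- FALSE
  if (!any(sig)) warn("No significant edge at q_cut; the twin is inert.")
  slopes <- matrix(0, p, p, dimnames = list(ggm$genes, ggm$genes))
  centered <- z - rowMeans(z)
  vars <- rowSums(centered^2)
  for (qg in seq_len(p)) {
    tg <- which(sig[, qg])
    if (length(tg) == 0 || vars[qg] == 0) next
    # OLS slope of each target on the query across cells
    slopes[tg, qg] <- (centered[tg, , drop = FALSE] %*% centered[qg, ]) / vars[qg]
  }
  structure(
    list(genes = ggm$genes, slopes = slopes, q_cut = q_cut,
         norm_stats = norm_stats),
    class = "linear_twin"
  )
}

#' @export
print.linear_twin <- function(x, ...) {
  cat(sprintf("<linear_twin> %d genes, %d nonzero slopes (q < %g)\n",
              length(x$genes), sum(x$slopes != 0), x$q_cut))
  invisible(x)
}

#' @export
tidy.linear_twin <- function(x, ...) {
  nz <- which(x$slopes != 0, arr.ind = TRUE)
  tibble::tibble(
    target = x$genes[nz[, 1]],
    query = x$genes[nz[, 2]],
    slope = x$slopes[nz]
  ) |>
    dplyr::arrange(.data$query, .data$target)
}

#' Simulate a single-gene expression perturbation
#'
#' Multiplies the query gene's basal (linear-scale) level by `factor` in
#' every cell, recomputes its z-score with the frozen per-cell mean/sd,
#' shifts every other gene's z-score by `slope(target, query) * dz_query`
#' (one propagation step through the significant edges only), recomputes PAS
#' per cell, and summarizes the shift as Cohen's d against baseline
#' (pooled-sd, n-1 denominators).
#'
#' @param twin A [build_linear_twin()] result.
#' @param cells The baseline [expr_mat] (same cells the twin was trained on).
#' @param network A [pn_network] supplying the PAS signs.
#' @param query Gene to perturb; must be a twin gene.
#' @param factor Multiplier of the basal linear-scale level; > 0.
#' @param norm_stats Frozen per-cell stats; defaults to the ones stored in
#'   the twin.
#' @return An object of class `perturbation_outcome`: `query`, `factor`,
#'   per-cell `pas_baseline` and `pas_perturbed`, and `cohen_d`.
#' @export
simulate_perturbation <- function(twin, cells, network, query, factor,
                                  norm_stats = NULL) {
  stopifnot(inherits(twin, "linear_twin"), inherits(cells, "expr_mat"))
  if (factor <= 0) abort("`factor` must be positive.")
  if (!query %in% twin$genes) abort(sprintf("Query '%s' is not a twin gene.", query))
  norm_stats <- norm_stats %||% twin$norm_stats
  if (is.null(norm_stats)) abort("Frozen `norm_stats` are required.")
  x <- cells$values
  if (!identical(norm_stats$sample, colnames(x))) {
    abort("`norm_stats` do not match the cells of the matrix.")
  }
  mu <- norm_stats$mean
  sdv <- ifelse(norm_stats$sd == 0, 1, norm_stats$sd)

  z_base <- sweep(sweep(x, 2, mu, `-`), 2, sdv, `/`)
  z_base <- z_base[twin$genes, , drop = FALSE]

  # multiply the basal linear level by `factor`; on the log2 scale this is an
  # additive shift of log2(factor)
  dx_query <- if (cells$scale == "log2") {
    rep(log2(factor), ncol(x))
  } else {
    x[query, ] * (factor - 1)
  }
  x_query_new <- x[query, ] + dx_query
  dz_query <- (x_query_new - x[query, ]) / sdv

  z_pert <- z_base + outer(twin$slopes[, query], dz_query)
  z_pert[query, ] <- z_base[query, ] + dz_query

  stats_tbl <- tibble::tibble(sample = colnames(x), mean = 0, sd = 1)
  pas_base <- compute_pas(zmat(z_base, stats_tbl), network)$pas
  pas_pert <- compute_pas(zmat(z_pert, stats_tbl), network)$pas

  structure(
    list(query = query, factor = factor,
         pas_baseline = pas_base, pas_perturbed = pas_pert,
         cohen_d = cohens_d(pas_pert, pas_base)),
    class = "perturbation_outcome"
  )
}

# pooled-sd standardized mean difference, n-1 denominators
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

#' @export
print.perturbation_outcome <- function(x, ...) {
  cat(sprintf("<perturbation_outcome> %s x %g: Cohen's d = %.3f over %d cells\n",
              x$query, x$factor, x$cohen_d, length(x$pas_baseline)))
  invisible(x)
}

#' @export
tidy.perturbation_outcome <- function(x, ...) {
  tibble::tibble(
    query = x$query, factor = x$factor,
    cell = seq_along(x$pas_baseline),
    pas_baseline = x$pas_baseline,
    pas_perturbed = x$pas_perturbed
  )
}

#' @export
glance.perturbation_outcome <- function(x, ...) {
  tibble::tibble(
    query = x$query, factor = x$factor,
    mean_pas_baseline = mean(x$pas_baseline),
    mean_pas_perturbed = mean(x$pas_perturbed),
    cohen_d = x$cohen_d,
    n_cells = length(x$pas_baseline)
  )
}

#' Knockdown/overexpression screen over candidate targets
#'
#' Runs [simulate_perturbation()] for every query x factor combination and
#' ranks queries by the maximum absolute Cohen's d across the ladder. The
#' per-query summary also reports d at the display factors 0.12 (knockdown)
#' and 8 (overexpression) when present in the ladder.
#'
#' @param twin,cells,network,norm_stats As in [simulate_perturbation()].
#' @param queries Character vector of twin genes to perturb.
#' @param factors Multiplier ladder; default the knockdown ladder
#'   `c(0.06, 0.12, 0.25, 0.5, 0.75)` plus the overexpression ladder
#'   `c(1.25, 1.5, 1.75, 2, 4, 8)`.
#' @return A list with `outcomes` (tibble: one row per query x factor) and
#'   `ranking` (tibble: one row per query, ranked by max |d|).
#' @export
perturbation_screen <- function(twin, cells, network, queries,
                                factors = c(0.06, 0.12, 0.25, 0.5, 0.75,
                                            1.25, 1.5, 1.75, 2, 4, 8),
                                norm_stats = NULL) {
  grid <- tidyr::expand_grid(query = queries, factor = factors)
  outcomes <- purrr::pmap(grid, function(query, factor) {
    glance(simulate_perturbation(twin, cells, network, query, factor,
                                 norm_stats = norm_stats))
  }) |>
    dplyr::bind_rows()
  ranking <- outcomes |>
    dplyr::group_by(.data$query) |>
    dplyr::summarise(
      max_abs_d = max(abs(.data$cohen_d)),
      d_knockdown_0.12 = .data$cohen_d[.data$factor == 0.12][1],
      d_overexpression_8 = .data$cohen_d[.data$factor == 8][1],
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$max_abs_d), .data$query)
  ranking$rank <- seq_len(nrow(ranking))
  list(outcomes = outcomes, ranking = ranking)
}
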