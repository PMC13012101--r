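#' Within-sample z-score normalization
#'
#' Standardizes every sample (column) over its genes: `(x - mean) / sd` with
#' the population standard deviation (divisor n). A constant column yields
#' all zeros with a warning. The per-sample mean/sd are stored so they can be
#' frozen and reused when simulating perturbations.
#'
#' @param matrix An [expr_mat] (or relative-expression matrix).
#' @return A [zmat].
#' @export
zscore_within_sample <- function(matrix) {
  stopifnot(inherits(matrix, "expr_mat"))
  x <- matrix$values
  if (nrow(x) < 2) abort("Need >= 2 genes per sample to z-score.")
  mu <- colMeans(x)
  sdv <- apply(x, 2, pop_sd)
  zero <- sdv == 0
  if (any(zero)) {
    warn(sprintf("%d constant sample(s); their z-scores are set to 0.",
                 sum(zero)))
  }
  sd_safe <- ifelse(zero, 1, sdv)
  z <- sweep(sweep(x, 2, mu, `-`), 2, sd_safe, `/`)
  z[, zero] <- 0
  zmat(z,
       norm_stats = tibble::tibble(sample = colnames(x), mean = unname(mu),
                                   sd = unname(sdv)),
       source_scale = matrix$scale)
}

#' Proteostasis activity score per sample
#'
#' `PAS = (1/K) * sum_i a_i * z_i` over the network genes present in the
#' z-matrix, where `a_i` is the node's aggregation-role sign. With
#' `missing_policy = "renormalize"` (default) K is the number of network
#' genes actually present; `"error"` demands full coverage.
#'
#' @param z A [zmat] from [zscore_within_sample()].
#' @param network A [pn_network].
#' @param missing_policy `"renormalize"` or `"error"`.
#' @return A tibble with columns `sample`, `pas`, `K_used`, `n_missing`.
#' @export
compute_pas <- function(z, network, missing_policy = c("renormalize", "error")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(z, "zmat"), inherits(network, "pn_network"))
  a <- network_signs(network)
  present <- names(a)[names(a) %in% rownames(z$values)]
  n_missing <- length(a) - length(present)
  if (length(present) == 0) abort("No network gene present in the matrix.")
  if (missing_policy == "error" && n_missing > 0) {
    abort(sprintf("%d network gene(s) missing from the matrix.", n_missing))
  }
  zi <- z$values[present, , drop = FALSE]
  pas <- as.vector(crossprod(zi, a[present])) / length(present)
  tibble::tibble(
    sample = colnames(z$values),
    pas = pas,
    K_used = length(present),
    n_missing = n_missing
  )
}

#' Change in PAS for a differential-expression signature
#'
#' `dPAS = (1/K) * sum_i a_i * e_i` where `e_i` is the per-gene differential
#' relative expression of a treatment-vs-control signature. Linear in the
#' signature.
#'
#' @param signature Named numeric vector of per-gene differential relative
#'   expression (log2 units).
#' @param network A [pn_network].
#' @param missing_policy `"renormalize"` or `"error"`.
#' @return A single number.
#' @export
compute_delta_pas <- function(signature, network,
                              missing_policy = c("renormalize", "error")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(network, "pn_network"), !is.null(names(signature)))
  a <- network_signs(network)
  present <- names(a)[names(a) %in% names(signature)]
  if (length(present) == 0) abort("No network gene present in the signature.")
  if (missing_policy == "error" && length(present) < length(a)) {
    abort("Signature does not cover all network genes.")
  }
  sum(a[present] * signature[present]) / length(present)
}

#' Compare PAS between groups or against age
#'
#' Group mode: two-sided Wilcoxon rank-sum test ([wilcoxon_p]) on PAS values
#' of two groups, with the median difference. Age mode: Spearman correlation
#' of PAS with age at death.
#'
#' @param results PAS tibble from [compute_pas()].
#' @param sample_meta Tibble with `sample` plus `group` (group mode) or
#'   `age_at_death` (age mode).
#' @param mode `"group"` or `"age"`.
#' @param case_label,control_label Group labels used in group mode.
#' @return A one-row tibble: group mode gives `median_diff`, `p`, group
#'   sizes; age mode gives `rho`, `p`, `n`.
#' @export
compare_pas_groups <- function(results, sample_meta, mode = c("group", "age"),
                               case_label = "case", control_label = "control") {
  mode <- match.arg(mode)
  df <- dplyr::left_join(results, sample_meta, by = "sample",
                         suffix = c(".pas", ""))
  if (mode == "group") {
    x <- df$pas[df$group == case_label]
    y <- df$pas[df$group == control_label]
    if (length(x) < 2 || length(y) < 2) {
      abort("Both groups need at least 2 samples.")
    }
    tibble::tibble(
      case = case_label, control = control_label,
      n_case = length(x), n_control = length(y),
      median_diff = median(x) - median(y),
      p = wilcoxon_p(x, y)
    )
  } else {
    ok <- !is.na(df$age_at_death)
    if (sum(ok) < 4) abort("Age mode needs >= 4 samples with ages.")
    ct <- suppressWarnings(
      cor.test(df$pas[ok], df$age_at_death[ok], method = "spearman")
    )
    tibble::tibble(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  }
}

#' Rank cell lines by baseline network activity
#'
#' Drops lines whose reference-gene nTPM is not above `snca_min`, computes
#' per-line gene:reference ratios (log2 by default), z-scores within each
#' line over all genes, computes PAS over the network genes, z-scores PAS
#' across lines, attaches a two-sided normal p-value and ranks lines by
#' descending PAS.
#'
#' @param ntpm Tibble with a `line` column and one numeric column per gene
#'   (nTPM, linear scale).
#' @param network A [pn_network].
#' @param reference Reference gene column; default `"SNCA"`.
#' @param snca_min Detectability cutoff (strict `>` keeps a line); default 2.
#' @param log_ratio Use log2 of the ratio before z-scoring (default TRUE);
#'   FALSE z-scores the raw ratio.
#' @return A tibble with columns `line`, `pas`, `pas_z`, `p`, `rank`, sorted
#'   by rank.
#' @export
rank_cell_lines <- function(ntpm, network, reference = "SNCA", snca_min = 2,
                            log_ratio = TRUE) {
  ntpm <- tibble::as_tibble(ntpm)
  if (!"line" %in% names(ntpm)) abort("`ntpm` needs a `line` column.")
  if (!reference %in% names(ntpm)) {
    abort(sprintf("Reference gene '%s' absent from the table.", reference))
  }
  keep <- ntpm[[reference]] > snca_min
  if (!any(keep)) abort("All cell lines fall below the detectability cutoff.")
  ntpm <- ntpm[keep, , drop = FALSE]
  genes <- setdiff(names(ntpm), "line")
  vals <- t(as.matrix(ntpm[, genes]))  # genes x lines
  colnames(vals) <- ntpm$line
  ratio <- sweep(vals, 2, vals[reference, ], `/`)
  if (log_ratio) {
    if (any(ratio <= 0)) {
      abort("Zero nTPM values cannot be log-ratioed; use log_ratio = FALSE or filter genes.")
    }
    ratio <- log2(ratio)
  }
  m <- expr_mat(ratio, scale = if (log_ratio) "log2" else "linear",
                sample_meta = tibble::tibble(sample = ntpm$line))
  pas <- compute_pas(zscore_within_sample(m), network)
  pas_z <- as.vector(scale(pas$pas))
  out <- tibble::tibble(
    line = pas$sample,
    pas = pas$pas,
    pas_z = pas_z,
    p = 2 * pnorm(-abs(pas_z))
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$pas), .data$line)
  out$rank <- seq_len(nrow(out))
  out
}
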