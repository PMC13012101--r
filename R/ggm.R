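#' Fit a shrinkage Gaussian graphical model
#'
#' Estimates the gene-gene correlation matrix across cells with analytic
#' identity-target shrinkage (the shrinkage intensity `lambda` is estimated
#' from the data, guaranteeing a positive-definite estimate), inverts it to
#' partial correlations, and assigns each edge a p- and q-value from a
#' two-component empirical-null mixture: the null partial-correlation density
#' `f0(r) ~ (1 - r^2)^((kappa - 3) / 2)` with `kappa` fitted to the central
#' bulk of the observed edges, and a null proportion `eta0` estimated from
#' the p-value distribution.
#'
#' @param z A [zmat] (genes x cells) or a plain numeric matrix with gene
#'   rownames; typically the per-cell z-scores restricted to the network
#'   genes.
#' @param genes Optional character vector restricting the fit to these genes.
#' @param qvalue_method `"empirical_null"` (default) or `"BH"` (plain
#'   Benjamini-Hochberg on the null-density p-values).
#' @return An object of class `ggm_fit` with elements `genes`, `pcor`, `p`,
#'   `q` (symmetric matrices), `shrinkage_lambda`, `kappa`, `eta0`,
#'   `n_cells`, and `norm_stats` (frozen per-cell stats when `z` is a
#'   [zmat]).
#' @export
fit_ggm <- function(z, genes = NULL, qvalue_method = c("empirical_null", "BH")) {
  qvalue_method <- match.arg(qvalue_method)
  norm_stats <- NULL
  if (inherits(z, "zmat")) {
    norm_stats <- z$norm_stats
    z <- z$values
  }
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(z))
    if (length(missing) > 0) {
      abort(paste0("Genes absent from the matrix: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    z <- z[genes, , drop = FALSE]
  }
  p <- nrow(z)
  n <- ncol(z)
  if (n <= 3) abort("Need more than 3 cells to fit a GGM.")
  if (p < 3) abort("Need at least 3 genes to fit a GGM.")

  X <- scale(t(z))                    # cells x genes, per-gene standardized
  X[is.nan(X)] <- 0                   # constant gene guard
  S1 <- crossprod(X)                  # (n-1) * R
  R <- S1 / (n - 1)
  S2 <- crossprod(X^2)                # sum_k w_kij^2
  varw <- n / (n - 1)^3 * (S2 - S1^2 / n)
  off <- upper.tri(R)
  lambda <- sum(varw[off]) / sum(R[off]^2)
  lambda <- min(1, max(lambda, 1e-6))
  Rs <- (1 - lambda) * R
  diag(Rs) <- 1
  omega <- solve(Rs)
  d <- 1 / sqrt(diag(omega))
  pcor <- -omega * tcrossprod(d)
  diag(pcor) <- 1
  pcor <- (pcor + t(pcor)) / 2

  r <- pcor[off]
  kappa <- estimate_null_kappa(r)
  pvals <- pbeta(r^2, 0.5, (kappa - 1) / 2, lower.tail = FALSE)
  eta0 <- min(1, mean(pvals > 0.5) / 0.5)
  qvals <- if (qvalue_method == "empirical_null") {
    pmin(1, eta0 * p.adjust(pvals, method = "BH"))
  } else {
    p.adjust(pvals, method = "BH")
  }
  P <- Q <- matrix(0, p, p, dimnames = dimnames(pcor))
  P[off] <- pvals; P <- P + t(P); diag(P) <- 0
  Q[off] <- qvals; Q <- Q + t(Q); diag(Q) <- 0

  structure(
    list(genes = rownames(z), pcor = pcor, p = P, q = Q,
         shrinkage_lambda = lambda, kappa = kappa, eta0 = eta0,
         n_cells = n, qvalue_method = qvalue_method,
         norm_stats = norm_stats),
    class = "ggm_fit"
  )
}

# Fit the effective degrees of freedom kappa of the null pcor density by
# matching the median |r|: under f0, r^2 ~ Beta(1/2, (kappa-1)/2). Robust to
# a minority of true edges in the tails.
estimate_null_kappa <- function(r) {
  med <- median(abs(r))
  if (med <= 0) return(1e7)
  f <- function(log_kappa) {
    pbeta(med^2, 0.5, (exp(log_kappa) - 1) / 2) - 0.5
  }
  lo <- log(3.5); hi <- log(1e7)
  if (f(hi) < 0) return(1e7)
  if (f(lo) > 0) return(3.5)
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root)
}

#' @export
print.ggm_fit <- function(x, ...) {
  cat(sprintf(
    "<ggm_fit> %d genes, %d cells; lambda = %.4f, kappa = %.1f, eta0 = %.3f; %d edges with q < 0.05\n",
    length(x$genes), x$n_cells, x$shrinkage_lambda, x$kappa, x$eta0,
    sum(x$q[upper.tri(x$q)] < 0.05)
  ))
  invisible(x)
}

#' Edge-level summary of a GGM fit
#'
#' @param x A `ggm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per gene pair: `gene1`, `gene2`, `pcor`,
#'   `p`, `q`.
#' @export
tidy.ggm_fit <- function(x, ...) {
  off <- which(upper.tri(x$pcor), arr.ind = TRUE)
  tibble::tibble(
    gene1 = x$genes[off[, 1]],
    gene2 = x$genes[off[, 2]],
    pcor = x$pcor[off],
    p = x$p[off],
    q = x$q[off]
  ) |>
    dplyr::arrange(.data$q, dplyr::desc(abs(.data$pcor)))
}

#' @export
glance.ggm_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$genes),
    n_cells = x$n_cells,
    shrinkage_lambda = x$shrinkage_lambda,
    kappa = x$kappa,
    eta0 = x$eta0,
    n_edges_q05 = sum(x$q[upper.tri(x$q)] < 0.05)
  )
}
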