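#' Expression matrix container
#'
#' A light genes-by-samples container used throughout the pipeline. `values`
#' is a numeric matrix with gene symbols as rownames and sample ids as
#' colnames; `scale` records whether values are linear or log2; `sample_meta`
#' is a tibble with one row per sample (column `sample`, plus optional
#' `group`, `region`, `braak_stage`, `age_at_death`).
#'
#' @param values Numeric matrix, genes x samples, with dimnames.
#' @param scale One of `"linear"` or `"log2"`.
#' @param sample_meta Optional tibble of per-sample metadata; defaults to a
#'   bare `sample` column taken from `colnames(values)`.
#'
#' @return An object of class `expr_mat`.
#' @export
expr_mat <- function(values, scale = c("log2", "linear"), sample_meta = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry gene rownames and sample colnames.")
  }
  genes <- rownames(values)
  if (any(genes == "" | grepl("\\s", genes))) {
    abort("Gene ids must be non-empty and whitespace-free.")
  }
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    abort(paste0(
      "Duplicate gene ids: ", paste(head(dup, 5), collapse = ", "),
      if (length(dup) > 5) ", ..." else ""
    ))
  }
  if (anyDuplicated(colnames(values))) {
    abort("Duplicate sample names in expression matrix.")
  }
  if (scale == "linear" && any(values < 0, na.rm = TRUE)) {
    abort("Linear-scale expression values must be non-negative.")
  }
  if (is.null(sample_meta)) {
    sample_meta <- tibble::tibble(sample = colnames(values))
  }
  sample_meta <- tibble::as_tibble(sample_meta)
  if (nrow(sample_meta) != ncol(values)) {
    abort("`sample_meta` must have one row per sample column.")
  }
  if (!"sample" %in% names(sample_meta)) {
    abort("`sample_meta` must contain a `sample` column.")
  }
  if (!identical(sample_meta$sample, colnames(values))) {
    abort("`sample_meta$sample` must match the column names, in order.")
  }
  structure(
    list(values = values, scale = scale, sample_meta = sample_meta),
    class = "expr_mat"
  )
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf(
    "<expr_mat> %d genes x %d samples (%s scale)\n",
    nrow(x$values), ncol(x$values), x$scale
  ))
  extra <- setdiff(names(x$sample_meta), "sample")
  if (length(extra) > 0) {
    cat("  sample_meta:", paste(extra, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' Convert an expression matrix to a long tibble
#'
#' @param x An `expr_mat`.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `sample`, `value` joined with the
#'   sample metadata.
#' @export
as_tibble.expr_mat <- function(x, ...) {
  long <- tibble::tibble(
    gene = rep(rownames(x$values), times = ncol(x$values)),
    sample = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
  dplyr::left_join(long, x$sample_meta, by = "sample")
}

#' Convert a linear-scale matrix to log2
#'
#' Applies `log2(x + pseudocount)`; the pseudocount keeps zeros finite.
#'
#' @param x An `expr_mat`.
#' @param pseudocount Added before the log; default 1.
#' @return A log2-scale `expr_mat`.
#' @export
to_log2 <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "expr_mat"))
  if (x$scale == "log2") {
    return(x)
  }
  expr_mat(log2(x$values + pseudocount), scale = "log2",
           sample_meta = x$sample_meta)
}

#' Within-sample z-score matrix container
#'
#' Holds per-sample standardized values together with the frozen per-sample
#' mean/sd used to produce them, so that later perturbation steps can reuse
#' the exact same normalization.
#'
#' @param values Numeric z-score matrix, genes x samples.
#' @param norm_stats Tibble with columns `sample`, `mean`, `sd` (one row per
#'   column of `values`, in order).
#' @param source_scale Provenance note (e.g. `"log2"`).
#' @return An object of class `zmat`.
#' @export
zmat <- function(values, norm_stats, source_scale = "log2") {
  stopifnot(is.matrix(values), nrow(norm_stats) == ncol(values))
  structure(
    list(values = values, norm_stats = tibble::as_tibble(norm_stats),
         source_scale = source_scale),
    class = "zmat"
  )
}

#' @export
print.zmat <- function(x, ...) {
  cat(sprintf("<zmat> %d genes x %d samples (source: %s)\n",
              nrow(x$values), ncol(x$values), x$source_scale))
  invisible(x)
}

# population sd (divisor n), the convention used for all within-sample scores
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}
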