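#' Read an expression table (TSV or GCT)
#'
#' Accepts a plain TSV with a gene-id first column and one column per sample,
#' or a GCT 1.2/1.3 file (detected by its `#1.2`/`#1.3` first line). Column
#' order is preserved exactly as on disk.
#'
#' With `scale_hint = "auto"` the scale is inferred: any negative value, or
#' all values below 50, is taken as log2; otherwise linear. Negative values
#' under an explicit `"linear"` hint are an error.
#'
#' @param path Path to the file.
#' @param scale_hint `"linear"`, `"log2"` or `"auto"`.
#' @param sample_meta Optional tibble of per-sample metadata (column
#'   `sample` matching the file's sample columns, in order).
#' @return An [expr_mat].
#' @export
read_expression_table <- function(path, scale_hint = c("auto", "log2", "linear"),
                                  sample_meta = NULL) {
  scale_hint <- match.arg(scale_hint)
  first <- readLines(path, n = 1L)
  df <- if (grepl("^#1\\.[23]", first)) read_gct(path) else read_tsv_matrix(path)
  vals <- df
  neg <- any(vals < 0, na.rm = TRUE)
  scale <- switch(scale_hint,
    auto = if (neg || all(vals < 50, na.rm = TRUE)) "log2" else "linear",
    log2 = "log2",
    linear = {
      if (neg) abort("Negative values are not allowed on the linear scale.")
      "linear"
    }
  )
  expr_mat(vals, scale = scale, sample_meta = sample_meta)
}

read_tsv_matrix <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header[-1])) {
    abort(paste0("Duplicate sample names: ",
                 paste(unique(header[-1][duplicated(header[-1])]),
                       collapse = ", ")))
  }
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(df) < 2) abort("Expression TSV needs a gene column plus samples.")
  samples <- names(df)[-1]
  if (anyDuplicated(samples)) {
    abort(paste0("Duplicate sample names: ",
                 paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  }
  genes <- df[[1]]
  num <- matrix(NA_real_, nrow = nrow(df), ncol = length(samples),
                dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    col <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(col) & !is.na(df[[j + 1]]))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric value at gene '%s', sample '%s'.",
                    genes[bad[1]], samples[j]))
    }
    num[, j] <- col
  }
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate gene rows (collapse probes first): ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  num
}

# GCT 1.2/1.3: version line, dimension line, then a header whose first two
# columns are id/description followed by samples.
read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) abort("Truncated GCT file.")
  dims <- strsplit(lines[2], "\t")[[1]]
  n_genes <- as.integer(dims[1])
  n_samples <- as.integer(dims[2])
  if (is.na(n_genes) || is.na(n_samples)) abort("Malformed GCT size line.")
  header <- strsplit(lines[3], "\t")[[1]]
  samples <- header[-(1:2)]
  if (length(samples) != n_samples) {
    abort("GCT header sample count disagrees with the size line.")
  }
  # GCT 1.3 interposes row/column metadata counts; only plain layouts with
  # data starting on line 4 are supported here.
  body <- lines[seq(4, length.out = n_genes)]
  cells <- strsplit(body, "\t")
  genes <- vapply(cells, `[[`, character(1), 1L)
  num <- matrix(NA_real_, nrow = n_genes, ncol = n_samples,
                dimnames = list(genes, samples))
  for (i in seq_len(n_genes)) {
    row <- suppressWarnings(as.numeric(cells[[i]][-(1:2)]))
    if (anyNA(row)) {
      abort(sprintf("Non-numeric value in GCT row for gene '%s'.", genes[i]))
    }
    num[i, ] <- row
  }
  if (anyDuplicated(genes)) {
    abort("Duplicate gene ids in GCT file (collapse probes first).")
  }
  num
}

#' Collapse probe-level rows to genes by maximal variance
#'
#' For every gene, the single probe with the largest across-sample variance is
#' kept and re-keyed by the gene symbol. Ties are broken towards the
#' lexicographically smaller probe id. Probes absent from the map are dropped
#' (count reported via a message).
#'
#' @param matrix An [expr_mat] keyed by probe ids.
#' @param probe_map Data frame with columns `probe` and `gene`.
#' @return An [expr_mat] keyed by gene.
#' @export
collapse_probes <- function(matrix, probe_map) {
  stopifnot(inherits(matrix, "expr_mat"))
  probe_map <- tibble::as_tibble(probe_map)
  if (!all(c("probe", "gene") %in% names(probe_map))) {
    abort("`probe_map` needs columns `probe` and `gene`.")
  }
  if (anyDuplicated(probe_map$probe)) {
    abort("Each probe must map to exactly one gene.")
  }
  probes <- rownames(matrix$values)
  unmapped <- setdiff(probes, probe_map$probe)
  if (length(unmapped) > 0) {
    inform(sprintf("Dropping %d probe(s) absent from the probe map.",
                   length(unmapped)))
  }
  kept <- tibble::tibble(probe = intersect(probes, probe_map$probe)) |>
    dplyr::left_join(probe_map, by = "probe") |>
    dplyr::mutate(variance = apply(matrix$values[.data$probe, , drop = FALSE],
                                   1, var)) |>
    dplyr::arrange(.data$gene, dplyr::desc(.data$variance), .data$probe) |>
    dplyr::distinct(.data$gene, .keep_all = TRUE)
  out <- matrix$values[kept$probe, , drop = FALSE]
  rownames(out) <- kept$gene
  expr_mat(out, scale = matrix$scale, sample_meta = matrix$sample_meta)
}

#' Read a functional-interaction edge list
#'
#' The TSV must have columns `source`, `target`, `direction` with direction
#' tokens `->` (directed) or `-` (undirected). Duplicate rows are collapsed
#' and self-loops dropped (count reported via a message).
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `source`, `target`, `directed`.
#' @export
read_edgelist <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    source = readr::col_character(),
    target = readr::col_character(),
    direction = readr::col_character()
  ), progress = FALSE)
  as_edge_tbl(df)
}

# validate/normalize an edge table coming from disk or from a generator
as_edge_tbl <- function(df) {
  df <- tibble::as_tibble(df)
  if (!all(c("source", "target") %in% names(df))) {
    abort("Edge table needs `source` and `target` columns.")
  }
  if ("direction" %in% names(df)) {
    bad <- setdiff(unique(df$direction), c("->", "-"))
    if (length(bad) > 0) {
      abort(paste0("Unknown direction token(s): ", paste(bad, collapse = ", ")))
    }
    df$directed <- df$direction == "->"
    df$direction <- NULL
  } else if (!"directed" %in% names(df)) {
    df$directed <- TRUE
  }
  loops <- df$source == df$target
  if (any(loops)) {
    inform(sprintf("Dropping %d self-loop(s).", sum(loops)))
    df <- df[!loops, , drop = FALSE]
  }
  dplyr::distinct(df, .data$source, .data$target, .data$directed)
}

#' Write a result table deterministically
#'
#' Writes a TSV with a fixed column order, rows sorted by the given keys and
#' floating-point columns rendered at six significant digits, so repeated runs
#' are byte-identical. An empty tibble yields a header-only file.
#'
#' @param records A data frame of results.
#' @param path Output path.
#' @param sort_by Character vector of columns to sort by; defaults to the
#'   first column.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(records, path, sort_by = NULL) {
  records <- tibble::as_tibble(records)
  if (nrow(records) > 0) {
    sort_by <- sort_by %||% names(records)[1]
    ord <- do.call(order, c(unname(records[sort_by]), list(method = "radix")))
    records <- records[ord, , drop = FALSE]
  }
  out <- dplyr::mutate(records, dplyr::across(
    dplyr::where(is.double), ~ formatC(.x, digits = 6, format = "g")
  ))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write an expression matrix as TSV
#'
#' @param x An [expr_mat]; the gene column is written first.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "expr_mat"))
  df <- tibble::as_tibble(cbind(
    tibble::tibble(gene = rownames(x$values)),
    tibble::as_tibble(x$values)
  ))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Serialize a proteostasis network to JSON
#'
#' @param network A [pn_network].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(network, path) {
  stopifnot(inherits(network, "pn_network"))
  obj <- list(
    focal = network$focal,
    nodes = network$nodes,
    edges = network$edges
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a proteostasis network from JSON
#'
#' @param path Path written by [write_network_json()].
#' @return A [pn_network].
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pn_network(
    focal = obj$focal,
    nodes = tibble::as_tibble(obj$nodes),
    edges = tibble::as_tibble(obj$edges)
  )
}
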