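#' Per-signature change in network activity
#'
#' Computes the change in PAS for every treatment signature: the signed mean
#' `(1/K) * sum_i a_i * e_i` over the network genes present in the
#' signature. Signatures with zero network overlap are skipped with a
#' message.
#'
#' @param signatures Long tibble with columns `drug`, `cell_line`,
#'   `concentration`, `gene`, `e` (per-gene differential relative
#'   expression, log2 units).
#' @param network A [pn_network].
#' @return A tibble `drug`, `cell_line`, `concentration`, `delta_pas`,
#'   `n_genes_used`.
#' @export
signature_delta_pas <- function(signatures, network) {
  stopifnot(inherits(network, "pn_network"))
  a <- network_signs(network)
  out <- signatures |>
    dplyr::group_by(.data$drug, .data$cell_line, .data$concentration) |>
    dplyr::summarise(
      delta_pas = {
        e <- setNames(.data$e, .data$gene)
        overlap <- intersect(names(a), names(e))
        if (length(overlap) == 0) NA_real_
        else sum(a[overlap] * e[overlap]) / length(overlap)
      },
      n_genes_used = sum(.data$gene %in% names(a)),
      .groups = "drop"
    )
  skipped <- sum(is.na(out$delta_pas))
  if (skipped > 0) {
    inform(sprintf("Skipping %d signature(s) with no network overlap.", skipped))
  }
  dplyr::filter(out, !is.na(.data$delta_pas))
}

#' Dose-response correlation of delta-PAS with concentration
#'
#' Per drug and cell line, Pearson correlation (Spearman selectable) of
#' delta-PAS with log10 concentration, with a two-sided p-value from the
#' t-transform on `n - 2` degrees of freedom. Replicate signatures at the
#' same concentration are averaged first. Constant delta-PAS gives `r = 0`,
#' `p = 1` by convention. Fewer than 3 distinct concentrations flags the
#' record as undefined (`r_defined = FALSE`).
#'
#' @param deltas Tibble from [signature_delta_pas()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A tibble `drug`, `cell_line`, `r`, `p`, `n_doses`, `r_defined`.
#' @export
dose_response <- function(deltas, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  deltas |>
    dplyr::group_by(.data$drug, .data$cell_line, .data$concentration) |>
    dplyr::summarise(delta_pas = mean(.data$delta_pas), .groups = "drop") |>
    dplyr::group_by(.data$drug, .data$cell_line) |>
    dplyr::group_modify(~ {
      n <- nrow(.x)
      if (n < 3) {
        return(tibble::tibble(r = NA_real_, p = NA_real_, n_doses = n,
                              r_defined = FALSE))
      }
      x <- log10(.x$concentration)
      y <- .x$delta_pas
      if (sd(y) == 0 || sd(x) == 0) {
        return(tibble::tibble(r = 0, p = 1, n_doses = n, r_defined = TRUE))
      }
      r <- cor(x, y, method = method)
      tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      tibble::tibble(r = r, p = 2 * pt(-abs(tstat), df = n - 2),
                     n_doses = n, r_defined = TRUE)
    }) |>
    dplyr::ungroup()
}

#' Per-line drug classification
#'
#' A drug is an inhibitor in a line when `|r| > r_cut` and `p < p_cut` with
#' `r < 0`; a promoter when the same holds with `r > 0`; otherwise `none`.
#'
#' @param dr Dose-response tibble from [dose_response()].
#' @param r_cut Absolute-correlation cutoff (strict `>`); default 0.5.
#' @param p_cut p-value cutoff (strict `<`); default 0.05.
#' @return The input with a `class` column added.
#' @export
classify_drug <- function(dr, r_cut = 0.5, p_cut = 0.05) {
  dr |>
    dplyr::mutate(class = dplyr::case_when(
      !.data$r_defined ~ NA_character_,
      abs(.data$r) > r_cut & .data$p < p_cut & .data$r < 0 ~ "inhibitor",
      abs(.data$r) > r_cut & .data$p < p_cut & .data$r > 0 ~ "promoter",
      TRUE ~ "none"
    ))
}

#' Cross-cell-line concordant drug calls
#'
#' Considers only drugs with a defined dose-response in every listed cell
#' line (the intersection). A drug is called inhibitor/promoter when the
#' sign of `r` agrees in every line, `|r| > r_cut` in every line, and
#' `p < p_cut` in at least one line; otherwise `none`. Drugs present in only
#' one line are returned separately via the `single_line` attribute and are
#' never ranked.
#'
#' @param dr Dose-response tibble covering >= 2 cell lines.
#' @param r_cut,p_cut Cutoffs as in [classify_drug()].
#' @param strict_p Require `p < p_cut` in every line instead of at least one
#'   (default FALSE).
#' @return A tibble `drug`, `class`, `mean_abs_r`, `n_lines`, `concordant`,
#'   plus one `r_<line>` column per cell line; attribute `single_line` lists
#'   drugs not testable across all lines.
#' @export
cross_line_concordance <- function(dr, r_cut = 0.5, p_cut = 0.05,
                                   strict_p = FALSE) {
  dr <- dplyr::filter(dr, .data$r_defined)
  lines <- sort(unique(dr$cell_line))
  if (length(lines) < 2) abort("Need dose-response records from >= 2 cell lines.")
  counts <- dplyr::count(dr, .data$drug)
  complete <- counts$drug[counts$n == length(lines)]
  single <- sort(setdiff(dr$drug, complete))
  calls <- dr |>
    dplyr::filter(.data$drug %in% complete) |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(
      concordant = length(unique(sign(.data$r))) == 1 && all(.data$r != 0),
      all_strong = all(abs(.data$r) > r_cut),
      p_ok = if (strict_p) all(.data$p < p_cut) else any(.data$p < p_cut),
      mean_abs_r = mean(abs(.data$r)),
      direction = sign(.data$r)[1],
      n_lines = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      class = dplyr::case_when(
        .data$concordant & .data$all_strong & .data$p_ok &
          .data$direction < 0 ~ "inhibitor",
        .data$concordant & .data$all_strong & .data$p_ok &
          .data$direction > 0 ~ "promoter",
        TRUE ~ "none"
      )
    )
  wide_r <- dr |>
    dplyr::filter(.data$drug %in% complete) |>
    dplyr::select("drug", "cell_line", "r") |>
    tidyr::pivot_wider(names_from = "cell_line", values_from = "r",
                       names_prefix = "r_")
  out <- calls |>
    dplyr::select("drug", "class", "mean_abs_r", "n_lines", "concordant") |>
    dplyr::left_join(wide_r, by = "drug") |>
    dplyr::arrange(.data$drug)
  attr(out, "single_line") <- single
  out
}

#' Rank drugs of a class by mean absolute correlation
#'
#' @param calls Tibble from [cross_line_concordance()].
#' @param wanted_class Class to rank; default `"inhibitor"`.
#' @return The class subset sorted by descending `mean_abs_r` (ties broken
#'   by drug id), with a `rank` column. Empty with a warning when the class
#'   is absent.
#' @export
prioritize_drugs <- function(calls, wanted_class = "inhibitor") {
  sub <- dplyr::filter(calls, .data$class == wanted_class)
  if (nrow(sub) == 0) {
    warn(sprintf("No drug of class '%s' to rank.", wanted_class))
    sub$rank <- integer(0)
    return(sub)
  }
  sub <- dplyr::arrange(sub, dplyr::desc(.data$mean_abs_r), .data$drug)
  sub$rank <- seq_len(nrow(sub))
  sub
}
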