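#' Default pipeline configuration
#'
#' Sizes and parameters for the end-to-end synthetic run; any element can be
#' overridden via the `config` argument of [run_pipeline()] or a YAML file.
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    n_first_degree = 12L, n_background = 40L, n_upstream = 6L,
    n_datasets = 6L, n_case = 10L, n_control = 10L,
    effect = 1.0, noise_sd = 0.2, n_consistent = 4L,
    fc_cut = 0.3, q_cut = 0.05, adjust = "BH",
    n_cells = 500L, cell_background_genes = 200L, twin_pcor = 0.3,
    n_queries = 3L,
    n_drugs = 20L, cell_lines = c("CL1", "CL2"),
    concentrations = 10^seq(-2, 3),
    drug_noise_sd = 0.05,
    heat_t = 0.1, damping = 0.85
  )
}

#' Run the full synthetic pipeline end to end
#'
#' Generates every input with planted truth, assembles the network, scores
#' PAS, computes influence, fits the digital twin and runs the perturbation
#' screen, then runs the dose-response drug screen — all from one seed — and
#' writes deterministic TSV outputs plus the network JSON to `out_dir`.
#' Running twice with the same config produces byte-identical files.
#'
#' @param config A named list overriding [default_config()], or a path to a
#'   YAML file with the same fields.
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @return Invisibly, a list with the main intermediate objects and result
#'   tibbles.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_config(), config)
  seed <- as.integer(cfg$seed)

  # --- inputs with planted truth -----------------------------------------
  net_in <- gen_edgelist(cfg$n_first_degree, cfg$n_background, cfg$n_upstream,
                         seed = seed)
  genes <- c("SNCA", net_in$truth$first_degree, net_in$truth$upstream,
             net_in$truth$background)
  planted <- tibble::tibble(
    gene = net_in$truth$upstream,
    direction = rep_len(c(1, -1), length(net_in$truth$upstream)),
    effect = cfg$effect
  )
  cc <- gen_case_control_sets(cfg$n_datasets, cfg$n_case, cfg$n_control,
                              genes, planted, cfg$noise_sd, cfg$n_consistent,
                              seed = seed + 1L)

  # --- network assembly ---------------------------------------------------
  pn_members <- c(net_in$truth$first_degree, net_in$truth$background)
  fd <- first_degree_interactors(net_in$edges, pn_members, "SNCA")
  diffs <- purrr::imap(cc$datasets, function(m, i) {
    relative_expression(m, "SNCA") |>
      differential_relative_expression(adjust = cfg$adjust,
                                       dataset_id = sprintf("ds%02d", i))
  })
  cons <- consensus_genes(diffs, fc_cut = cfg$fc_cut, q_cut = cfg$q_cut)
  up <- integrate_upstream(cons, net_in$edges, fd, "SNCA")
  network <- assemble_network(fd, up, net_in$roles, cons, net_in$edges, "SNCA")

  # --- PAS on the case/control datasets ------------------------------------
  pas_tbl <- purrr::imap(cc$datasets, function(m, i) {
    compute_pas(zscore_within_sample(m), network) |>
      dplyr::mutate(dataset_id = sprintf("ds%02d", i), .before = 1) |>
      dplyr::left_join(m$sample_meta, by = "sample")
  }) |>
    dplyr::bind_rows()
  pas_cmp <- purrr::imap(cc$datasets, function(m, i) {
    id <- sprintf("ds%02d", i)
    compare_pas_groups(pas_tbl[pas_tbl$dataset_id == id, ], m$sample_meta) |>
      dplyr::mutate(dataset_id = id, .before = 1)
  }) |>
    dplyr::bind_rows()

  # --- influence ------------------------------------------------------------
  infl <- influence_scores(network, t = cfg$heat_t, damping = cfg$damping)

  # --- digital twin ----------------------------------------------------------
  prec <- planted_precision(network$nodes$gene, pcor = cfg$twin_pcor)
  sc <- gen_single_cell(prec, cfg$n_cells, seed = seed + 2L,
                        n_background = cfg$cell_background_genes)
  z <- zscore_per_cell(sc$cells)
  ggm <- fit_ggm(z, genes = network$nodes$gene)
  twin <- build_linear_twin(ggm, zmat(z$values[network$nodes$gene, , drop = FALSE],
                                      z$norm_stats, z$source_scale))
  queries <- head(infl$gene[order(-infl$heat)], cfg$n_queries)
  queries <- intersect(queries, twin$genes)
  if (length(queries) == 0) queries <- head(twin$genes, cfg$n_queries)
  screen <- perturbation_screen(twin, sc$cells, network, queries)

  # --- drug screen ------------------------------------------------------------
  slopes <- rep_len(c(-1, -0.5, 0, 0.5, 1), cfg$n_drugs)
  names(slopes) <- sprintf("drug%03d", seq_len(cfg$n_drugs))
  ds <- gen_dose_signatures(slopes, cfg$concentrations, cfg$cell_lines,
                            network, cfg$drug_noise_sd, seed = seed + 3L)
  deltas <- signature_delta_pas(ds$signatures, network)
  dr <- dose_response(deltas)
  calls <- cross_line_concordance(dr)
  ranking <- suppressWarnings(prioritize_drugs(calls, "inhibitor"))

  res <- list(
    config = cfg, network = network, consensus = cons,
    differential = dplyr::bind_rows(diffs), pas = pas_tbl,
    pas_comparison = pas_cmp, influence = infl, ggm = ggm, twin = twin,
    perturbation = screen, dose_response = dr, drug_calls = calls,
    drug_ranking = ranking, truth = list(
      edgelist = net_in$truth, case_control = cc$truth,
      single_cell = sc$truth, drugs = ds$truth
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(out_dir, f)
    write_network_json(network, out("network.json"))
    write_result_table(res$differential, out("differential.tsv"),
                       sort_by = c("dataset_id", "gene"))
    write_result_table(cons, out("consensus.tsv"), sort_by = "gene")
    write_result_table(pas_tbl, out("pas.tsv"),
                       sort_by = c("dataset_id", "sample"))
    write_result_table(pas_cmp, out("pas_comparison.tsv"),
                       sort_by = "dataset_id")
    write_result_table(infl, out("influence.tsv"), sort_by = "gene")
    write_result_table(tidy(ggm), out("ggm_edges.tsv"),
                       sort_by = c("gene1", "gene2"))
    write_result_table(screen$outcomes, out("perturbation_outcomes.tsv"),
                       sort_by = c("query", "factor"))
    write_result_table(screen$ranking, out("perturbation_ranking.tsv"),
                       sort_by = "rank")
    write_result_table(dr, out("dose_response.tsv"),
                       sort_by = c("drug", "cell_line"))
    write_result_table(calls, out("drug_calls.tsv"), sort_by = "drug")
    write_result_table(ranking, out("drug_ranking.tsv"), sort_by = "rank")
  }
  invisible(res)
}
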