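# End-to-end pipeline: simulate (or load) -> preprocess -> cluster -> label
# -> differential expression -> signature -> gene-set tests -> markers ->
# clinical summary, with every stage output written to a run directory and a
# report.json aggregating the headline numbers.

#' Pipeline configuration
#'
#' All stage parameters with their defaults, plus the seed. Unknown keys are
#' rejected so a run is reproducible from its config alone.
#'
#' @param ... Overrides of the default fields.
#' @return A list classed `endo_pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1,
    simulate = TRUE,
    counts_path = NULL, samples_path = NULL, gmt_path = NULL,
    sim = sim_config(),
    globin_ids = default_globin_genes(),
    anchor_genes = default_anchor_genes(),
    n_clusters = 3,
    fc_min = 1.5, fdr_max = 0.05,
    signature_k = 20, signature_fc_min = 2, signature_var_quantile = 0.5,
    signature_min_mean_count = 100,
    rotations = 999,
    marker_pairs = default_marker_pairs()
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("Unknown pipeline config keys: ", paste(unknown, collapse = ", ")),
          class = "endoseq_config_error")
  }
  cfg <- utils::modifyList(defaults, overrides)
  structure(cfg, class = "endo_pipeline_config")
}

config_hash <- function(config) {
  hash(lapply(unclass(config), function(x) if (is.function(x)) deparse(x) else x))
}

#' Run the full endotype-discovery pipeline
#'
#' Executes every stage and writes its outputs (`counts.tsv`, `samples.tsv`,
#' `vst.tsv`, `sizefactors.tsv`, `endotypes.tsv`, `de.tsv`, `signature.tsv`,
#' `genesets.tsv`, `markers.tsv`, `clinical_summary.tsv`, `report.json`,
#' `run_info.json`) to `outdir`. `run_info.json` records the config hash and
#' seed that produced the run. Returns the stage results invisibly.
#'
#' @param config An `endo_pipeline_config`.
#' @param outdir Run directory (created if missing); `NULL` to skip writing.
#' @return Invisibly, a list of stage results plus `report`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  if (isTRUE(config$simulate)) {
    sim <- simulate_cohort(config$sim, seed = config$seed)
    counts <- sim$counts; samples <- sim$samples; sets <- sim$sets
    truth <- sim$truth
  } else {
    counts <- read_counts(config$counts_path)
    samples <- read_sample_table(config$samples_path)
    sets <- if (!is.null(config$gmt_path)) read_gmt(config$gmt_path) else NULL
    truth <- NULL
  }

  prep <- preprocess_counts(counts, samples, config$globin_ids)
  dend <- cluster_samples(prep$vst)
  assignment <- assign_endotypes(dend, config$n_clusters, vst = prep$vst) |>
    label_endotypes(prep$vst, config$anchor_genes)
  de <- nb_wald_de(prep$counts, prep$sf, assignment, prep$dispersion)
  lists <- de_genes(de, config$fc_min, config$fdr_max)
  sig <- select_signature(prep$vst, prep$counts, assignment, de,
                          k = config$signature_k,
                          fc_min = config$signature_fc_min,
                          var_quantile = config$signature_var_quantile,
                          min_mean_count = config$signature_min_mean_count,
                          sf = prep$sf)
  self_val <- validate_signature(sig, prep$vst, assignment)

  sig_roast <- roast_test(prep$vst, assignment, sig$gene,
                          B = config$rotations, seed = config$seed)
  sig_camera <- camera_test(prep$vst, assignment, sig$gene)
  gs <- NULL
  if (!is.null(sets)) {
    universe <- rownames(prep$vst)
    query <- intersect(c(lists$up_in_a, lists$up_in_b), universe)
    gs <- ora(query, universe, sets)
  }
  mk <- marker_present <- all(c(config$marker_pairs$numerator,
                                config$marker_pairs$denominator) %in%
                              rownames(prep$vst))
  mk <- if (marker_present) {
    marker_ratios(prep$vst, assignment, config$marker_pairs)
  } else NULL

  clin <- if (!is.null(truth)) {
    simulate_clinical(truth, config$sim, seed = config$seed + 1)
  } else NULL
  clin_summary <- if (!is.null(clin)) {
    cs <- clin
    cs$endotype <- assignment$label[match(cs$patient_id, assignment$sample_id)]
    clinical_summary(cs[!is.na(cs$endotype), , drop = FALSE])
  } else NULL

  report <- list(
    config_hash = unname(config_hash(config)),
    seed = config$seed,
    n_genes = nrow(prep$counts), n_samples = ncol(prep$counts),
    cluster_sizes = as.list(table(assignment$label)),
    n_up_in_a = length(lists$up_in_a), n_up_in_b = length(lists$up_in_b),
    signature_genes = sig$gene,
    signature_self_agreement = self_val$agreement_fraction,
    signature_roast_p = sig_roast$p_value,
    signature_camera_p = sig_camera$p_value,
    top_gene_sets = if (!is.null(gs)) utils::head(gs[order(gs$p_value), ], 5) else NULL,
    marker_p = if (!is.null(mk)) setNames(as.list(mk$summary$p_value),
                                          mk$summary$pair) else NULL,
    truth_ari = if (!is.null(truth)) {
      adjusted_rand_index(
        assignment$label,
        truth$samples$group[match(assignment$sample_id, truth$samples$sample_id)])
    } else NULL
  )

  results <- list(counts = prep$counts, samples = samples, prep = prep,
                  dend = dend, assignment = assignment, de = de,
                  de_lists = lists, signature = sig, self_validation = self_val,
                  roast = sig_roast, camera = sig_camera, ora = gs,
                  markers = mk, clinical = clin, clinical_summary = clin_summary,
                  truth = truth, report = report)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_counts(prep$counts, file.path(outdir, "counts.tsv"))
    readr::write_tsv(samples, file.path(outdir, "samples.tsv"))
    vst_df <- data.frame(gene_id = rownames(prep$vst), unclass(prep$vst),
                         check.names = FALSE)
    readr::write_tsv(vst_df, file.path(outdir, "vst.tsv"))
    readr::write_tsv(tibble(sample_id = names(prep$sf), size_factor = prep$sf),
                     file.path(outdir, "sizefactors.tsv"))
    readr::write_tsv(assignment, file.path(outdir, "endotypes.tsv"))
    readr::write_tsv(de, file.path(outdir, "de.tsv"))
    readr::write_tsv(tibble::as_tibble(sig), file.path(outdir, "signature.tsv"))
    if (!is.null(gs)) readr::write_tsv(gs, file.path(outdir, "genesets.tsv"))
    if (!is.null(mk)) readr::write_tsv(mk$summary, file.path(outdir, "markers.tsv"))
    if (!is.null(clin_summary)) {
      readr::write_tsv(select(clin_summary, -"ema"),
                       file.path(outdir, "clinical_summary.tsv"))
    }
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(
      list(config_hash = unname(config_hash(config)), seed = config$seed,
           files = list.files(outdir)),
      file.path(outdir, "run_info.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(results)
}
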