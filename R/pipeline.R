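# End-to-end orchestration: normalize -> subtype -> instability ->
# enrichment -> kinase -> integration -> survival, with a JSON run report.

#' Run the full analysis pipeline on a cohort
#'
#' Takes the matrices/metadata of a cohort (real, read with the `read_*`
#' functions, or synthetic from [simulate_cohort()]), executes every stage in
#' order, writes all stage outputs as TSV plus a JSON run report to
#' `out_dir`, and returns the results. Re-running with the same inputs and
#' seed reproduces all outputs.
#'
#' @param cohort List with elements `protein`, `phospho`, `mrna`, `cna`,
#'   `samples`, `segments`, `ks_map`, `gene_sets` (as from
#'   [simulate_cohort()]); `mrna`, `cna`, `segments`, `ks_map`, `gene_sets`
#'   may be `NULL` to skip their stages. An optional `truth` element adds
#'   label-recovery metrics to the report.
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @param genome A `genome_build` for the instability stage; default the
#'   bundled GRCh37-like build.
#' @param top_n,k_range,n_init Clustering parameters (see
#'   [prepare_nmf_input()], [rank_survey()]).
#' @param k_override Optional fixed cluster number.
#' @param min_valid_frac,knn_k Normalization parameters.
#' @param seed Integer seed governing every stochastic stage.
#' @return List with `normalized` (protein/phospho), `survey`, `subtypes`,
#'   `instability`, `enrichment`, `kinase`, `cis_trans`, `survival_os`,
#'   `survival_rfs`, `report`.
#' @export
run_pipeline <- function(cohort, out_dir = NULL, genome = NULL,
                         top_n = 500, k_range = 2:7, n_init = 200,
                         k_override = NULL, min_valid_frac = 0.30,
                         knn_k = 10, seed = 1L) {
  t0 <- proc.time()[["elapsed"]]
  report <- list(seed = seed,
                 version = as.character(utils::packageVersion("lmsproteo")),
                 params = list(top_n = top_n, k_range = range(k_range),
                               n_init = n_init, min_valid_frac = min_valid_frac,
                               knn_k = knn_k),
                 stages = list())
  stage <- function(name, expr) {
    ts <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    report$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - ts, 2),
                                   completed = TRUE)
    out
  }
  if (is.null(genome) && !is.null(cohort$segments)) {
    genome <- read_genome_build(system.file("extdata", "genome_grch37.tsv",
                                            package = "lmsproteo"))
  }

  norm_p <- stage("normalize_protein",
                  normalize_tmt(cohort$protein, cohort$samples,
                                min_valid_frac, knn_k))
  norm_ph <- stage("normalize_phospho",
                   normalize_tmt(cohort$phospho, cohort$samples,
                                 min_valid_frac, knn_k))
  tumor_ids <- cohort$samples$sample_id[!cohort$samples$is_pooled_reference]
  prot_t <- subset_omics(norm_p$matrix,
                         samples = intersect(sample_ids(norm_p$matrix), tumor_ids))
  phos_t <- subset_omics(norm_ph$matrix,
                         samples = intersect(sample_ids(norm_ph$matrix), tumor_ids))

  V <- stage("nmf_input", prepare_nmf_input(prot_t, phos_t, top_n = top_n))
  survey <- stage("rank_survey",
                  rank_survey(V, k_range = k_range, n_init = n_init, seed = seed))
  subtypes <- stage("assign_subtypes", assign_subtypes(survey, k_override))
  report$chosen_k <- subtypes$chosen_k

  instability <- NULL
  if (!is.null(cohort$segments)) {
    instability <- stage("instability", score_instability(cohort$segments, genome))
  }
  enrichment <- NULL
  if (!is.null(cohort$gene_sets)) {
    enrichment <- stage("ssgsea", {
      suppressWarnings(ssgsea_scores(prot_t, cohort$gene_sets))
    })
  }
  kinase <- NULL
  if (!is.null(cohort$ks_map)) {
    kinase <- stage("kinase", {
      sites <- expand_sites(phos_t)
      lab <- subtypes$labels[sample_ids(sites)]
      contrasts <- lapply(sort(unique(lab)), function(cl) {
        fc <- rowMeans(sites$values[, lab == cl, drop = FALSE]) -
          rowMeans(sites$values[, lab != cl, drop = FALSE])
        kinase_scores(fc, cohort$ks_map)
      })
      stats::setNames(contrasts, sort(unique(lab)))
    })
  }
  cis_trans <- NULL
  if (!is.null(cohort$cna)) {
    cis_trans <- stage("cis_trans",
                       cis_trans_map(cohort$cna, cohort$mrna, prot_t))
  }
  surv_os <- surv_rfs <- NULL
  if ("os_time" %in% names(cohort$samples)) {
    surv_os <- stage("survival_os",
                     km_logrank(cohort$samples, subtypes$labels, "os"))
    surv_rfs <- stage("survival_rfs",
                      km_logrank(cohort$samples, subtypes$labels, "rfs"))
    report$logrank_os_p <- surv_os$p
    report$logrank_rfs_p <- surv_rfs$p
  }
  if (!is.null(cohort$truth)) {
    report$ari_vs_truth <- adjusted_rand_index(
      subtypes$labels[tumor_ids], cohort$truth$labels[tumor_ids])
  }
  report$total_seconds <- round(proc.time()[["elapsed"]] - t0, 2)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_matrix(prot_t, file.path(out_dir, "protein_normalized.tsv"))
    write_matrix(phos_t, file.path(out_dir, "phospho_normalized.tsv"))
    utils::write.table(survey$table, file.path(out_dir, "rank_survey.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(sample_id = names(subtypes$labels),
                                  subtype = unname(subtypes$labels)),
                       file.path(out_dir, "subtypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(instability)) {
      utils::write.table(instability, file.path(out_dir, "instability.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(cis_trans)) {
      utils::write.table(cis_trans$records, file.path(out_dir, "cis_trans.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(normalized = list(protein = prot_t, phospho = phos_t,
                         reports = list(protein = norm_p$report,
                                        phospho = norm_ph$report)),
       survey = survey, subtypes = subtypes, instability = instability,
       enrichment = enrichment, kinase = kinase, cis_trans = cis_trans,
       survival_os = surv_os, survival_rfs = surv_rfs, report = report)
}
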