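# End-to-end orchestration: simulate -> discover -> enrich -> survival,
# writing every stage's tables so a run is fully reproducible from its output
# directory. All randomness derives from the simulation config seed.

default_tf_specs <- function(truth, final_ids, n_genes_ids) {
  met_ids <- truth$met_deg$gene_id
  list(
    # GTRD-style meta-cluster sets: two TFs planted on the metastasis genes,
    # three null TFs
    EZH2  = list(targets = met_ids, p1 = 0.6, p0 = 0.05),
    SUZ12 = list(targets = met_ids, p1 = 0.35, p0 = 0.05),
    TP63  = list(targets = character(), p1 = 0.05, p0 = 0.05),
    CBX7  = list(targets = character(), p1 = 0.05, p0 = 0.05),
    RNF2  = list(targets = character(), p1 = 0.05, p0 = 0.05),
    # tumor / normal AR binding plus co-occupying pioneers, anchored so
    # co-occupancy happens at the peak level
    AR_tumor  = list(targets = final_ids, p1 = 0.6, p0 = 0.10, condition = "tumor"),
    AR_normal = list(targets = final_ids, p1 = 0.25, p0 = 0.10, condition = "normal"),
    FOXA1  = list(targets = final_ids, p1 = 0.5, p0 = 0.10, condition = "tumor",
                  anchor = "AR_tumor"),
    HOXB13 = list(targets = final_ids, p1 = 0.5, p0 = 0.10, condition = "tumor",
                  anchor = "AR_tumor")
  )
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates a cohort, runs the discovery cascade, the TF enrichment and ARBS
#' annotation stage, and the prognostic survival screen, writing every
#' intermediate and final table into `outdir`. Given identical configs
#' (including seeds) two runs produce byte-identical outputs.
#'
#' @param sim_cfg A [sim_config()].
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @param tf_specs TF peak simulation specs (see [simulate_peaks()]); a
#'   default set (two planted + three null meta-cluster TFs, AR tumor/normal,
#'   FOXA1 and HOXB13 anchored to tumor AR) is built from the truth.
#' @param n_surv Patients in the simulated prognostic cohort.
#' @return List of class `pipeline_result`: `cohort`, `discovery`,
#'   `enrichment`, `arbs`, `screen`, `outdir`.
#' @export
run_pipeline <- function(sim_cfg = sim_config(), config = pipeline_config(),
                         outdir, tf_specs = NULL, n_surv = 200) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  peak_dir <- file.path(outdir, "peaks")
  dir.create(peak_dir, showWarnings = FALSE)

  cohort <- simulate_cohort(sim_cfg)
  write_counts(cohort$counts, file.path(outdir, "counts.tsv"))
  write_samples(cohort$samples, file.path(outdir, "samples.tsv"))
  write_annotation(cohort$annotation, file.path(outdir, "genes.tsv"))
  jsonlite::write_json(cohort$truth, file.path(outdir, "truth.json"),
                       dataframe = "columns", digits = NA)

  disc <- run_discovery(cohort$counts, cohort$samples, config)
  de_tab <- as.data.frame(disc$de)
  write_tsv_strict(de_tab, file.path(outdir, "de_primary_vs_met.tsv"))
  write_tsv_strict(disc$decisions, file.path(outdir, "discovery_report.tsv"))
  write_tsv_strict(as.data.frame(disc$final), file.path(outdir, "final_degs.tsv"))
  jsonlite::write_json(
    list(stage_counts = disc$stage_counts,
         n_genes = disc$n_genes,
         matched_patients = disc$matched_patients,
         expression_values = disc$expression_values,
         n_final = nrow(disc$final)),
    file.path(outdir, "discovery_summary.json"),
    dataframe = "columns", digits = NA, auto_unbox = TRUE)

  final_ids <- disc$final$gene_id
  if (is.null(tf_specs))
    tf_specs <- default_tf_specs(cohort$truth, final_ids, cohort$annotation$gene_id)
  peaks <- simulate_peaks(cohort$annotation, tf_specs,
                          upstream = config$upstream, downstream = config$downstream,
                          seed = sim_cfg$seed + 1L)
  for (nm in names(peaks))
    write_bed_peaks(peaks[[nm]], file.path(peak_dir, paste0(nm, ".bed")))

  windows <- regulatory_windows(cohort$annotation, config$upstream, config$downstream)
  enrichment <- NULL
  arbs <- NULL
  if (length(final_ids)) {
    meta_sets <- peaks[vapply(peaks, function(p) p$condition == "metacluster", TRUE)]
    enrichment <- tf_enrichment(final_ids, windows, meta_sets,
                                alpha = config$alpha_enrich,
                                background = config$enrich_background)
    write_tsv_strict(as.data.frame(enrichment), file.path(outdir, "enrichment.tsv"))
    deg_windows <- windows[windows$gene_id %in% final_ids, , drop = FALSE]
    arbs <- annotate_arbs(deg_windows, peaks$AR_tumor, peaks$AR_normal,
                          peaks$FOXA1, peaks$HOXB13)
    write_tsv_strict(arbs$flags, file.path(outdir, "arbs_annotation.tsv"))
  } else {
    message("no final DEGs; enrichment and ARBS stages skipped")
  }

  screen_ids <- union(final_ids, cohort$truth$prognostic$gene_id)
  screen <- NULL
  if (length(screen_ids)) {
    prog <- simulate_prognostic_cohort(screen_ids, cohort$truth$prognostic,
                                       n = n_surv,
                                       censoring_fraction = sim_cfg$censoring_fraction,
                                       seed = sim_cfg$seed + 2L)
    write_tsv_strict(prog$expression, file.path(outdir, "expression.tsv"),
                     row_names_col = "gene_id")
    write_survival(prog$records, file.path(outdir, "survival.tsv"))
    screen <- prognostic_screen(screen_ids, prog$expression, prog$records,
                                alpha = config$alpha_surv)
    write_tsv_strict(screen$km, file.path(outdir, "km_screen.tsv"))
    write_tsv_strict(screen$cox, file.path(outdir, "cox_results.tsv"))
    write_tsv_strict(data.frame(gene_id = screen$independent, stringsAsFactors = FALSE),
                     file.path(outdir, "independent_predictors.tsv"))
  }

  jsonlite::write_json(
    list(n_final_degs = length(final_ids),
         n_enriched_tfs = if (is.null(enrichment)) 0L else sum(enrichment$enriched),
         arbs_summary = if (is.null(arbs)) NULL else as.list(arbs$summary),
         n_prognostic_hits = if (is.null(screen)) 0L else length(screen$significant),
         n_independent = if (is.null(screen)) 0L else length(screen$independent)),
    file.path(outdir, "pipeline_summary.json"), digits = NA, auto_unbox = TRUE)

  structure(list(cohort = cohort, discovery = disc, enrichment = enrichment,
                 arbs = arbs, screen = screen, peaks = peaks, outdir = outdir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$discovery)
  if (!is.null(x$enrichment))
    cat(sprintf("enrichment: %d TF(s) enriched\n", sum(x$enrichment$enriched)))
  if (!is.null(x$screen))
    cat(sprintf("prognosis: %d significant, %d independent predictor(s)\n",
                length(x$screen$significant), length(x$screen$independent)))
  cat(sprintf("outputs in %s\n", x$outdir))
  invisible(x)
}
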