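#' Pipeline configuration
#'
#' Bundles the thresholds and geometry parameters used across the discovery,
#' enrichment and survival stages. Each alpha is the adjusted-p cutoff for one
#' stage; the comparison rule (`<=` vs `<`) is encoded per stage, not globally:
#' the discovery contrast keeps genes at adjusted p `<= alpha_de`, while the
#' control filters, enrichment and survival screens use strict `<`.
#'
#' @param alpha_de Adjusted-p cutoff for the primary-vs-metastasis call
#'   (inclusive; default 0.1).
#' @param alpha_filter Strict cutoff for the three tissue-control filters
#'   (default 0.01).
#' @param alpha_enrich Strict cutoff for TF enrichment (default 0.15; 0.1 is
#'   the stricter value used in some reports and can be set here).
#' @param alpha_surv Strict cutoff for the prognostic screens (default 0.05).
#' @param upstream,downstream Regulatory-window extent around the TSS in bp
#'   (defaults 15000 and 2000).
#' @param max_divergent_patients Pairwise filter tolerance: a gene is dropped
#'   when more than this many matched patients change in the direction
#'   opposite the cohort-level call (default 2).
#' @param two_primary_rule How a patient with two primary tumors enters the
#'   pairwise filter: `"any"` (divergent if either comparison diverges,
#'   default) or `"mean"` (average the primaries first).
#' @param enrich_background `"exclusive"` (background genes exclude the DEGs;
#'   default, giving disjoint 2x2 cells) or `"inclusive"`.
#' @param seed Integer seed driving every stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha_de = 0.1,
                            alpha_filter = 0.01,
                            alpha_enrich = 0.15,
                            alpha_surv = 0.05,
                            upstream = 15000,
                            downstream = 2000,
                            max_divergent_patients = 2,
                            two_primary_rule = c("any", "mean"),
                            enrich_background = c("exclusive", "inclusive"),
                            seed = 1L) {
  two_primary_rule <- match.arg(two_primary_rule)
  enrich_background <- match.arg(enrich_background)
  for (a in c(alpha_de, alpha_filter, alpha_enrich, alpha_surv))
    if (!is.numeric(a) || a <= 0 || a >= 1)
      md_stop("config", "each alpha must lie strictly between 0 and 1")
  if (upstream < 0 || downstream < 0)
    md_stop("config", "window offsets must be >= 0")
  if (max_divergent_patients < 0)
    md_stop("config", "max_divergent_patients must be >= 0")
  structure(list(alpha_de = alpha_de, alpha_filter = alpha_filter,
                 alpha_enrich = alpha_enrich, alpha_surv = alpha_surv,
                 upstream = upstream, downstream = downstream,
                 max_divergent_patients = max_divergent_patients,
                 two_primary_rule = two_primary_rule,
                 enrich_background = enrich_background,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; omitted keys fall back to the
#' [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) md_stop("missing_file", sprintf("file not found: %s", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) md_stop("config", sprintf("unknown config key(s): %s",
                                             paste(bad, collapse = ", ")))
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  DE call:        adj p <= %g (metastasis vs primary)\n", x$alpha_de))
  cat(sprintf("  tissue filters: adj p <  %g\n", x$alpha_filter))
  cat(sprintf("  enrichment:     adj p <  %g, window -%d/+%d bp of TSS, %s background\n",
              x$alpha_enrich, x$upstream, x$downstream, x$enrich_background))
  cat(sprintf("  survival:       p < %g\n", x$alpha_surv))
  cat(sprintf("  pairwise:       drop if > %d divergent patients (two-primary rule: %s)\n",
              x$max_divergent_patients, x$two_primary_rule))
  cat(sprintf("  seed:           %d\n", x$seed))
  invisible(x)
}
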