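# The discovery cascade: initial metastasis-vs-primary DEG call, three
# tissue-control filters with the opposing-direction rule, and the per-patient
# pairwise concordance filter. Every control contrast is oriented
# prostate-side over control-side, so a DEG with metastasis-direction d is
# tissue-driven (and removed) exactly when the control contrast is significant
# with sign -d: "high in the control tissue" then explains "high in the
# metastases growing at that tissue".

filter_decision <- function(gene_id, stage, kept, reason,
                            stat_log2fc = NA_real_, stat_adj_p = NA_real_,
                            detail = NA_character_) {
  if (!length(gene_id))
    return(data.frame(gene_id = character(), stage = character(), kept = logical(),
                      reason = character(), control_log2fc = numeric(),
                      control_adj_p = numeric(), detail = character(),
                      stringsAsFactors = FALSE))
  data.frame(gene_id = gene_id, stage = stage, kept = kept, reason = reason,
             control_log2fc = stat_log2fc, control_adj_p = stat_adj_p,
             detail = detail, stringsAsFactors = FALSE)
}

# The opposing-direction removal rule shared by all three control filters.
control_opposes <- function(d, control_log2fc, control_adj_p, alpha) {
  !is.na(control_adj_p) & control_adj_p < alpha &
    sign(control_log2fc) == -d
}

split_design <- function(samples) {
  list(primaries = samples$sample_id[samples$category == "primary"],
       mets = samples$sample_id[samples$category == "metastasis"],
       normals = samples$sample_id[samples$category == "normal"],
       bph = samples$sample_id[samples$category == "bph"])
}

#' Per-tissue baseline control filter
#'
#' For every non-prostate normal tissue with at least two samples, contrasts
#' all primary tumors against that tissue's normals. A DEG (metastasis
#' direction `d`) is removed when any such contrast is significant
#' (adjusted p < `alpha`) with a fold change of sign `-d`, i.e. when its
#' apparent metastasis change is explained by baseline expression of the
#' tissue the metastases grow in. Tissues with fewer than two normal samples
#' are skipped with a warning.
#'
#' @param degs A `deg_call` from [call_degs()].
#' @param counts Full count matrix.
#' @param samples Sample design table.
#' @param alpha Strict adjusted-p cutoff (default 0.01).
#' @return data.frame of filter decisions (stage `tissue_per`).
#' @export
tissue_baseline_filter <- function(degs, counts, samples, alpha = 0.01) {
  samples <- validate_samples(samples)
  dn <- split_design(samples)
  norm_tab <- table(samples$tissue[samples$category == "normal"])
  tissues <- names(norm_tab)[norm_tab >= 2]
  if (!length(tissues))
    md_stop("config", "per-tissue filter needs >= 1 non-prostate normal tissue with >= 2 samples")
  skipped <- setdiff(names(norm_tab), tissues)
  if (length(skipped))
    md_warn("config", sprintf("normal tissue(s) with < 2 samples skipped by per-tissue filter: %s",
                              paste(skipped, collapse = ", ")))
  per_tissue <- lapply(tissues, function(t) {
    ids <- samples$sample_id[samples$category == "normal" & samples$tissue == t]
    nb_wald_test(counts, contrast(dn$primaries, ids))
  })
  names(per_tissue) <- tissues
  idx <- match(degs$gene_id, rownames(counts))
  out <- lapply(seq_len(nrow(degs)), function(i) {
    d <- degs$direction[i]
    for (t in tissues) {
      r <- per_tissue[[t]]
      lfc <- r$log2fc[idx[i]]
      ap <- r$adj_p[idx[i]]
      if (isTRUE(control_opposes(d, lfc, ap, alpha)))
        return(filter_decision(degs$gene_id[i], "tissue_per", FALSE,
                               sprintf("baseline expression in %s", t), lfc, ap, t))
    }
    filter_decision(degs$gene_id[i], "tissue_per", TRUE, "no opposing per-tissue control change")
  })
  do.call(rbind, out)
}

#' Pooled non-prostate control filter
#'
#' One contrast of all primary tumors against all non-prostate normal samples
#' combined; removal rule as in [tissue_baseline_filter()]. Catches genes with
#' generally higher (or lower) expression outside the prostate.
#'
#' @inheritParams tissue_baseline_filter
#' @return data.frame of filter decisions (stage `tissue_pooled`).
#' @export
pooled_tissue_filter <- function(degs, counts, samples, alpha = 0.01) {
  samples <- validate_samples(samples)
  dn <- split_design(samples)
  if (length(dn$normals) < 2)
    md_stop("config", "pooled filter needs >= 2 non-prostate normal samples")
  r <- nb_wald_test(counts, contrast(dn$primaries, dn$normals))
  idx <- match(degs$gene_id, rownames(counts))
  lfc <- r$log2fc[idx]
  ap <- r$adj_p[idx]
  rem <- control_opposes(degs$direction, lfc, ap, alpha)
  filter_decision(degs$gene_id, "tissue_pooled", !rem,
                  ifelse(rem, "higher baseline outside prostate",
                         "no opposing pooled-control change"), lfc, ap)
}

#' Benign-prostate (BPH) control filter
#'
#' Contrasts BPH prostate controls against the pooled non-prostate normals;
#' removal rule as in [tissue_baseline_filter()]. Catches genes whose apparent
#' metastasis change reflects prostate-vs-other-tissue differences already
#' present in benign tissue.
#'
#' @inheritParams tissue_baseline_filter
#' @return data.frame of filter decisions (stage `bph`).
#' @export
bph_filter <- function(degs, counts, samples, alpha = 0.01) {
  samples <- validate_samples(samples)
  dn <- split_design(samples)
  if (length(dn$bph) < 2) md_stop("config", "BPH filter needs >= 2 BPH samples")
  if (length(dn$normals) < 2) md_stop("config", "BPH filter needs >= 2 pooled normal samples")
  r <- nb_wald_test(counts, contrast(dn$bph, dn$normals))
  idx <- match(degs$gene_id, rownames(counts))
  lfc <- r$log2fc[idx]
  ap <- r$adj_p[idx]
  rem <- control_opposes(degs$direction, lfc, ap, alpha)
  filter_decision(degs$gene_id, "bph", !rem,
                  ifelse(rem, "BPH vs normal-tissue difference",
                         "no opposing BPH control change"), lfc, ap)
}

#' Per-patient pairwise concordance filter
#'
#' For each patient with both a primary tumor and metastases, compares the
#' mean normalized expression over that patient's metastases with the
#' normalized expression of their primary. A patient is divergent for a gene
#' when this within-patient change has sign opposite the cohort-level
#' metastasis direction; a zero difference counts as concordant. A patient
#' with two primaries contributes one comparison per primary and is divergent
#' if any comparison diverges (`two_primary_rule = "any"`, default) or is
#' first averaged (`"mean"`). Genes divergent in more than
#' `max_divergent` patients are removed.
#'
#' @param degs A `deg_call`.
#' @param norm_counts Normalized count matrix (full cohort).
#' @param samples Sample design table.
#' @param max_divergent Maximum tolerated divergent patients (default 2).
#' @param two_primary_rule `"any"` or `"mean"`.
#' @return data.frame of filter decisions (stage `pairwise`) with the
#'   per-patient direction vector in `detail`.
#' @export
pairwise_concordance_filter <- function(degs, norm_counts, samples,
                                        max_divergent = 2,
                                        two_primary_rule = c("any", "mean")) {
  two_primary_rule <- match.arg(two_primary_rule)
  samples <- validate_samples(samples)
  prim <- samples[samples$category == "primary", ]
  met <- samples[samples$category == "metastasis", ]
  matched <- intersect(unique(prim$patient_id), unique(met$patient_id))
  if (!length(matched)) md_stop("config", "pairwise filter needs >= 1 matched patient")
  idx <- match(degs$gene_id, rownames(norm_counts))
  if (anyNA(idx)) md_stop("config", "DEG absent from normalized count matrix")
  # per patient: matrix (genes x comparisons) of sign(mean met - primary)
  pat_sign <- lapply(matched, function(p) {
    met_ids <- met$sample_id[met$patient_id == p]
    prim_ids <- prim$sample_id[prim$patient_id == p]
    met_mean <- rowMeans(norm_counts[idx, met_ids, drop = FALSE])
    if (two_primary_rule == "mean" && length(prim_ids) > 1) {
      sg <- sign(met_mean - rowMeans(norm_counts[idx, prim_ids, drop = FALSE]))
      matrix(sg, ncol = 1)
    } else {
      vapply(prim_ids, function(s) sign(met_mean - norm_counts[idx, s]),
             numeric(length(idx)))
    }
  })
  d <- degs$direction
  divergent <- vapply(pat_sign, function(sg) {
    # divergent if ANY of this patient's comparisons opposes d
    rowSums(matrix(sg == -d, nrow = length(d))) > 0
  }, logical(length(d)))
  divergent <- matrix(divergent, nrow = length(d))
  n_div <- rowSums(divergent)
  rem <- n_div > max_divergent
  detail <- apply(divergent, 1, function(v) paste(ifelse(v, "-", "+"), collapse = ""))
  filter_decision(degs$gene_id, "pairwise", !rem,
                  ifelse(rem,
                         sprintf("divergent in %d of %d matched patients", n_div, length(matched)),
                         "concordant within patients"),
                  detail = detail)
}

#' Run the full metastasis-associated gene discovery cascade
#'
#' Executes, in order: the metastasis-vs-primary NB Wald call (adjusted p
#' `<= alpha_de`), the per-tissue, pooled and BPH control filters (strict
#' `< alpha_filter`), and the pairwise concordance filter. All design
#' preconditions are checked before any model is fit.
#'
#' @param counts Count matrix (genes x samples).
#' @param samples Sample design table.
#' @param config A [pipeline_config()].
#' @return A `discovery_report`: list with the full `de` result, the initial
#'   `degs` call, per-stage `decisions`, reconciled `stage_counts`, and the
#'   `final` DEG table.
#' @export
run_discovery <- function(counts, samples, config = pipeline_config()) {
  validate_counts(counts)
  samples <- validate_samples(samples)
  if (!all(samples$sample_id %in% colnames(counts)))
    md_stop("config", "sample table contains ids absent from the count matrix")
  dn <- split_design(samples)
  if (length(dn$primaries) < 2 || length(dn$mets) < 2)
    md_stop("config", "discovery needs >= 2 primary and >= 2 metastasis samples")
  norm_tab <- table(samples$tissue[samples$category == "normal"])
  if (!any(norm_tab >= 2))
    md_stop("config", "discovery needs >= 1 non-prostate normal tissue with >= 2 samples")
  if (length(dn$bph) < 2)
    md_stop("config", "discovery needs >= 2 BPH samples")
  matched <- intersect(samples$patient_id[samples$category == "primary"],
                       samples$patient_id[samples$category == "metastasis"])
  if (!length(matched))
    md_stop("config", "discovery needs >= 1 patient with both primary and metastasis samples")

  de <- nb_wald_test(counts, contrast(dn$mets, dn$primaries))
  degs <- call_degs(de, config$alpha_de)
  dec_de <- filter_decision(degs$gene_id, "de", TRUE,
                            sprintf("adj p <= %g", config$alpha_de),
                            degs$log2fc, degs$adj_p)

  cur <- degs
  run_stage <- function(fun, ...) {
    if (nrow(cur) == 0)
      return(filter_decision(character(), "empty", logical(), character()))
    fun(cur, ...)
  }
  dec_t <- run_stage(tissue_baseline_filter, counts, samples, config$alpha_filter)
  cur <- cur[cur$gene_id %in% dec_t$gene_id[dec_t$kept], , drop = FALSE]
  dec_p <- run_stage(pooled_tissue_filter, counts, samples, config$alpha_filter)
  cur <- cur[cur$gene_id %in% dec_p$gene_id[dec_p$kept], , drop = FALSE]
  dec_b <- run_stage(bph_filter, counts, samples, config$alpha_filter)
  cur <- cur[cur$gene_id %in% dec_b$gene_id[dec_b$kept], , drop = FALSE]
  nc <- normalized_counts(counts)
  dec_w <- run_stage(pairwise_concordance_filter, nc, samples,
                     config$max_divergent_patients, config$two_primary_rule)
  cur <- cur[cur$gene_id %in% dec_w$gene_id[dec_w$kept], , drop = FALSE]

  decisions <- rbind(dec_de, dec_t, dec_p, dec_b, dec_w)
  decisions <- decisions[decisions$stage != "empty", , drop = FALSE]
  rownames(decisions) <- NULL

  stage_counts <- do.call(rbind, lapply(
    list(dec_de, dec_t, dec_p, dec_b, dec_w), function(dec) {
      if (!nrow(dec)) return(NULL)
      kept_ids <- dec$gene_id[dec$kept]
      dirs <- degs$direction[match(kept_ids, degs$gene_id)]
      data.frame(stage = dec$stage[1], n_in = nrow(dec), n_kept = length(kept_ids),
                 n_up = sum(dirs > 0), n_down = sum(dirs < 0),
                 stringsAsFactors = FALSE)
    }))
  rownames(cur) <- NULL
  structure(list(de = de, degs = degs, decisions = decisions,
                 stage_counts = stage_counts, final = cur,
                 n_genes = nrow(counts), config = config,
                 matched_patients = matched,
                 expression_values = "median-of-ratios normalized counts"),
            class = "discovery_report")
}

#' @export
print.discovery_report <- function(x, ...) {
  cat(sprintf("<discovery_report> %d genes, %d matched patient(s)\n",
              x$n_genes, length(x$matched_patients)))
  print(x$stage_counts, row.names = FALSE)
  cat(sprintf("final: %d metastasis-associated gene(s) (%d up, %d down)\n",
              nrow(x$final), sum(x$final$direction > 0), sum(x$final$direction < 0)))
  invisible(x)
}

#' @export
summary.discovery_report <- function(object, ...) {
  print(object)
  if (nrow(object$final)) {
    cat("\nTop genes by adjusted p:\n")
    print(utils::head(object$final[order(object$final$adj_p), ], 10), row.names = FALSE)
  }
  invisible(object)
}
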