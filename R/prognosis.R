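# Prognostic screening: third-quartile expression stratification,
# Kaplan-Meier / log-rank comparison, clinical covariate coding and
# multivariate Cox proportional-hazards regression (Efron ties), all built on
# the survival package.

#' Stratify values at the third quartile
#'
#' Q3 is the type-7 (linear interpolation) quantile; a value is `high` when
#' strictly greater than Q3, `low` otherwise, so roughly a quarter of a
#' continuous sample is labeled high.
#'
#' @param values Named numeric vector (one value per patient/sample).
#' @return Character vector of labels "high"/"low", names preserved.
#' @export
stratify_by_q3 <- function(values) {
  if (length(values) < 4) md_stop("stratification", "need >= 4 values to stratify")
  if (anyNA(values)) md_stop("stratification", "missing expression values")
  if (diff(range(values)) == 0)
    md_stop("degenerate_stratification", "all expression values equal; cannot stratify")
  q3 <- stats::quantile(values, 0.75, type = 7, names = FALSE)
  labs <- ifelse(values > q3, "high", "low")
  if (length(unique(labs)) < 2)
    md_stop("degenerate_stratification", "stratification produced a single group")
  stats::setNames(labs, names(values))
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' @param records Survival table (see [read_survival()]), or any data.frame
#'   with `sample_id`, `time`, `event`.
#' @param labels Named character vector of group labels (names = sample ids),
#'   or unnamed in record order.
#' @return List of class `km_result`: `surv` (per-group step function table
#'   with at-risk counts), `chisq`, `df`, `p`, `n`, `n_events`.
#' @export
km_logrank <- function(records, labels) {
  if (!is.null(names(labels))) {
    labels <- labels[records$sample_id]
    if (anyNA(labels)) md_stop("config", "labels missing for some survival records")
  }
  if (length(labels) != nrow(records))
    md_stop("config", "need one label per survival record")
  if (length(unique(labels)) != 2)
    md_stop("config", "log-rank comparison needs exactly two groups")
  if (sum(records$event) == 0)
    md_stop("undefined_test", "log-rank test undefined with zero events")
  grp <- factor(labels)
  fit <- survival::survfit(survival::Surv(records$time, records$event) ~ grp)
  sm <- summary(fit)
  surv <- data.frame(group = sub("^grp=", "", as.character(sm$strata)),
                     time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
                     survival = sm$surv, stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(records$time, records$event) ~ grp)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  structure(list(surv = surv, chisq = unname(sd$chisq), df = 1L, p = p,
                 n = nrow(records), n_events = sum(records$event)),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("<km_result> n = %d, events = %d, log-rank chi-square = %.3f, p = %.4g\n",
              x$n, x$n_events, x$chisq, x$p))
  invisible(x)
}

#' Encode clinical covariates into the standard prognostic groups
#'
#' Age: low <= 62 < high. PSA (ng/mL): low <= 10, intermediate (10, 20),
#' high >= 20. Gleason score: low < 7, intermediate = 7, high > 7 (missing
#' scores are flagged, and excluded from Cox fits with a count). Pathologic T:
#' low = pT2a/pT2b, high = pT3a/pT3b. The first level of each factor is the
#' reference.
#'
#' @param records Survival table.
#' @return data.frame with sample_id and factors `age_group`, `psa_group`,
#'   `gs_group`, `pt_group`, plus logical `complete`.
#' @export
encode_covariates <- function(records) {
  bad_pt <- setdiff(unique(records$pt_stage[!is.na(records$pt_stage)]),
                    c("pT2a", "pT2b", "pT3a", "pT3b"))
  if (length(bad_pt))
    md_stop("vocabulary", sprintf("unmappable pT label(s): %s", paste(bad_pt, collapse = ", ")))
  age_group <- factor(ifelse(records$age <= 62, "low", "high"), levels = c("low", "high"))
  psa_group <- factor(ifelse(records$psa <= 10, "low",
                             ifelse(records$psa < 20, "intermediate", "high")),
                      levels = c("low", "intermediate", "high"))
  gs_group <- factor(ifelse(records$gleason < 7, "low",
                            ifelse(records$gleason == 7, "intermediate", "high")),
                     levels = c("low", "intermediate", "high"))
  pt_group <- factor(ifelse(records$pt_stage %in% c("pT2a", "pT2b"), "low", "high"),
                     levels = c("low", "high"))
  out <- data.frame(sample_id = records$sample_id, age_group = age_group,
                    psa_group = psa_group, gs_group = gs_group, pt_group = pt_group,
                    stringsAsFactors = FALSE)
  out$complete <- stats::complete.cases(out[c("age_group", "psa_group", "gs_group", "pt_group")])
  out
}

#' Multivariate Cox proportional-hazards fit
#'
#' Fits expression group (high vs low) together with the encoded clinical
#' covariates by partial likelihood with Efron tie handling. Records with
#' missing covariates (typically the Gleason score) are excluded and counted.
#' Covariates constant over the used records are dropped with a warning;
#' non-convergence or infinite coefficients are flagged.
#'
#' @param records Survival table.
#' @param expression_labels Named "high"/"low" labels per sample id (from
#'   [stratify_by_q3()]), or NULL for a clinical-covariates-only model.
#' @param covariates Character vector of covariate columns to include
#'   (default all four encoded groups).
#' @return List of class `cox_fit`: `terms` data.frame (term, level, beta,
#'   rr, lower, upper, p), `n_used`, `n_excluded`, `converged`, `dropped`.
#' @export
cox_multivariate <- function(records, expression_labels = NULL,
                             covariates = c("age_group", "psa_group", "gs_group", "pt_group")) {
  enc <- encode_covariates(records)
  dat <- data.frame(time = records$time, event = records$event, enc,
                    stringsAsFactors = FALSE)
  if (!is.null(expression_labels)) {
    labs <- expression_labels[records$sample_id]
    if (anyNA(labs)) md_stop("config", "expression labels missing for some survival records")
    dat$expression <- factor(labs, levels = c("low", "high"))
    covariates <- c("expression", covariates)
  }
  keep <- stats::complete.cases(dat[covariates])
  n_excluded <- sum(!keep)
  dat <- dat[keep, , drop = FALSE]
  if (sum(dat$event) < 1) md_stop("undefined_test", "no events among usable records")
  const <- covariates[vapply(covariates, function(v) length(unique(dat[[v]])) < 2, TRUE)]
  if (length(const)) {
    md_warn("degenerate_design", sprintf("constant covariate(s) dropped: %s",
                                         paste(const, collapse = ", ")))
    covariates <- setdiff(covariates, const)
  }
  if (!length(covariates)) md_stop("degenerate_design", "no usable covariates remain")
  dat[covariates] <- lapply(dat[covariates], droplevels)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  s <- summary(fit)
  beta <- stats::coef(fit)
  converged <- all(is.finite(beta)) && fit$iter < 100 &&
    all(is.finite(sqrt(diag(fit$var))))
  terms <- data.frame(term = names(beta),
                      beta = unname(beta),
                      rr = unname(exp(beta)),
                      lower = unname(s$conf.int[, "lower .95"]),
                      upper = unname(s$conf.int[, "upper .95"]),
                      se = unname(s$coefficients[, "se(coef)"]),
                      p = unname(s$coefficients[, "Pr(>|z|)"]),
                      stringsAsFactors = FALSE)
  structure(list(terms = terms, n_used = nrow(dat), n_excluded = n_excluded,
                 n_events = sum(dat$event), converged = converged,
                 dropped = const, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d (%d excluded), events = %d%s\n",
              x$n_used, x$n_excluded, x$n_events,
              if (x$converged) "" else " [NOT CONVERGED]"))
  t <- x$terms
  t$rr_ci <- sprintf("%.3f (%.3f-%.3f)", t$rr, t$lower, t$upper)
  print(t[c("term", "rr_ci", "p")], row.names = FALSE)
  invisible(x)
}

#' Prognostic screen over a DEG list
#'
#' Per gene: stratify patients at the third quartile of normalized expression,
#' log-rank test for progression-free survival; genes with log-rank
#' p < `alpha` proceed to a multivariate Cox model (expression group plus
#' clinical covariates) and are independent predictors when the expression
#' term keeps Wald p < `alpha` there. Genes that cannot be stratified
#' (constant expression) are recorded and skipped, never fatal.
#'
#' @param deg_ids Genes to screen.
#' @param expression Normalized expression matrix (genes x samples).
#' @param records Survival table; sample ids must match expression columns.
#' @param alpha Strict p cutoff for both screens (default 0.05).
#' @return List of class `prognostic_screen`: `km` (per-gene log-rank table),
#'   `cox` (per-gene expression-term results), `independent` (gene ids),
#'   `skipped` (gene and reason).
#' @export
prognostic_screen <- function(deg_ids, expression, records, alpha = 0.05) {
  missing_genes <- setdiff(deg_ids, rownames(expression))
  unmatched <- setdiff(records$sample_id, colnames(expression))
  if (length(unmatched))
    md_stop("config", sprintf("survival records with no expression column: %s",
                              paste(utils::head(unmatched, 3), collapse = ", ")))
  skipped <- list()
  if (length(missing_genes))
    skipped <- list(data.frame(gene_id = missing_genes, reason = "not in expression matrix",
                               stringsAsFactors = FALSE))
  km_rows <- list()
  cox_rows <- list()
  for (g in intersect(deg_ids, rownames(expression))) {
    vals <- expression[g, records$sample_id]
    labs <- tryCatch(stratify_by_q3(stats::setNames(vals, records$sample_id)),
                     metadeg_error = function(e) e)
    if (inherits(labs, "condition")) {
      skipped <- c(skipped, list(data.frame(gene_id = g, reason = conditionMessage(labs),
                                            stringsAsFactors = FALSE)))
      next
    }
    km <- km_logrank(records, labs)
    km_rows <- c(km_rows, list(data.frame(gene_id = g, chisq = km$chisq, p = km$p,
                                          n_high = sum(labs == "high"),
                                          stringsAsFactors = FALSE)))
    if (km$p < alpha) {
      cf <- withCallingHandlers(
        cox_multivariate(records, labs),
        metadeg_warning = function(w) invokeRestart("muffleWarning"))
      expr_term <- cf$terms[cf$terms$term == "expressionhigh", , drop = FALSE]
      if (nrow(expr_term) == 1 && cf$converged) {
        cox_rows <- c(cox_rows, list(data.frame(
          gene_id = g, beta = expr_term$beta, rr = expr_term$rr,
          lower = expr_term$lower, upper = expr_term$upper, p = expr_term$p,
          n_used = cf$n_used, n_excluded = cf$n_excluded,
          independent = expr_term$p < alpha, stringsAsFactors = FALSE)))
      } else {
        skipped <- c(skipped, list(data.frame(gene_id = g, reason = "Cox fit not usable",
                                              stringsAsFactors = FALSE)))
      }
    }
  }
  km_tab <- if (length(km_rows)) do.call(rbind, km_rows) else
    data.frame(gene_id = character(), chisq = numeric(), p = numeric(),
               n_high = integer(), stringsAsFactors = FALSE)
  cox_tab <- if (length(cox_rows)) do.call(rbind, cox_rows) else
    data.frame(gene_id = character(), beta = numeric(), rr = numeric(),
               lower = numeric(), upper = numeric(), p = numeric(),
               n_used = integer(), n_excluded = integer(), independent = logical(),
               stringsAsFactors = FALSE)
  skip_tab <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(gene_id = character(), reason = character(), stringsAsFactors = FALSE)
  structure(list(km = km_tab, cox = cox_tab,
                 significant = km_tab$gene_id[km_tab$p < alpha],
                 independent = cox_tab$gene_id[cox_tab$independent],
                 skipped = skip_tab, alpha = alpha,
                 quantile_method = "type 7 (linear interpolation), high strictly > Q3"),
            class = "prognostic_screen")
}

#' @export
print.prognostic_screen <- function(x, ...) {
  cat(sprintf("<prognostic_screen> %d gene(s) screened, %d with log-rank p < %g, %d independent predictor(s)\n",
              nrow(x$km), length(x$significant), x$alpha, length(x$independent)))
  if (nrow(x$skipped)) cat(sprintf("  skipped: %d\n", nrow(x$skipped)))
  invisible(x)
}
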