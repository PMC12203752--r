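# Synthetic cohort generator. Counts follow, per gene g and sample s,
#   count ~ NB(mean = L_s * 2^(b_g + u_patient(s) + t_{g,tissue(s)} +
#                              d_g * I[s is metastasis]),
#              var = mu + alpha_g * mu^2)
# with gene baselines b_g, shared patient random effects u (the dominant
# clustering factor in autopsy cohorts, and what the pairwise filter
# exploits), tissue-specific effects t for a planted gene subset (nonzero in
# that tissue's metastases AND normals), and planted metastasis effects d.
# The default design mirrors a 25-patient autopsy cohort: metastases at five
# sites (liver 12, adrenal 7, bone 18, subdural 6, lymph node 39), six
# patients with matched primaries (one with two), normal controls for liver
# (14), adrenal (5) and bone (14), and seven BPH prostate controls.

#' Simulation configuration
#'
#' Defaults emulate the study design described above. Tissue-specific
#' confounder genes are planted only in tissues that have normal control
#' samples (liver, adrenal, bone), because signatures of tissues without
#' controls are structurally invisible to the control filters.
#'
#' @param n_genes Number of genes.
#' @param n_patients Number of autopsy patients (each contributes >= 1 metastasis).
#' @param site_counts Named integer vector of metastasis counts per tissue.
#' @param n_matched Patients with a primary tumor sample.
#' @param two_primary One matched patient carries two primary samples
#'   (generated whenever `n_matched >= 1`).
#' @param n_normals Named integer vector of normal-sample counts per
#'   non-prostate tissue.
#' @param n_bph BPH prostate control samples.
#' @param baseline_log2_mean,baseline_log2_sd Gene baseline `b_g` distribution
#'   (log2 scale).
#' @param sigma_patient SD of the patient random effect (log2 scale).
#' @param dispersion_meanlog,dispersion_sdlog Log-normal parameters of the
#'   per-gene NB dispersion `alpha_g`.
#' @param n_met_up,n_met_down Planted metastasis-associated genes per direction.
#' @param met_lfc Planted |log2 fold change| for metastasis genes.
#' @param n_tissue_specific Named integer vector: planted tissue-signature
#'   genes per tissue.
#' @param tissue_lfc Planted |log2| tissue effect.
#' @param n_prognostic Planted prognostic genes (affect survival simulation,
#'   not counts).
#' @param prognostic_loghr True log hazard ratio (high vs low expression) of
#'   planted prognostic genes.
#' @param lib_size_range Range of per-sample relative depth factors `L_s`.
#' @param censoring_fraction Target censoring fraction for survival simulation.
#' @param disjoint_planted Draw the planted sets without overlap (default).
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000,
                       n_patients = 25,
                       site_counts = c(liver = 12, adrenal = 7, bone = 18,
                                       subdural = 6, lymph_node = 39),
                       n_matched = 6,
                       two_primary = TRUE,
                       n_normals = c(liver = 14, adrenal = 5, bone = 14),
                       n_bph = 7,
                       baseline_log2_mean = 5,
                       baseline_log2_sd = 2,
                       sigma_patient = 0.5,
                       dispersion_meanlog = log(0.1),
                       dispersion_sdlog = 0.5,
                       n_met_up = 150,
                       n_met_down = 150,
                       met_lfc = 1.5,
                       n_tissue_specific = c(liver = 70, adrenal = 60, bone = 70),
                       tissue_lfc = 6,
                       n_prognostic = 5,
                       prognostic_loghr = log(2),
                       lib_size_range = c(0.7, 1.4),
                       censoring_fraction = 0.3,
                       disjoint_planted = TRUE,
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  if (n_genes < 1 || n_patients < 1) md_stop("config", "need >= 1 gene and >= 1 patient")
  if (sum(site_counts) < n_patients)
    md_stop("config", "need at least one metastasis per patient: sum(site_counts) >= n_patients")
  if (n_matched > n_patients) md_stop("config", "n_matched cannot exceed n_patients")
  if (n_matched < 1) md_stop("config", "empty sample design: need >= 1 matched patient")
  bad_tissue <- setdiff(names(n_tissue_specific), setdiff(TISSUES, "prostate"))
  if (length(bad_tissue))
    md_stop("config", sprintf("unknown tissue in n_tissue_specific: %s",
                              paste(bad_tissue, collapse = ", ")))
  n_planted <- n_met_up + n_met_down + sum(n_tissue_specific) + n_prognostic
  if (disjoint_planted && n_planted > n_genes)
    md_stop("config", sprintf("planted sets (%d genes) exceed n_genes (%d)", n_planted, n_genes))
  if (censoring_fraction < 0 || censoring_fraction >= 1)
    md_stop("config", "censoring_fraction must lie in [0, 1)")
  if (length(lib_size_range) != 2 || any(lib_size_range <= 0))
    md_stop("config", "lib_size_range must be two positive numbers")
  cfg$seed <- as.integer(seed)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d genes; %d patients, %d metastases, %d matched primaries; seed %d\n",
              x$n_genes, x$n_patients, sum(x$site_counts),
              x$n_matched + (x$two_primary && x$n_matched >= 1), x$seed))
  cat(sprintf("  planted: %d up / %d down at |log2FC| %g; tissue genes %s at |log2| %g; %d prognostic\n",
              x$n_met_up, x$n_met_down, x$met_lfc,
              paste(sprintf("%s=%d", names(x$n_tissue_specific), x$n_tissue_specific),
                    collapse = ","), x$tissue_lfc, x$n_prognostic))
  invisible(x)
}

# Deterministic gene annotation: genes spaced 100 kb apart along 22
# chromosomes so regulatory windows (<= 17 kb) never overlap between genes.
build_annotation <- function(n_genes) {
  per_chr <- ceiling(n_genes / 22)
  chrom <- paste0("chr", rep(seq_len(22), each = per_chr))[seq_len(n_genes)]
  slot <- (seq_len(n_genes) - 1) %% per_chr
  data.frame(gene_id = sprintf("G%05d", seq_len(n_genes)),
             chrom = chrom,
             strand = rep(c("+", "-"), length.out = n_genes),
             tss = 50000 + slot * 100000,
             gene_name = sprintf("GENE%05d", seq_len(n_genes)),
             stringsAsFactors = FALSE)
}

build_design <- function(cfg) {
  patients <- sprintf("P%02d", seq_len(cfg$n_patients))
  rows <- list()
  # primaries for matched patients; the first matched patient has two when
  # two_primary is set (always exercised when n_matched >= 1)
  for (i in seq_len(cfg$n_matched)) {
    k <- if (i == 1 && cfg$two_primary) 2 else 1
    for (j in seq_len(k))
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sprintf("%s_pri%d", patients[i], j), patient_id = patients[i],
        category = "primary", tissue = "prostate", stringsAsFactors = FALSE)
  }
  # metastasis sites: shuffled, then dealt so every patient receives >= 1
  sites <- sample(rep(names(cfg$site_counts), cfg$site_counts))
  owner <- c(patients, sample(patients, length(sites) - cfg$n_patients, replace = TRUE))
  for (i in seq_along(sites))
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = sprintf("%s_met%d_%s", owner[i], sum(owner[seq_len(i)] == owner[i]), sites[i]),
      patient_id = owner[i], category = "metastasis", tissue = sites[i],
      stringsAsFactors = FALSE)
  for (t in names(cfg$n_normals)) {
    for (j in seq_len(cfg$n_normals[[t]]))
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sprintf("NORM_%s_%d", t, j), patient_id = sprintf("DONOR_%s_%d", t, j),
        category = "normal", tissue = t, stringsAsFactors = FALSE)
  }
  for (j in seq_len(cfg$n_bph))
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = sprintf("BPH_%d", j), patient_id = sprintf("DONOR_bph_%d", j),
      category = "bph", tissue = "prostate", stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Simulate the autopsy cohort
#'
#' Generates the count matrix, sample design, gene annotation and the ground
#' truth of planted effects under the model described above. Identical
#' configurations (including the seed) give bit-identical output.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_cohort`: `counts`, `samples`, `annotation`,
#'   `truth` (data.frames `met_deg`, `tissue_specific`, `prognostic`),
#'   `lib_sizes`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  anno <- build_annotation(cfg$n_genes)
  samples <- build_design(cfg)
  G <- cfg$n_genes
  S <- nrow(samples)

  b <- stats::rnorm(G, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  alpha <- stats::rlnorm(G, cfg$dispersion_meanlog, cfg$dispersion_sdlog)

  # planted sets
  pool <- seq_len(G)
  draw <- function(n) {
    if (n == 0) return(integer())
    picked <- sample(pool, n)
    if (cfg$disjoint_planted) pool <<- setdiff(pool, picked)
    picked
  }
  up_idx <- draw(cfg$n_met_up)
  down_idx <- draw(cfg$n_met_down)
  tissue_idx <- lapply(cfg$n_tissue_specific, draw)
  prog_idx <- draw(cfg$n_prognostic)

  d <- numeric(G)
  d[up_idx] <- cfg$met_lfc
  d[down_idx] <- -cfg$met_lfc
  tissue_truth <- list()
  t_eff <- list()
  for (t in names(tissue_idx)) {
    idx <- tissue_idx[[t]]
    if (!length(idx)) next
    sgn <- sample(c(1, -1), length(idx), replace = TRUE)
    t_eff[[t]] <- list(idx = idx, eff = sgn * cfg$tissue_lfc)
    tissue_truth[[t]] <- data.frame(gene_id = anno$gene_id[idx], tissue = t,
                                    direction = sgn, stringsAsFactors = FALSE)
  }

  donors <- unique(samples$patient_id)
  u <- stats::setNames(stats::rnorm(length(donors), 0, cfg$sigma_patient), donors)
  L <- stats::runif(S, cfg$lib_size_range[1], cfg$lib_size_range[2])

  log2mu <- matrix(b, G, S) + matrix(u[samples$patient_id], G, S, byrow = TRUE)
  is_met <- samples$category == "metastasis"
  if (any(is_met)) log2mu[, is_met] <- log2mu[, is_met] + d
  for (t in names(t_eff)) {
    cols <- which(samples$tissue == t & samples$category %in% c("metastasis", "normal"))
    if (length(cols))
      log2mu[t_eff[[t]]$idx, cols] <- log2mu[t_eff[[t]]$idx, cols] + t_eff[[t]]$eff
  }
  mu <- 2^log2mu * matrix(L, G, S, byrow = TRUE)
  counts <- matrix(stats::rnbinom(G * S, size = rep(1 / alpha, S), mu = as.vector(mu)),
                   G, S, dimnames = list(anno$gene_id, samples$sample_id))
  storage.mode(counts) <- "integer"

  truth <- list(
    met_deg = data.frame(gene_id = anno$gene_id[c(up_idx, down_idx)],
                         direction = rep(c(1, -1), c(length(up_idx), length(down_idx))),
                         log2fc = d[c(up_idx, down_idx)], stringsAsFactors = FALSE),
    tissue_specific = if (length(tissue_truth)) do.call(rbind, c(tissue_truth, list(make.row.names = FALSE)))
      else data.frame(gene_id = character(), tissue = character(), direction = numeric()),
    prognostic = data.frame(gene_id = anno$gene_id[prog_idx],
                            loghr = rep(cfg$prognostic_loghr, length(prog_idx)),
                            stringsAsFactors = FALSE))
  structure(list(counts = counts, samples = samples, annotation = anno,
                 truth = truth, lib_sizes = stats::setNames(L, samples$sample_id),
                 dispersion = stats::setNames(alpha, anno$gene_id),
                 config = cfg),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  tab <- table(x$samples$category)
  cat(sprintf("<sim_cohort> %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  planted: %d metastasis gene(s), %d tissue gene(s), %d prognostic gene(s)\n",
              nrow(x$truth$met_deg), nrow(x$truth$tissue_specific), nrow(x$truth$prognostic)))
  invisible(x)
}

#' Simulate TF peak sets over gene regulatory windows
#'
#' Each TF places one peak inside a gene's regulatory window with probability
#' `p1` for genes in its target set and `p0` otherwise. A TF spec may anchor
#' its target peaks to another TF's peaks (`anchor`), which reproduces
#' peak-level co-occupancy: for target genes where the anchor TF placed a
#' peak, the anchored TF's peak coincides with it.
#'
#' @param annotation Gene annotation.
#' @param tf_specs Named list; each element a list with `targets` (character
#'   gene ids), `p1`, `p0`, and optionally `width` (bp, default 400),
#'   `condition` (default "metacluster") and `anchor` (name of an earlier
#'   spec).
#' @param upstream,downstream Window geometry (defaults 15000 / 2000).
#' @param seed Integer seed.
#' @return Named list of `peak_set` objects.
#' @export
simulate_peaks <- function(annotation, tf_specs, upstream = 15000,
                           downstream = 2000, seed = 1L) {
  set.seed(as.integer(seed))
  anno <- validate_annotation(annotation)
  win <- regulatory_windows(anno, upstream, downstream)
  out <- list()
  placed <- list()  # per TF: data.frame gene_id, chrom, start, end
  for (nm in names(tf_specs)) {
    spec <- tf_specs[[nm]]
    p1 <- spec$p1
    p0 <- spec$p0
    if (any(c(p0, p1) < 0) || any(c(p0, p1) > 1))
      md_stop("config", sprintf("TF %s: p0 and p1 must lie in [0, 1]", nm))
    width <- spec$width %||% 400
    is_target <- win$gene_id %in% spec$targets
    present <- stats::rbinom(nrow(win), 1, ifelse(is_target, p1, p0)) == 1
    idx <- which(present)
    if (length(idx)) {
      lo <- win$start[idx]
      hi <- pmax(win$end[idx] - width + 1, lo)
      start <- floor(stats::runif(length(idx), lo, hi + 1))
      iv <- data.frame(gene_id = win$gene_id[idx], chrom = win$chrom[idx],
                       start = start, end = start + width - 1,
                       stringsAsFactors = FALSE)
    } else {
      iv <- data.frame(gene_id = character(), chrom = character(),
                       start = numeric(), end = numeric(), stringsAsFactors = FALSE)
    }
    if (!is.null(spec$anchor)) {
      anc <- placed[[spec$anchor]]
      if (is.null(anc)) md_stop("config", sprintf("TF %s anchors to unknown set %s", nm, spec$anchor))
      # snap target-gene peaks onto the anchor peak of the same gene
      hit <- match(iv$gene_id, anc$gene_id)
      snap <- !is.na(hit) & iv$gene_id %in% spec$targets
      iv$start[snap] <- anc$start[hit[snap]]
      iv$end[snap] <- anc$end[hit[snap]]
    }
    placed[[nm]] <- iv
    out[[nm]] <- peak_set(nm, spec$condition %||% "metacluster",
                          iv[c("chrom", "start", "end")])
  }
  out
}

#' Simulate survival records for labeled samples
#'
#' Event times are exponential with hazard `h0 * exp(beta * I[high] +
#' covariate effects)`; censoring is independent uniform on `(0, tau)` with
#' `tau` solved numerically so the expected censoring fraction matches the
#' target. Clinical covariates (age, PSA, Gleason, pT) are drawn from fixed
#' categorical distributions typical of a prostatectomy series.
#'
#' @param labels Named character vector of "high"/"low" expression labels
#'   (names become sample ids; unnamed vectors get generated ids).
#' @param beta True log hazard ratio of high vs low expression.
#' @param h0 Baseline hazard (> 0), per month.
#' @param covariate_effects Named numeric log-hazard effects for
#'   `age_high`, `psa_intermediate`, `psa_high`, `gs_intermediate`, `gs_high`,
#'   `pt_high` (defaults all 0).
#' @param censoring_fraction Target fraction censored, in `[0, 1)`.
#' @param missing_gleason Fraction of records with missing Gleason score.
#' @param seed Integer seed, or NULL to use the current RNG state.
#' @return Validated survival data.frame (see [read_survival()]).
#' @export
simulate_survival <- function(labels, beta = log(2), h0 = 0.02,
                              covariate_effects = NULL,
                              censoring_fraction = 0.3,
                              missing_gleason = 0,
                              seed = NULL) {
  if (h0 <= 0) md_stop("config", "baseline hazard h0 must be > 0")
  if (censoring_fraction < 0 || censoring_fraction >= 1)
    md_stop("config", "censoring_fraction must lie in [0, 1)")
  if (!all(labels %in% c("high", "low")))
    md_stop("config", "labels must be 'high' or 'low'")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(labels)
  ids <- names(labels) %||% sprintf("S%04d", seq_len(n))
  eff <- c(age_high = 0, psa_intermediate = 0, psa_high = 0,
           gs_intermediate = 0, gs_high = 0, pt_high = 0)
  if (!is.null(covariate_effects)) eff[names(covariate_effects)] <- covariate_effects

  age <- round(stats::rnorm(n, 63, 7))
  psa <- round(stats::rlnorm(n, log(8), 0.8), 1)
  gleason <- sample(6:9, n, replace = TRUE, prob = c(0.25, 0.45, 0.20, 0.10))
  pt_stage <- sample(c("pT2a", "pT2b", "pT3a", "pT3b"), n, replace = TRUE,
                     prob = c(0.15, 0.35, 0.30, 0.20))
  lp <- beta * (labels == "high") +
    eff["age_high"] * (age > 62) +
    eff["psa_intermediate"] * (psa > 10 & psa < 20) +
    eff["psa_high"] * (psa >= 20) +
    eff["gs_intermediate"] * (gleason == 7) +
    eff["gs_high"] * (gleason > 7) +
    eff["pt_high"] * (pt_stage %in% c("pT3a", "pT3b"))
  rate <- h0 * exp(as.numeric(lp))
  t_event <- stats::rexp(n, rate)
  if (censoring_fraction == 0) {
    time <- t_event
    event <- rep(1, n)
  } else {
    cens_frac <- function(tau) mean((1 - exp(-rate * tau)) / (rate * tau)) - censoring_fraction
    tau <- stats::uniroot(cens_frac, interval = c(1e-6, 1e8), tol = 1e-8)$root
    c_time <- stats::runif(n, 0, tau)
    time <- pmin(t_event, c_time)
    event <- as.numeric(t_event <= c_time)
  }
  if (missing_gleason > 0) {
    n_miss <- round(missing_gleason * n)
    if (n_miss > 0) gleason[sample(n, n_miss)] <- NA
  }
  validate_survival(data.frame(sample_id = ids, time = time, event = event,
                               age = age, psa = psa, gleason = gleason,
                               pt_stage = pt_stage, stringsAsFactors = FALSE))
}

#' Simulate a prognostic (prostatectomy-style) expression + survival cohort
#'
#' Draws log-normal expression for the requested genes across `n` patients;
#' each planted prognostic gene contributes its log hazard ratio to a
#' patient's hazard through that patient's high/low (third-quartile) status
#' for the gene. Used by the pipeline's survival stage.
#'
#' @param gene_ids Genes to include in the expression matrix.
#' @param prognostic data.frame with `gene_id`, `loghr` (the planted truth);
#'   genes absent from `gene_ids` are added.
#' @param n Number of patients.
#' @param h0 Baseline hazard per month.
#' @param censoring_fraction Target censoring fraction.
#' @param missing_gleason Fraction of missing Gleason scores.
#' @param seed Integer seed.
#' @return List: `expression` (genes x patients), `records` (survival table).
#' @export
simulate_prognostic_cohort <- function(gene_ids, prognostic, n = 200,
                                       h0 = 0.02, censoring_fraction = 0.3,
                                       missing_gleason = 0.03, seed = 1L) {
  set.seed(as.integer(seed))
  gene_ids <- union(gene_ids, prognostic$gene_id)
  ids <- sprintf("PT%04d", seq_len(n))
  expr <- matrix(2^stats::rnorm(length(gene_ids) * n, 5, 1.5),
                 length(gene_ids), n, dimnames = list(gene_ids, ids))
  lp <- numeric(n)
  for (i in seq_len(nrow(prognostic))) {
    labs <- stratify_by_q3(expr[prognostic$gene_id[i], ])
    lp <- lp + prognostic$loghr[i] * (labs == "high")
  }
  rate <- h0 * exp(lp)
  t_event <- stats::rexp(n, rate)
  if (censoring_fraction == 0) {
    time <- t_event
    event <- rep(1, n)
  } else {
    cens_frac <- function(tau) mean((1 - exp(-rate * tau)) / (rate * tau)) - censoring_fraction
    tau <- stats::uniroot(cens_frac, interval = c(1e-6, 1e8), tol = 1e-8)$root
    c_time <- stats::runif(n, 0, tau)
    time <- pmin(t_event, c_time)
    event <- as.numeric(t_event <= c_time)
  }
  age <- round(stats::rnorm(n, 63, 7))
  psa <- round(stats::rlnorm(n, log(8), 0.8), 1)
  gleason <- sample(6:9, n, replace = TRUE, prob = c(0.25, 0.45, 0.20, 0.10))
  if (missing_gleason > 0) {
    n_miss <- round(missing_gleason * n)
    if (n_miss > 0) gleason[sample(n, n_miss)] <- NA
  }
  pt_stage <- sample(c("pT2a", "pT2b", "pT3a", "pT3b"), n, replace = TRUE,
                     prob = c(0.15, 0.35, 0.30, 0.20))
  records <- validate_survival(data.frame(
    sample_id = ids, time = time, event = event, age = age, psa = psa,
    gleason = gleason, pt_stage = pt_stage, stringsAsFactors = FALSE))
  list(expression = expr, records = records)
}
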