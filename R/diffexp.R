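# Negative-binomial Wald differential expression with median-of-ratios
# normalization. The two-group log-link model mu_{g,s} = sf_s * exp(b0 + b1 *
# I[s in numerator]) separates per group, so each group's log-mean is fit by a
# 1-D Newton iteration on a strictly concave likelihood (unique root); the
# Wald variance of b1 is 1/I_num + 1/I_den with expected Fisher information
# I = sum mu/(1 + alpha*mu).

#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: the median across genes of the ratio of
#' a sample's count to the gene's geometric mean over all samples. Genes with
#' a zero count in any sample are excluded from the geometric-mean reference.
#'
#' @param counts Count matrix (genes x samples).
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  validate_counts(counts)
  m <- counts
  storage.mode(m) <- "double"
  ref_ok <- rowSums(m == 0) == 0
  if (!any(ref_ok))
    md_stop("normalization", "no gene has nonzero counts in every sample; cannot normalize")
  ref <- m[ref_ok, , drop = FALSE]
  geo <- exp(rowMeans(log(ref)))
  sf <- apply(ref / geo, 2, stats::median)
  stats::setNames(sf, colnames(counts))
}

#' Normalized counts
#' @param counts Count matrix.
#' @param sf Size factors from [size_factors()] (computed if omitted).
#' @return Matrix of counts divided by their sample's size factor.
#' @export
normalized_counts <- function(counts, sf = size_factors(counts)) {
  sweep(counts, 2, sf[colnames(counts)], "/")
}

#' Per-gene dispersion by method of moments
#'
#' For each gene, the NB overdispersion `alpha` in `var = mu + alpha mu^2` is
#' estimated from the pooled within-group variance of normalized counts:
#' `alpha = max((s2_pooled - mean) / mean^2, alpha_min)`. Degenerate genes
#' (variance at or below the mean, or too few replicated samples) get the
#' floor value.
#'
#' @param norm_counts Normalized count matrix (genes x samples).
#' @param groups Factor or character vector, one group label per column.
#' @param alpha_min Dispersion floor (default 1e-8).
#' @return Numeric vector of dispersions, one per gene.
#' @export
estimate_dispersion <- function(norm_counts, groups, alpha_min = 1e-8) {
  groups <- as.factor(groups)
  if (length(groups) != ncol(norm_counts))
    md_stop("config", "groups must have one label per sample column")
  tab <- table(groups)
  use <- names(tab)[tab >= 2]
  if (!length(use))
    md_stop("config", "dispersion estimation needs >= 2 samples in some group")
  ss <- 0
  df <- 0
  for (g in use) {
    x <- norm_counts[, groups == g, drop = FALSE]
    mu_g <- rowMeans(x)
    ss <- ss + rowSums((x - mu_g)^2)
    df <- df + ncol(x) - 1
  }
  s2 <- ss / df
  mu <- rowMeans(norm_counts)
  alpha <- (s2 - mu) / mu^2
  alpha[!is.finite(alpha)] <- alpha_min
  pmax(alpha, alpha_min)
}

#' Define a two-group contrast
#'
#' @param numerator,denominator Disjoint character vectors of sample ids; fold
#'   changes are reported numerator over denominator.
#' @param allow_single Permit a side with a single sample (descriptive use
#'   only; dispersion then comes from the replicated side).
#' @return A `contrast` object.
#' @export
contrast <- function(numerator, denominator, allow_single = FALSE) {
  numerator <- as.character(numerator)
  denominator <- as.character(denominator)
  if (!length(numerator) || !length(denominator))
    md_stop("config", "both contrast sides must be nonempty")
  if (length(intersect(numerator, denominator)))
    md_stop("config", "contrast sides must be disjoint")
  min_n <- min(length(numerator), length(denominator))
  if (min_n < 2 && !allow_single)
    md_stop("config", "each contrast side needs >= 2 samples (or allow_single = TRUE)")
  structure(list(numerator = numerator, denominator = denominator),
            class = "contrast")
}

# 1-D Newton MLE of the log group mean with offsets log(sf), fixed dispersion.
# Returns theta (log mean), expected Fisher information at the MLE, and a
# convergence flag. Genes with zero group total get theta = -Inf, info = 0.
fit_group_logmean <- function(Y, sf, alpha, max_iter = 100, tol = 1e-10) {
  G <- nrow(Y)
  tot <- rowSums(Y)
  theta <- rep(-Inf, G)
  info <- numeric(G)
  conv <- rep(TRUE, G)
  act <- which(tot > 0)
  if (length(act)) {
    Ya <- Y[act, , drop = FALSE]
    al <- alpha[act]
    th <- log(rowMeans(sweep(Ya, 2, sf, "/")))
    done <- rep(FALSE, length(act))
    for (it in seq_len(max_iter)) {
      live <- which(!done)
      if (!length(live)) break
      M <- exp(th[live]) %o% sf
      D <- 1 + al[live] * M
      U <- rowSums((Ya[live, , drop = FALSE] - M) / D)
      Iobs <- rowSums(M / D)
      step <- U / Iobs
      step <- pmax(pmin(step, 5), -5)
      th[live] <- th[live] + step
      done[live] <- abs(step) < tol
    }
    M <- exp(th) %o% sf
    info_a <- rowSums(M / (1 + al * M))
    theta[act] <- th
    info[act] <- info_a
    conv[act] <- done
  }
  list(theta = theta, info = info, converged = conv)
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' Fits, per gene, the NB log-link model with size-factor offsets and a group
#' indicator, and tests the group coefficient with a Wald z test. Genes with
#' zero counts throughout the contrast get status `all_zero`; genes whose fit
#' does not converge (including an all-zero side, whose fold change is
#' unbounded) get `failed_fit`. Benjamini-Hochberg adjustment is applied over
#' tested genes only.
#'
#' @param counts Count matrix (genes x samples); must contain all contrast samples.
#' @param ctr A [contrast()].
#' @param sf Size factors for (at least) the contrast samples; computed from
#'   the full matrix if omitted.
#' @param alpha Optional per-gene dispersion vector; estimated by
#'   [estimate_dispersion()] on the contrast samples if omitted.
#' @return A data.frame of class `de_result` with columns `gene_id`,
#'   `base_mean`, `log2fc`, `se`, `p`, `adj_p`, `status`, plus attributes
#'   `numerator`/`denominator`.
#' @export
nb_wald_test <- function(counts, ctr, sf = NULL, alpha = NULL) {
  stopifnot(inherits(ctr, "contrast"))
  samp <- c(ctr$numerator, ctr$denominator)
  missing <- setdiff(samp, colnames(counts))
  if (length(missing))
    md_stop("config", sprintf("contrast samples absent from count matrix: %s",
                              paste(utils::head(missing, 3), collapse = ", ")))
  if (is.null(sf)) sf <- size_factors(counts[, samp, drop = FALSE])
  sf <- sf[samp]
  Y <- counts[, samp, drop = FALSE]
  storage.mode(Y) <- "double"
  grp <- ifelse(samp %in% ctr$numerator, "num", "den")
  nc <- normalized_counts(Y, sf)
  if (is.null(alpha)) alpha <- estimate_dispersion(nc, grp)
  num_fit <- fit_group_logmean(Y[, grp == "num", drop = FALSE], sf[grp == "num"], alpha)
  den_fit <- fit_group_logmean(Y[, grp == "den", drop = FALSE], sf[grp == "den"], alpha)

  all_zero <- rowSums(Y) == 0
  one_side_zero <- !all_zero & (!is.finite(num_fit$theta) | !is.finite(den_fit$theta))
  failed <- one_side_zero | !num_fit$converged | !den_fit$converged
  tested <- !all_zero & !failed

  b1 <- num_fit$theta - den_fit$theta
  se_log <- sqrt(1 / num_fit$info + 1 / den_fit$info)
  z <- b1 / se_log
  p <- 2 * stats::pnorm(-abs(z))

  res <- data.frame(gene_id = rownames(counts),
                    base_mean = rowMeans(nc),
                    log2fc = ifelse(tested, b1 / log(2), NA_real_),
                    se = ifelse(tested, se_log / log(2), NA_real_),
                    p = ifelse(tested, p, NA_real_),
                    adj_p = NA_real_,
                    status = ifelse(all_zero, "all_zero",
                                    ifelse(failed, "failed_fit", "tested")),
                    stringsAsFactors = FALSE, row.names = NULL)
  res$adj_p[tested] <- bh_adjust(res$p[tested])
  attr(res, "numerator") <- ctr$numerator
  attr(res, "denominator") <- ctr$denominator
  class(res) <- c("de_result", "data.frame")
  res
}

#' @export
print.de_result <- function(x, ...) {
  tested <- sum(x$status == "tested")
  cat(sprintf("<de_result> %d genes (%d tested, %d all-zero, %d failed)\n",
              nrow(x), tested, sum(x$status == "all_zero"), sum(x$status == "failed_fit")))
  cat(sprintf("  contrast: %d vs %d samples\n",
              length(attr(x, "numerator")), length(attr(x, "denominator"))))
  print(utils::head(as.data.frame(x)[order(x$adj_p), ], 6))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, order-preserving: `adj_(i) = min_{j >= i} m p_(j) /
#' j`, capped at 1. Input p-values outside `[0, 1]` raise a validation error.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    md_stop("pvalue", "p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes from a test result
#'
#' @param results A `de_result`.
#' @param alpha Adjusted-p cutoff.
#' @param strict Use strict `<` instead of the default inclusive `<=`.
#' @return data.frame of class `deg_call` with `gene_id`, `direction`
#'   (+1 up / -1 down in the numerator), `log2fc`, `adj_p`.
#' @export
call_degs <- function(results, alpha, strict = FALSE) {
  ok <- results$status == "tested" &
    (if (strict) results$adj_p < alpha else results$adj_p <= alpha)
  out <- results[which(ok), c("gene_id", "log2fc", "adj_p"), drop = FALSE]
  if (any(out$log2fc == 0))
    md_stop("impossible_state", "a gene with log2fc = 0 cannot be significant (Wald p = 1)")
  out$direction <- sign(out$log2fc)
  out <- out[c("gene_id", "direction", "log2fc", "adj_p")]
  rownames(out) <- NULL
  class(out) <- c("deg_call", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "rule") <- if (strict) "<" else "<="
  out
}

#' @export
print.deg_call <- function(x, ...) {
  cat(sprintf("<deg_call> %d gene(s) at adj p %s %g: %d up, %d down\n",
              nrow(x), attr(x, "rule"), attr(x, "alpha"),
              sum(x$direction > 0), sum(x$direction < 0)))
  invisible(x)
}
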