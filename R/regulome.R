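# Regulatory windows around the TSS, peak/window overlap counting (via
# IRanges; both sides 1-based inclusive so "overlap" means
# max(starts) <= min(ends) with >= 1 bp shared), AR/FOXA1/HOXB13 annotation
# and GTRD-style TF binding-site enrichment with one-tailed Fisher tests.

#' Strand-aware regulatory windows around gene TSSs
#'
#' For a + strand gene the window spans `[tss - upstream, tss + downstream]`;
#' for a - strand gene `[tss - downstream, tss + upstream]`. Windows are
#' clamped to start at position 1.
#'
#' @param annotation Gene annotation data.frame (see [read_annotation()]).
#' @param upstream,downstream Extent in bp (defaults 15000 / 2000).
#' @return data.frame with gene_id, chrom, start, end (1-based inclusive).
#' @export
regulatory_windows <- function(annotation, upstream = 15000, downstream = 2000) {
  annotation <- validate_annotation(annotation)
  if (upstream < 0 || downstream < 0) md_stop("config", "window offsets must be >= 0")
  plus <- annotation$strand == "+"
  start <- ifelse(plus, annotation$tss - upstream, annotation$tss - downstream)
  end <- ifelse(plus, annotation$tss + downstream, annotation$tss + upstream)
  data.frame(gene_id = annotation$gene_id, chrom = annotation$chrom,
             start = pmax(start, 1), end = end, stringsAsFactors = FALSE)
}

as_granges <- function(df, seqlevels = NULL) {
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  if (!is.null(seqlevels))
    GenomeInfoDb::seqlevels(gr) <- seqlevels
  gr
}

# shared chromosome universe so overlap calls never warn about seqlevels
common_levels <- function(...) sort(unique(unlist(lapply(list(...), `[[`, "chrom"))))

#' Count peak overlaps per regulatory window
#'
#' A peak and a window overlap when they share at least one base on the same
#' chromosome. Counts are invariant to peak ordering.
#'
#' @param windows data.frame from [regulatory_windows()].
#' @param peaks A `peak_set`.
#' @return data.frame with gene_id, n_overlaps, present (n_overlaps >= 1).
#' @export
count_overlaps <- function(windows, peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  if (!nrow(peaks$intervals)) {
    n <- integer(nrow(windows))
  } else {
    lv <- common_levels(windows, peaks$intervals)
    n <- GenomicRanges::countOverlaps(as_granges(windows, lv),
                                      as_granges(peaks$intervals, lv),
                                      minoverlap = 1L)
  }
  data.frame(gene_id = windows$gene_id, n_overlaps = as.integer(n),
             present = n >= 1L, stringsAsFactors = FALSE)
}

#' Annotate DEG windows with AR / FOXA1 / HOXB13 binding
#'
#' Flags, per gene window: presence of at least one tumor-specific AR peak,
#' presence of a normal-specific AR peak, and co-occupancy, defined at the
#' peak level: some tumor AR peak that overlaps the window itself overlaps
#' (>= 1 bp) both a FOXA1 peak and a HOXB13 peak.
#'
#' @param windows Regulatory windows for the genes of interest.
#' @param ar_tumor,ar_normal,foxa1,hoxb13 `peak_set` objects.
#' @return List with per-gene `flags` data.frame (`has_tumor_arbs`,
#'   `has_normal_arbs`, `co_occupied`) and a `summary` count vector.
#' @export
annotate_arbs <- function(windows, ar_tumor, ar_normal, foxa1, hoxb13) {
  for (ps in list(ar_tumor, ar_normal, foxa1, hoxb13))
    if (!inherits(ps, "peak_set")) md_stop("config", "all four peak sets are required")
  has_tumor <- count_overlaps(windows, ar_tumor)$present
  has_normal <- count_overlaps(windows, ar_normal)$present
  co <- rep(FALSE, nrow(windows))
  if (nrow(ar_tumor$intervals)) {
    lv <- common_levels(windows, ar_tumor$intervals,
                        foxa1$intervals, hoxb13$intervals)
    gr_w <- as_granges(windows, lv)
    gr_ar <- as_granges(ar_tumor$intervals, lv)
    # AR peaks that touch both partner TFs anywhere in the genome
    ar_co <- rep(TRUE, length(gr_ar))
    for (partner in list(foxa1, hoxb13)) {
      if (!nrow(partner$intervals)) { ar_co[] <- FALSE; break }
      ar_co <- ar_co &
        GenomicRanges::countOverlaps(gr_ar, as_granges(partner$intervals, lv)) >= 1
    }
    if (any(ar_co)) {
      hits <- GenomicRanges::findOverlaps(gr_w, gr_ar[ar_co])
      co[unique(S4Vectors::queryHits(hits))] <- TRUE
    }
  }
  flags <- data.frame(gene_id = windows$gene_id,
                      has_tumor_arbs = has_tumor,
                      has_normal_arbs = has_normal,
                      co_occupied = co, stringsAsFactors = FALSE)
  list(flags = flags,
       summary = c(n_tumor_arbs = sum(has_tumor),
                   n_normal_arbs = sum(has_normal),
                   n_co_occupied = sum(co)))
}

# One-tailed (greater) Fisher p for the 2x2 table
#   a = DEG windows with a site, b = DEG windows without,
#   c = background with a site, d = background without.
fisher_greater <- function(a, b, c, d) {
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' TF binding-site enrichment in DEG regulatory windows
#'
#' For each TF peak set, tests whether DEG windows contain at least one
#' binding site more often than background gene windows, with a one-tailed
#' Fisher exact test (alternative: greater) and BH adjustment across TFs.
#' By default background genes exclude the DEGs so the 2x2 cells are
#' disjoint; `background = "inclusive"` compares against all genes instead.
#'
#' @param deg_ids Character vector of DEG gene ids.
#' @param windows Regulatory windows for the whole gene universe.
#' @param peak_sets Named list of `peak_set` objects (one per TF).
#' @param alpha Strict adjusted-p cutoff for the `enriched` flag (default 0.15).
#' @param background `"exclusive"` (default) or `"inclusive"`.
#' @return data.frame of class `tf_enrichment`: per TF the table cells
#'   `a`,`b`,`c`,`d`, `odds_ratio`, `p`, `adj_p`, `enriched`.
#' @export
tf_enrichment <- function(deg_ids, windows, peak_sets, alpha = 0.15,
                          background = c("exclusive", "inclusive")) {
  background <- match.arg(background)
  if (!length(deg_ids)) md_stop("config", "empty DEG set")
  if (!length(peak_sets)) md_stop("config", "need >= 1 TF peak set")
  missing <- setdiff(deg_ids, windows$gene_id)
  if (length(missing))
    md_warn("config", sprintf("%d DEG(s) lack annotation and are excluded from enrichment",
                              length(missing)))
  deg_ids <- intersect(deg_ids, windows$gene_id)
  if (!length(deg_ids)) md_stop("config", "no DEG has an annotated window")
  is_deg <- windows$gene_id %in% deg_ids
  tf_names <- vapply(peak_sets, function(ps) ps$tf_name, "")
  rows <- lapply(peak_sets, function(ps) {
    pres <- count_overlaps(windows, ps)$present
    a <- sum(pres & is_deg)
    b <- sum(!pres & is_deg)
    if (background == "exclusive") {
      c_ <- sum(pres & !is_deg)
      d_ <- sum(!pres & !is_deg)
    } else {
      c_ <- sum(pres)
      d_ <- sum(!pres)
    }
    or <- (a * d_) / (b * c_)
    data.frame(tf_name = ps$tf_name, a = a, b = b, c = c_, d = d_,
               odds_ratio = or, p = fisher_greater(a, b, c_, d_),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$adj_p <- bh_adjust(res$p)
  res$enriched <- res$adj_p < alpha
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  attr(res, "background") <- background
  attr(res, "n_deg") <- length(deg_ids)
  attr(res, "n_unannotated_deg") <- length(missing)
  class(res) <- c("tf_enrichment", "data.frame")
  res
}

#' @export
print.tf_enrichment <- function(x, ...) {
  cat(sprintf("<tf_enrichment> %d TF(s), %d DEG windows, %s background; %d enriched at adj p < %g\n",
              nrow(x), attr(x, "n_deg"), attr(x, "background"),
              sum(x$enriched), attr(x, "alpha")))
  print(utils::head(as.data.frame(x), 10), row.names = FALSE)
  invisible(x)
}
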