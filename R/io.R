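# Closed vocabularies for the sample design. The prostate / non-prostate
# distinction is load-bearing for every control filter, so unknown labels are
# rejected unless explicitly permitted.
CATEGORIES <- c("primary", "metastasis", "normal", "bph")
TISSUES    <- c("prostate", "liver", "adrenal", "bone", "subdural", "lymph_node")

# TSV dialect used throughout: tab-separated, UTF-8, '#' comment lines, no quoting.
read_tsv_strict <- function(path, ...) {
  if (!file.exists(path)) md_stop("missing_file", sprintf("file not found: %s", path))
  utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8", ...)
}

write_tsv_strict <- function(df, path, row_names_col = NULL) {
  if (!is.null(row_names_col)) {
    df <- cbind(stats::setNames(data.frame(rownames(df), stringsAsFactors = FALSE),
                                row_names_col),
                as.data.frame(df, check.names = FALSE))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gene-by-sample count matrix from TSV
#'
#' The first column holds gene identifiers, the header row sample identifiers,
#' and the body non-negative integers. Row and column order are preserved.
#'
#' @param path Path to a tab-separated file.
#' @return Integer matrix (genes x samples) with gene ids as rownames and
#'   sample ids as colnames.
#' @export
read_counts <- function(path) {
  df <- read_tsv_strict(path)
  if (ncol(df) < 2) md_stop("parse", sprintf("count file %s has no sample columns", path))
  gene_ids <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  m <- as.matrix(body)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow = nrow(m)))), arr.ind = TRUE)
    loc <- if (nrow(bad)) sprintf(" (gene %s, sample %s)", gene_ids[bad[1, 1]],
                                  colnames(body)[bad[1, 2]]) else ""
    md_stop("non_integer_count", sprintf("non-numeric count in %s%s", path, loc))
  }
  storage.mode(m) <- "double"
  rownames(m) <- gene_ids
  validate_counts(m, where = path)
  storage.mode(m) <- "integer"
  m
}

#' Validate a count matrix
#'
#' Checks the count-matrix invariants: non-negative integral values and unique
#' gene/sample identifiers. Called by [read_counts()] and by every pipeline
#' entry point.
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param where Label used in error messages.
#' @return `m`, invisibly.
#' @export
validate_counts <- function(m, where = "count matrix") {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    md_stop("parse", sprintf("%s must carry gene rownames and sample colnames", where))
  if (anyDuplicated(rownames(m))) {
    dup <- rownames(m)[duplicated(rownames(m))][1]
    md_stop("duplicate_id", sprintf("duplicate gene id in %s: %s", where, dup))
  }
  if (anyDuplicated(colnames(m))) {
    dup <- colnames(m)[duplicated(colnames(m))][1]
    md_stop("duplicate_id", sprintf("duplicate sample id in %s: %s", where, dup))
  }
  if (anyNA(m)) md_stop("non_integer_count", sprintf("missing value in %s", where))
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    md_stop("negative_count", sprintf("negative count in %s (gene %s, sample %s)",
                                      where, rownames(m)[neg[1, 1]], colnames(m)[neg[1, 2]]))
  frac <- which(m != round(m), arr.ind = TRUE)
  if (nrow(frac) > 0)
    md_stop("non_integer_count", sprintf("non-integer count in %s (gene %s, sample %s)",
                                         where, rownames(m)[frac[1, 1]], colnames(m)[frac[1, 2]]))
  invisible(m)
}

#' Write a count matrix to TSV
#' @param m Count matrix as returned by [read_counts()].
#' @param path Output path.
#' @export
write_counts <- function(m, path) {
  write_tsv_strict(m, path, row_names_col = "gene_id")
}

#' Read the sample design table
#'
#' Columns: `sample_id`, `patient_id`, `category` (primary / metastasis /
#' normal / bph) and `tissue`. Category/tissue consistency is enforced:
#' primaries and BPH are prostate tissue, normals and metastases are not.
#'
#' @param path TSV path.
#' @param permissive Accept tissue labels outside the built-in vocabulary
#'   (the category/tissue consistency rules still apply).
#' @return data.frame of sample records, order preserved.
#' @export
read_samples <- function(path, permissive = FALSE) {
  df <- read_tsv_strict(path)
  validate_samples(df, permissive = permissive)
}

#' Validate a sample design table
#' @param df data.frame with sample_id, patient_id, category, tissue.
#' @param permissive Accept tissue labels outside the built-in vocabulary.
#' @return The validated data.frame (character columns), invisibly usable.
#' @export
validate_samples <- function(df, permissive = FALSE) {
  need <- c("sample_id", "patient_id", "category", "tissue")
  miss <- setdiff(need, names(df))
  if (length(miss)) md_stop("parse", sprintf("sample table lacks column(s): %s",
                                             paste(miss, collapse = ", ")))
  df <- df[need]
  df[] <- lapply(df, as.character)
  if (anyDuplicated(df$sample_id))
    md_stop("duplicate_id", sprintf("duplicate sample id: %s",
                                    df$sample_id[duplicated(df$sample_id)][1]))
  bad_cat <- setdiff(unique(df$category), CATEGORIES)
  if (length(bad_cat))
    md_stop("vocabulary", sprintf("unknown category label(s): %s",
                                  paste(bad_cat, collapse = ", ")))
  if (!permissive) {
    bad_tis <- setdiff(unique(df$tissue), TISSUES)
    if (length(bad_tis))
      md_stop("vocabulary", sprintf("unknown tissue label(s): %s (use permissive = TRUE to accept)",
                                    paste(bad_tis, collapse = ", ")))
  }
  pros <- df$tissue == "prostate"
  if (any(df$category %in% c("primary", "bph") & !pros))
    md_stop("vocabulary", "primary/bph samples must be prostate tissue")
  if (any(df$category %in% c("normal", "metastasis") & pros))
    md_stop("vocabulary", "normal and metastasis samples must be non-prostate tissue")
  df
}

#' Write a sample design table
#' @param df Sample table.
#' @param path Output path.
#' @export
write_samples <- function(df, path) write_tsv_strict(df, path)

#' Read a gene annotation table
#'
#' A minimal 4-5 column gene table: `gene_id`, `chrom`, `strand` (+/-),
#' `tss` (1-based transcription start position) and optional `gene_name`.
#'
#' @param path TSV path.
#' @return data.frame of gene annotations, order preserved.
#' @export
read_annotation <- function(path) {
  df <- read_tsv_strict(path)
  validate_annotation(df)
}

#' Validate a gene annotation table
#' @param df data.frame with gene_id, chrom, strand, tss (and optionally gene_name).
#' @return The validated annotation data.frame.
#' @export
validate_annotation <- function(df) {
  need <- c("gene_id", "chrom", "strand", "tss")
  miss <- setdiff(need, names(df))
  if (length(miss)) md_stop("parse", sprintf("annotation lacks column(s): %s",
                                             paste(miss, collapse = ", ")))
  if (!"gene_name" %in% names(df)) df$gene_name <- df$gene_id
  df <- df[c(need, "gene_name")]
  df$gene_id <- as.character(df$gene_id)
  df$chrom <- as.character(df$chrom)
  df$strand <- as.character(df$strand)
  df$gene_name <- as.character(df$gene_name)
  df$tss <- as.numeric(df$tss)
  if (anyDuplicated(df$gene_id))
    md_stop("duplicate_id", sprintf("duplicate gene id in annotation: %s",
                                    df$gene_id[duplicated(df$gene_id)][1]))
  bad <- setdiff(unique(df$strand), c("+", "-"))
  if (length(bad)) md_stop("strand", sprintf("strand must be + or -, got: %s",
                                             paste(bad, collapse = ", ")))
  if (anyNA(df$tss) || any(df$tss < 1) || any(df$tss != round(df$tss)))
    md_stop("coordinate", "tss must be an integer position >= 1")
  df
}

#' Write a gene annotation table
#' @param df Annotation table.
#' @param path Output path.
#' @export
write_annotation <- function(df, path) write_tsv_strict(df, path)

#' Read a BED peak file into a peak set
#'
#' BED is 0-based half-open on disk; intervals are converted to the package's
#' internal 1-based inclusive convention at this boundary. Duplicate identical
#' intervals are collapsed with a message.
#'
#' @param path BED file (3+ columns).
#' @param tf_name Transcription-factor name for the set.
#' @param condition Free-text condition label (e.g. "tumor", "metacluster").
#' @return A `peak_set` object: list with `tf_name`, `condition` and an
#'   `intervals` data.frame (chrom, start, end; 1-based inclusive).
#' @export
read_bed_peaks <- function(path, tf_name, condition = "metacluster") {
  if (!file.exists(path)) md_stop("missing_file", sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines))
    return(peak_set(tf_name, condition,
                    data.frame(chrom = character(), start = numeric(), end = numeric())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, 0L)
  if (any(n < 3)) md_stop("parse", sprintf("malformed BED line %d in %s (need >= 3 fields)",
                                           which(n < 3)[1], path))
  chrom <- vapply(fields, `[[`, "", 1)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad)) md_stop("parse", sprintf("malformed BED line %d in %s (non-numeric coordinate)",
                                            bad[1], path))
  empty <- which(start0 >= end0)
  if (length(empty)) md_stop("coordinate", sprintf("empty or inverted interval at BED line %d in %s",
                                                   empty[1], path))
  iv <- data.frame(chrom = chrom, start = start0 + 1, end = end0,
                   stringsAsFactors = FALSE)
  peak_set(tf_name, condition, iv)
}

#' Construct a peak set
#' @param tf_name TF name.
#' @param condition Condition label.
#' @param intervals data.frame with chrom, start, end in 1-based inclusive coordinates.
#' @param dedup Collapse duplicate identical intervals (with a message).
#' @return A `peak_set` object.
#' @export
peak_set <- function(tf_name, condition, intervals, dedup = TRUE) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  intervals <- intervals[c("chrom", "start", "end")]
  intervals$chrom <- as.character(intervals$chrom)
  intervals$start <- as.numeric(intervals$start)
  intervals$end <- as.numeric(intervals$end)
  if (nrow(intervals) && (any(intervals$start < 1) || any(intervals$end < intervals$start)))
    md_stop("coordinate", sprintf("peak set %s: intervals must satisfy 1 <= start <= end", tf_name))
  if (dedup && nrow(intervals)) {
    n0 <- nrow(intervals)
    intervals <- unique(intervals)
    if (nrow(intervals) < n0)
      message(sprintf("peak set %s/%s: removed %d duplicate interval(s)",
                      tf_name, condition, n0 - nrow(intervals)))
  }
  rownames(intervals) <- NULL
  structure(list(tf_name = tf_name, condition = condition, intervals = intervals),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %s (%s): %d interval(s)\n",
              x$tf_name, x$condition, nrow(x$intervals)))
  invisible(x)
}

#' Write a peak set to BED (0-based half-open)
#' @param ps `peak_set`.
#' @param path Output BED path.
#' @export
write_bed_peaks <- function(ps, path) {
  stopifnot(inherits(ps, "peak_set"))
  iv <- ps$intervals
  out <- sprintf("%s\t%d\t%d", iv$chrom, as.integer(iv$start - 1), as.integer(iv$end))
  writeLines(out, path)
  invisible(path)
}

#' Read a clinical survival table
#'
#' Columns: `sample_id`, `time` (months, > 0), `event` (0 censored / 1
#' biochemical recurrence), `age`, `psa`, `gleason` (may be missing/NA),
#' `pt_stage` (pT2a, pT2b, pT3a, pT3b).
#'
#' @param path TSV path.
#' @return Validated data.frame.
#' @export
read_survival <- function(path) {
  df <- read_tsv_strict(path, na.strings = c("NA", ""))
  validate_survival(df)
}

#' Validate a survival table
#' @param df Survival data.frame.
#' @return The validated data.frame.
#' @export
validate_survival <- function(df) {
  need <- c("sample_id", "time", "event", "age", "psa", "gleason", "pt_stage")
  miss <- setdiff(need, names(df))
  if (length(miss)) md_stop("parse", sprintf("survival table lacks column(s): %s",
                                             paste(miss, collapse = ", ")))
  df <- df[need]
  df$sample_id <- as.character(df$sample_id)
  for (col in c("time", "event", "age", "psa", "gleason")) df[[col]] <- as.numeric(df[[col]])
  df$pt_stage <- as.character(df$pt_stage)
  if (any(is.na(df$time)) || any(df$time <= 0))
    md_stop("survival_record", "follow-up time must be > 0")
  if (!all(df$event %in% c(0, 1)))
    md_stop("survival_record", "event must be 0 (censored) or 1 (recurrence)")
  if (any(!is.na(df$psa) & df$psa < 0))
    md_stop("survival_record", "psa must be >= 0")
  df
}

#' Write a survival table
#' @param df Survival table.
#' @param path Output path.
#' @export
write_survival <- function(df, path) write_tsv_strict(df, path)
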