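# I/O for the pipeline's standard formats: tab-separated gene x sample
# matrices with a sample sheet, FASTA promoters, and ranked candidate tables.
# Dialect: tab-separated, UTF-8, '.' decimal separator, no quoting, missing
# values written as "NA" (missing is distinct from zero: negative-signal
# filtering replaces non-positive intensities by NA).

#' Construct an expression matrix with optional sample design metadata
#'
#' The central container of the package: a numeric gene x sample matrix plus,
#' when the experimental design is known, a sample sheet describing each
#' column (variety, seed class SD/SL, stage S1-S4, replicate). Auxiliary
#' datasets (e.g. an expression atlas used only for co-expression) may carry
#' no design metadata (`samples = NULL`).
#'
#' @param values numeric matrix, rownames = unique gene IDs, colnames =
#'   unique sample IDs.
#' @param samples `NULL`, or a data.frame with columns `sample_id`,
#'   `variety`, `seed_class` (one of `"SD"`, `"SL"`), `stage` (one of
#'   `"S1"`..`"S4"`) and `replicate` (positive integer), covering every
#'   column of `values`.
#' @param log2 logical; `TRUE` if `values` are already on the log2 scale,
#'   `FALSE` (default) for linear-scale intensities.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `samples`, `log2`.
#' @export
expression_matrix <- function(values, samples = NULL, log2 = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || anyNA(gid) || !all(nzchar(gid))) {
    stop("'values' must have non-empty rownames (gene IDs)")
  }
  if (anyDuplicated(gid)) {
    stop("duplicate gene ID(s): ", paste(unique(gid[duplicated(gid)]), collapse = ", "))
  }
  if (is.null(sid) || anyDuplicated(sid)) {
    stop("'values' must have unique colnames (sample IDs)")
  }
  if (!is.null(samples)) {
    samples <- validate_sample_sheet(samples)
    missing <- setdiff(sid, samples$sample_id)
    if (length(missing)) {
      stop("sample(s) missing from sample sheet: ", paste(missing, collapse = ", "))
    }
    samples <- samples[match(sid, samples$sample_id), , drop = FALSE]
    rownames(samples) <- NULL
  }
  structure(list(values = values, samples = samples, log2 = isTRUE(log2)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$log2) "log2" else "linear"))
  if (!is.null(x$samples)) {
    cat(sprintf("  design: %d varieties, stages %s\n",
                length(unique(x$samples$variety)),
                paste(sort(unique(x$samples$stage)), collapse = ",")))
  } else {
    cat("  no sample design metadata\n")
  }
  invisible(x)
}

validate_sample_sheet <- function(samples) {
  req <- c("sample_id", "variety", "seed_class", "stage", "replicate")
  if (!is.data.frame(samples) || !all(req %in% names(samples))) {
    stop("sample sheet must be a data.frame with columns: ",
         paste(req, collapse = ", "))
  }
  samples <- as.data.frame(samples)[req]
  samples$sample_id <- as.character(samples$sample_id)
  samples$variety <- as.character(samples$variety)
  samples$seed_class <- as.character(samples$seed_class)
  samples$stage <- as.character(samples$stage)
  samples$replicate <- as.integer(samples$replicate)
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id(s) in sample sheet: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(samples$seed_class), SEED_CLASSES)
  if (length(bad)) stop("invalid seed_class value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(samples$stage), STAGES)
  if (length(bad)) stop("invalid stage value(s): ", paste(bad, collapse = ", "))
  if (anyNA(samples$replicate) || any(samples$replicate < 1)) {
    stop("replicate must be a positive integer")
  }
  samples
}

#' Read a tab-separated gene x sample expression matrix
#'
#' First column gene IDs, header row sample IDs, `NA` for missing. With a
#' sample sheet every matrix column must be described there; rows/columns are
#' returned in file order and no row is ever silently dropped.
#'
#' @param path path to the matrix file.
#' @param sample_sheet optional path to a tab-separated sample sheet
#'   (columns sample_id, variety, seed_class, stage, replicate).
#' @param log2 logical flag stating the scale of the stored values.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, sample_sheet = NULL, log2 = FALSE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2) stop("matrix file needs a gene-ID column plus >=1 sample column")
  gid <- raw[[1]]
  if (anyDuplicated(gid)) {
    stop("duplicate gene ID(s) in ", path, ": ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "))
  }
  sid <- colnames(raw)[-1]
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sid),
                 dimnames = list(gid, sid))
  for (j in seq_along(sid)) {
    col <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !(is.na(col) | col %in% c("NA", "")))
    if (length(bad)) {
      stop(sprintf("non-numeric cell in %s at row %d (gene %s), column %s: '%s'",
                   path, bad[1], gid[bad[1]], sid[j], col[bad[1]]))
    }
    vals[, j] <- num
  }
  samples <- if (!is.null(sample_sheet)) read_sample_sheet(sample_sheet) else NULL
  expression_matrix(vals, samples = samples, log2 = log2)
}

#' Read a tab-separated sample sheet
#' @param path file path.
#' @return Validated data.frame of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character", quote = "")
  validate_sample_sheet(df)
}

# Full-precision text rendering of numeric columns: %.17g guarantees that
# doubles survive a write -> read round trip bitwise.
full_precision <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

full_precision_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- full_precision(df[[j]])
  }
  df
}

#' Write an expression matrix (and optionally its sample sheet) to disk
#' @param em an [expression_matrix()].
#' @param path output path for the matrix.
#' @param sample_sheet_path optional output path for the sample sheet.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(em, path, sample_sheet_path = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(full_precision_df(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  if (!is.null(sample_sheet_path)) {
    if (is.null(em$samples)) stop("matrix carries no sample metadata to write")
    utils::write.table(em$samples, sample_sheet_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' Read promoter sequences from FASTA
#'
#' Sequences are uppercased and U is converted to T; after normalization
#' only A/C/G/T/N are accepted. Coordinates used downstream are 1-based,
#' inclusive, with position 1 the 5'-most base of the provided sequence
#' (promoters are expected to be given upstream-of-ATG, 5'->3').
#'
#' @param path FASTA file path.
#' @return data.frame with columns `gene_id` and `sequence`, in file order.
#' @export
read_promoters <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate promoter record ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- chartr("U", "T", toupper(as.character(ss)))
  if (any(!nzchar(seqs))) {
    stop("empty promoter sequence for: ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-IUPAC-DNA characters (after normalization) in: ",
         paste(ids[bad], collapse = ", "))
  }
  short <- nchar(seqs) < 10
  if (any(short)) {
    stop("promoter shorter than the minimal motif width (10 bp): ",
         paste(ids[short], collapse = ", "))
  }
  data.frame(gene_id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write promoter sequences to FASTA
#' @param promoters data.frame with columns `gene_id`, `sequence`.
#' @param path output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_promoters <- function(promoters, path) {
  stopifnot(is.data.frame(promoters),
            all(c("gene_id", "sequence") %in% names(promoters)))
  ss <- Biostrings::DNAStringSet(stats::setNames(promoters$sequence,
                                                 promoters$gene_id))
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Write a candidate ranking table
#'
#' Tab-separated, sorted by descending final score (i.e. ascending rank),
#' with per-dataset association values, the three score components, the
#' composite score, the rank and the top-K membership flag.
#'
#' @param ranking a `candidate_ranking` data.frame from [composite_rank()] or
#'   [rank_candidates()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(is.data.frame(ranking))
  if (nrow(ranking) > 0) ranking <- ranking[order(ranking$rank), , drop = FALSE]
  utils::write.table(full_precision_df(as.data.frame(ranking)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a candidate ranking table written by [write_ranking()]
#' @param path file path.
#' @return data.frame with the same columns, numeric columns restored.
#' @export
read_ranking <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  if ("in_top_k" %in% names(df)) df$in_top_k <- as.logical(df$in_top_k)
  df
}
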