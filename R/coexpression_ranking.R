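# Bait-centred multi-dataset co-expression and the composite a*b*c
# prioritization score. For every dataset the association of each gene with
# the bait is either the Pearson correlation of log2 values over that
# dataset's samples, or the highest-reciprocal-rank (HRR) network measure
# HRR(g) = max(rank of g among the bait's correlation-sorted neighbours,
# rank of the bait among g's), lower = stronger. The final score multiplies
# a) concordance across data sources, b) intensity of correlation, and
# c) expression level in the target tissue, and the candidate list is the
# top K of the descending sort.

#' Scoring configuration for the composite candidate ranking
#'
#' @param bait_id gene ID of the bait transcription factor.
#' @param datasets named character vector giving, per dataset, the
#'   co-expression measure: `"pearson"` or `"hrr"`.
#' @param r_min membership threshold for Pearson datasets (default 0.6):
#'   under `sign_mode = "positive"` a gene is co-expressed in the dataset
#'   when `r >= r_min`, under `"negative"` when `r <= -r_min`.
#' @param hrr_max membership threshold for HRR datasets (default 100):
#'   co-expressed when `HRR <= hrr_max`.
#' @param top_k size of the candidate list (default 100).
#' @param sign_mode `"positive"` (default) ranks putative activated
#'   targets; `"negative"` produces the separate repressed-target ranking
#'   (the bait may act as both activator and repressor, but a signed product
#'   across datasets is ill-defined, so the two signs are ranked apart).
#' @param require_down_in_sl demote genes that lack the seedless
#'   down-regulation flag below all flagged genes before ranking
#'   (default `FALSE`).
#' @return list of class `scoring_config`.
#' @export
scoring_config <- function(bait_id, datasets, r_min = 0.6, hrr_max = 100,
                           top_k = 100, sign_mode = c("positive", "negative"),
                           require_down_in_sl = FALSE) {
  sign_mode <- match.arg(sign_mode)
  if (is.null(names(datasets)) || any(!nzchar(names(datasets)))) {
    stop("'datasets' must be a named vector")
  }
  if (!all(datasets %in% c("pearson", "hrr"))) {
    stop("dataset measures must be 'pearson' or 'hrr'")
  }
  stopifnot(length(datasets) >= 1, r_min > 0, r_min < 1, hrr_max >= 1, top_k >= 1)
  structure(list(bait_id = bait_id, datasets = datasets, r_min = r_min,
                 hrr_max = as.integer(hrr_max), top_k = as.integer(top_k),
                 sign_mode = sign_mode,
                 require_down_in_sl = isTRUE(require_down_in_sl)),
            class = "scoring_config")
}

#' Pearson correlation of every gene with the bait
#'
#' Computed on log2 values over all samples of the dataset
#' (pairwise-complete over missing values). Genes with zero variance get
#' `NA` (undefined, excluded downstream with a reason).
#'
#' @param em an [expression_matrix()].
#' @param bait_id bait gene ID; must be present with non-zero variance.
#' @return Named numeric vector of correlations (bait itself = 1).
#' @export
bait_pearson <- function(em, bait_id) {
  stopifnot(inherits(em, "expression_matrix"))
  X <- log2_values(em)
  if (!bait_id %in% rownames(X)) stop("bait gene absent from matrix: ", bait_id)
  bait <- X[bait_id, ]
  if (sum(!is.na(bait)) < 3 || stats::sd(bait, na.rm = TRUE) == 0) {
    stop("bait gene is flat (zero variance): ", bait_id)
  }
  r <- suppressWarnings(
    as.numeric(stats::cor(t(X), bait, use = "pairwise.complete.obs")))
  stats::setNames(r, rownames(X))
}

#' Highest reciprocal rank (HRR) of every gene with the bait
#'
#' From the full Pearson correlation matrix (log2 values), each gene's rank
#' in the bait's neighbour list (self excluded, best neighbour = rank 1) and
#' the bait's rank in the gene's neighbour list are combined as
#' `HRR = max(rank_bait(g), rank_g(bait))`. Ties in correlation are broken
#' deterministically by gene-ID lexicographic order. Genes with undefined
#' correlation (zero variance) and the bait itself get `NA`.
#'
#' @inheritParams bait_pearson
#' @return Named numeric vector of HRR values (lower = stronger).
#' @export
bait_hrr <- function(em, bait_id) {
  stopifnot(inherits(em, "expression_matrix"))
  X <- log2_values(em)
  if (nrow(X) < 3) stop("HRR needs at least 3 genes")
  if (!bait_id %in% rownames(X)) stop("bait gene absent from matrix: ", bait_id)
  if (stats::sd(X[bait_id, ], na.rm = TRUE) == 0) {
    stop("bait gene is flat (zero variance): ", bait_id)
  }
  ids <- rownames(X)
  R <- suppressWarnings(stats::cor(t(X), use = "pairwise.complete.obs"))
  diag(R) <- NA_real_

  # rank of each gene in the bait's neighbour list
  r_b <- R[bait_id, ]
  ord <- order(-r_b, ids, na.last = NA)
  rank_in_bait <- rep(NA_real_, length(ids))
  rank_in_bait[ord] <- seq_along(ord)

  # rank of the bait in each gene's neighbour list:
  # 1 + #{j: r(g,j) > r(g,bait)} + #{ties with lexicographically earlier ID}
  r_gb <- R[, bait_id]
  gt <- rowSums(R > r_gb, na.rm = TRUE)
  earlier <- matrix(ids < bait_id, nrow(R), ncol(R), byrow = TRUE)
  ties <- rowSums((R == r_gb) & earlier, na.rm = TRUE)
  rank_of_bait <- 1 + gt + ties
  rank_of_bait[is.na(r_gb)] <- NA_real_

  hrr <- pmax(rank_in_bait, rank_of_bait)
  hrr[bait_id == ids] <- NA_real_
  stats::setNames(hrr, ids)
}

#' Concordance component a: fraction of datasets where a gene passes
#'
#' @param membership logical matrix, genes x datasets (`NA` = not measured,
#'   counted as not passing).
#' @return Numeric vector in `[0, 1]`: passing datasets / total datasets.
#' @export
concordance_a <- function(membership) {
  stopifnot(is.matrix(membership))
  m <- membership
  m[is.na(m)] <- FALSE
  rowSums(m) / ncol(m)
}

#' Intensity component b: product of per-dataset similarities
#'
#' Each dataset where the gene is measured contributes a similarity in
#' `[0, 1]` — `|r|` for Pearson datasets, `1/HRR` for HRR datasets — and b
#' is their product; datasets where the gene is absent contribute nothing
#' (no neutral factor). Genes measured nowhere get `NA`.
#'
#' @param similarity numeric matrix, genes x datasets, `NA` = not measured.
#' @return Numeric vector with attribute `"n_measured"` (contributing
#'   dataset count per gene).
#' @export
intensity_b <- function(similarity) {
  stopifnot(is.matrix(similarity))
  n_measured <- rowSums(!is.na(similarity))
  b <- apply(similarity, 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else prod(x)
  })
  attr(b, "n_measured") <- n_measured
  b
}

#' Expression component c: rank fraction of mean intensity
#'
#' The mean normalized intensity of each gene over all samples of the
#' primary (ovule/seed) matrix, converted to a rank fraction: the
#' highest-expressed gene gets c = 1, ties receive average ranks. Scale
#' free: multiplying all intensities by a constant leaves c unchanged.
#'
#' @param em normalized primary [expression_matrix()] (linear scale).
#' @return Named numeric vector in `(0, 1]`.
#' @export
expression_c <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  means <- rowMeans(em$values, na.rm = TRUE)
  r <- rank(means, ties.method = "average")
  stats::setNames(r / length(r), rownames(em$values))
}

#' Combine score components into the final candidate ranking
#'
#' `score = a * b * c`, sorted descending; ties broken by higher b, then by
#' gene ID. Genes with `a = 0` (co-expressed in no dataset) are excluded
#' from the listed set. With `require_down_in_sl`, genes lacking the
#' seedless down-regulation flag are demoted below all flagged genes before
#' ranks are drawn.
#'
#' @param components data.frame with columns `gene_id`, `a`, `b`, `c` and
#'   optionally `down_in_sl`, plus any per-dataset columns to carry along.
#' @param config a [scoring_config()].
#' @return data.frame of class `candidate_ranking`, sorted by rank, with
#'   `score`, `rank` and `in_top_k` columns appended.
#' @export
composite_rank <- function(components, config) {
  stopifnot(is.data.frame(components), inherits(config, "scoring_config"),
            all(c("gene_id", "a", "b", "c") %in% names(components)))
  keep <- !is.na(components$a) & components$a > 0 &
    !is.na(components$b) & !is.na(components$c)
  out <- components[keep, , drop = FALSE]
  out$score <- out$a * out$b * out$c
  if (config$require_down_in_sl) {
    if (!"down_in_sl" %in% names(out)) {
      stop("require_down_in_sl is set but components carry no down_in_sl flag")
    }
    ord <- order(!out$down_in_sl, -out$score, -out$b, out$gene_id)
  } else {
    ord <- order(-out$score, -out$b, out$gene_id)
  }
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$in_top_k <- out$rank <= config$top_k
  rownames(out) <- NULL
  class(out) <- c("candidate_ranking", class(out))
  out
}

#' Seedless down-regulation flags
#'
#' A gene is flagged when its log2 fold change (SD minus SL mean log2
#' expression) is positive at two or more of stages S2-S4 — the internal
#' analogue of requiring down-regulation in seedless varieties during three
#' stages of seed development.
#'
#' @param em normalized primary [expression_matrix()] with SD/SL metadata.
#' @return Named logical vector.
#' @export
down_in_sl_flags <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.null(em$samples)) stop("matrix carries no sample metadata")
  X <- log2_values(em)
  lfc <- sapply(c("S2", "S3", "S4"), function(s) {
    sd_cols <- which(em$samples$seed_class == "SD" & em$samples$stage == s)
    sl_cols <- which(em$samples$seed_class == "SL" & em$samples$stage == s)
    rowMeans(X[, sd_cols, drop = FALSE], na.rm = TRUE) -
      rowMeans(X[, sl_cols, drop = FALSE], na.rm = TRUE)
  })
  flags <- rowSums(lfc > 0, na.rm = TRUE) >= 2
  stats::setNames(flags, rownames(X))
}

#' Full bait-centred candidate ranking across datasets
#'
#' Runs the chosen co-expression measure per dataset, derives membership
#' flags and the three score components, and returns the composite ranking
#' together with the per-gene evidence and the exclusion log. The bait is
#' never a candidate (excluded by ID).
#'
#' @param datasets named list of [expression_matrix()] objects; names must
#'   match `config$datasets`.
#' @param primary name of the primary (ovule/seed) dataset within
#'   `datasets`, used for the expression component and the seedless
#'   down-regulation flags.
#' @param config a [scoring_config()].
#' @return list of class `candidate_ranking_result`: `ranking` (the
#'   [composite_rank()] table with per-dataset `r_*`/`hrr_*` and
#'   `member_*` columns), `excluded` (data.frame gene_id/reason),
#'   `config`.
#' @export
rank_candidates <- function(datasets, primary, config) {
  stopifnot(inherits(config, "scoring_config"), is.list(datasets))
  dnames <- names(config$datasets)
  if (!all(dnames %in% names(datasets))) {
    stop("datasets missing from input: ",
         paste(setdiff(dnames, names(datasets)), collapse = ", "))
  }
  if (!primary %in% names(datasets)) stop("unknown primary dataset: ", primary)
  genes <- sort(unique(unlist(lapply(datasets[dnames],
                                     function(d) rownames(d$values)))))
  D <- length(dnames)
  assoc <- matrix(NA_real_, length(genes), D, dimnames = list(genes, dnames))
  member <- matrix(NA, length(genes), D, dimnames = list(genes, dnames))
  similarity <- assoc
  for (d in dnames) {
    measure <- config$datasets[[d]]
    if (measure == "pearson") {
      r <- bait_pearson(datasets[[d]], config$bait_id)
      assoc[names(r), d] <- r
      member[names(r), d] <- if (config$sign_mode == "positive") {
        r >= config$r_min
      } else {
        r <= -config$r_min
      }
      similarity[names(r), d] <- abs(r)
    } else {
      h <- bait_hrr(datasets[[d]], config$bait_id)
      assoc[names(h), d] <- h
      member[names(h), d] <- h <= config$hrr_max
      similarity[names(h), d] <- 1 / h
    }
  }
  a <- concordance_a(member)
  b <- intensity_b(similarity)
  cc <- expression_c(datasets[[primary]])
  cvec <- stats::setNames(rep(NA_real_, length(genes)), genes)
  cvec[names(cc)] <- cc

  comp <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (d in dnames) {
    col <- if (config$datasets[[d]] == "pearson") paste0("r_", d) else paste0("hrr_", d)
    comp[[col]] <- assoc[, d]
    comp[[paste0("member_", d)]] <- member[, d]
  }
  comp$a <- a
  comp$b <- b
  comp$c <- cvec
  if (!is.null(datasets[[primary]]$samples)) {
    flags <- down_in_sl_flags(datasets[[primary]])
    comp$down_in_sl <- unname(flags[genes])
  }

  is_bait <- comp$gene_id == config$bait_id
  reasons <- character(0); excl_ids <- character(0)
  if (any(is_bait)) {
    excl_ids <- c(excl_ids, config$bait_id)
    reasons <- c(reasons, "bait gene")
  }
  unmeasured <- !is_bait & is.na(comp$b)
  excl_ids <- c(excl_ids, comp$gene_id[unmeasured])
  reasons <- c(reasons, rep("undefined association in every dataset", sum(unmeasured)))
  no_c <- !is_bait & !unmeasured & is.na(comp$c)
  excl_ids <- c(excl_ids, comp$gene_id[no_c])
  reasons <- c(reasons, rep("absent from primary matrix", sum(no_c)))
  not_coexpr <- !is_bait & !unmeasured & !no_c & comp$a == 0
  excl_ids <- c(excl_ids, comp$gene_id[not_coexpr])
  reasons <- c(reasons, rep("co-expressed in no dataset", sum(not_coexpr)))

  scored <- comp[!is_bait & !unmeasured & !no_c, , drop = FALSE]
  ranking <- composite_rank(scored, config)
  structure(list(ranking = ranking,
                 excluded = data.frame(gene_id = excl_ids, reason = reasons,
                                       stringsAsFactors = FALSE),
                 config = config),
            class = "candidate_ranking_result")
}

#' @export
print.candidate_ranking_result <- function(x, ...) {
  cat(sprintf("candidate ranking: %d genes scored, %d excluded, top_k = %d\n",
              nrow(x$ranking), nrow(x$excluded), x$config$top_k))
  print(utils::head(x$ranking[, intersect(c("gene_id", "a", "b", "c", "score",
                                            "rank"), names(x$ranking))], 10),
        row.names = FALSE)
  invisible(x)
}
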