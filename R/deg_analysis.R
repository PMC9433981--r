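# Normalization and differential expression between seeded and seedless
# groups, as run on percentile-normalized intensity data: negative-signal
# filtering on the linear scale, per-sample 75th-percentile scaling, a
# Welch t-test on log2 values with the (p < 0.05, |FC| > 2) decision rule,
# and Venn set algebra over contrasts.

#' Differential-expression configuration
#'
#' @param p_threshold significance threshold on the (optionally adjusted)
#'   p-value (default 0.05).
#' @param fc_threshold linear fold-change threshold, >= 1 (default 2): a
#'   gene is called only when `|FC| > fc_threshold` i.e.
#'   `|log2fc| >= log2(fc_threshold)`.
#' @param percentile per-sample normalization percentile in (0,1)
#'   (default 0.75).
#' @param percentile_target value the chosen percentile is scaled to
#'   (default 100).
#' @param var_equal use the pooled-variance t-test instead of Welch
#'   (default `FALSE`; the Welch test is the safer default when the original
#'   software's choice is unknown).
#' @param adjust multiple-testing correction applied before thresholding:
#'   `"none"` (default; raw per-gene p-values, matching headline DEG counts
#'   reported without correction) or `"BH"`.
#' @return list of class `deg_config`.
#' @export
deg_config <- function(p_threshold = 0.05, fc_threshold = 2,
                       percentile = 0.75, percentile_target = 100,
                       var_equal = FALSE, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(p_threshold > 0, fc_threshold >= 1,
            percentile > 0, percentile < 1, percentile_target > 0)
  structure(list(p_threshold = p_threshold, fc_threshold = fc_threshold,
                 percentile = percentile, percentile_target = percentile_target,
                 var_equal = var_equal, adjust = adjust),
            class = "deg_config")
}

#' Filter out negative signals
#'
#' Linear-scale intensities that are zero or negative are measurement noise:
#' individual non-positive values become missing, and genes that are
#' non-positive or missing in every sample are removed. Gene order is
#' preserved; the removed IDs are attached as attribute `"removed_genes"`.
#'
#' @param em linear-scale [expression_matrix()].
#' @return Filtered [expression_matrix()].
#' @export
filter_negative_signals <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$log2) stop("negative-signal filtering is defined on the linear scale only")
  v <- em$values
  v[!is.na(v) & v <= 0] <- NA_real_
  keep <- rowSums(!is.na(v)) > 0
  out <- expression_matrix(v[keep, , drop = FALSE], samples = em$samples,
                           log2 = FALSE)
  attr(out, "removed_genes") <- rownames(em$values)[!keep]
  out
}

#' Per-sample percentile normalization
#'
#' Rescales each sample so that its `percentile` quantile (linear
#' interpolation over non-missing values, [stats::quantile()] type 7) equals
#' `percentile_target`. Scale factors are attached as attribute
#' `"scale_factors"`.
#'
#' @param em linear-scale, negative-filtered [expression_matrix()].
#' @param config a [deg_config()].
#' @return Normalized [expression_matrix()] (still linear scale).
#' @export
percentile_normalize <- function(em, config = deg_config()) {
  stopifnot(inherits(em, "expression_matrix"), inherits(config, "deg_config"))
  if (em$log2) stop("percentile normalization expects linear-scale intensities")
  v <- em$values
  q <- apply(v, 2, function(x) {
    if (all(is.na(x))) NA_real_
    else stats::quantile(x, config$percentile, na.rm = TRUE, type = 7, names = FALSE)
  })
  if (anyNA(q)) {
    stop("sample(s) with all values missing: ",
         paste(colnames(v)[is.na(q)], collapse = ", "))
  }
  if (any(q <= 0)) {
    stop("sample(s) with non-positive normalization percentile: ",
         paste(colnames(v)[q <= 0], collapse = ", "))
  }
  factors <- config$percentile_target / q
  out <- expression_matrix(sweep(v, 2, factors, `*`), samples = em$samples,
                           log2 = FALSE)
  attr(out, "scale_factors") <- stats::setNames(factors, colnames(v))
  out
}

# log2 view of an expression matrix; non-positive linear values -> NA.
log2_values <- function(em) {
  if (em$log2) return(em$values)
  v <- em$values
  v[!is.na(v) & v <= 0] <- NA_real_
  log2(v)
}

select_samples <- function(em, group, by, stage = NULL) {
  if (is.null(em$samples)) stop("matrix carries no sample metadata")
  sel <- em$samples[[by]] %in% group
  if (!is.null(stage)) sel <- sel & em$samples$stage == stage
  which(sel)
}

#' Per-gene differential expression between two sample groups
#'
#' A two-sample t-test (Welch by default) on log2 values per gene, with
#' `log2fc = mean_log2_A - mean_log2_B` and a signed linear fold change
#' `sign(log2fc) * 2^|log2fc|`. A gene is `up` when
#' `p <= p_threshold` and `log2fc >= log2(fc_threshold)`, `down`
#' symmetrically, `ns` otherwise. Genes with fewer than two non-missing
#' values in either group are reported with `testable = FALSE` rather than
#' dropped. Genes with zero variance in both groups and equal means get
#' p = 1 (and p = 0 when their means differ).
#'
#' @param em normalized [expression_matrix()] (linear or log2 scale).
#' @param group_a,group_b character vectors of values of the `by` column
#'   defining the two groups (e.g. `"SD"` vs `"SL"`, or two variety names).
#' @param stage optional stage (`"S1"`..`"S4"`) the contrast is restricted
#'   to.
#' @param config a [deg_config()].
#' @param by sample-sheet column the groups refer to: `"seed_class"`
#'   (default) or `"variety"`.
#' @return data.frame of class `deg_table`: `gene_id`, `mean_log2_A`,
#'   `mean_log2_B`, `log2fc`, `fold_change`, `p_value` (plus `p_adjusted`
#'   when BH is enabled), `direction` (`up`/`down`/`ns`, `NA` for
#'   untestable genes), `testable`, `stage`.
#' @export
differential_expression <- function(em, group_a, group_b, stage = NULL,
                                    config = deg_config(),
                                    by = c("seed_class", "variety")) {
  stopifnot(inherits(em, "expression_matrix"), inherits(config, "deg_config"))
  by <- match.arg(by)
  ia <- select_samples(em, group_a, by, stage)
  ib <- select_samples(em, group_b, by, stage)
  if (!length(ia)) stop("empty group A: no sample with ", by, " in {",
                        paste(group_a, collapse = ","), "}",
                        if (!is.null(stage)) paste0(" at stage ", stage))
  if (!length(ib)) stop("empty group B: no sample with ", by, " in {",
                        paste(group_b, collapse = ","), "}",
                        if (!is.null(stage)) paste0(" at stage ", stage))
  X <- log2_values(em)
  A <- X[, ia, drop = FALSE]
  B <- X[, ib, drop = FALSE]
  nA <- rowSums(!is.na(A)); nB <- rowSums(!is.na(B))
  mA <- rowMeans(A, na.rm = TRUE); mB <- rowMeans(B, na.rm = TRUE)
  vA <- rowSums((A - mA)^2, na.rm = TRUE) / pmax(nA - 1, 1)
  vB <- rowSums((B - mB)^2, na.rm = TRUE) / pmax(nB - 1, 1)
  testable <- nA >= 2 & nB >= 2

  if (config$var_equal) {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se2 <- sp2 * (1 / nA + 1 / nB)
    df <- nA + nB - 2
  } else {
    se2 <- vA / nA + vB / nB
    df <- se2^2 / ((vA / nA)^2 / pmax(nA - 1, 1) + (vB / nB)^2 / pmax(nB - 1, 1))
  }
  tstat <- (mA - mB) / sqrt(se2)
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- testable & se2 == 0
  p[degenerate & mA == mB] <- 1
  p[degenerate & mA != mB] <- 0
  p[!testable] <- NA_real_

  p_used <- p
  out <- data.frame(gene_id = rownames(X),
                    mean_log2_A = mA, mean_log2_B = mB,
                    log2fc = mA - mB,
                    p_value = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$fold_change <- ifelse(out$log2fc >= 0, 2^out$log2fc, -(2^(-out$log2fc)))
  if (config$adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(p, method = "BH")
    p_used <- out$p_adjusted
  }
  lfc_min <- log2(config$fc_threshold)
  direction <- rep(NA_character_, nrow(out))
  direction[testable] <- "ns"
  direction[testable & p_used <= config$p_threshold & out$log2fc >= lfc_min] <- "up"
  direction[testable & p_used <= config$p_threshold & out$log2fc <= -lfc_min] <- "down"
  out$direction <- direction
  out$testable <- testable
  out$stage <- if (is.null(stage)) NA_character_ else stage
  attr(out, "contrast") <- list(group_a = group_a, group_b = group_b,
                                by = by, stage = stage, config = config)
  class(out) <- c("deg_table", class(out))
  out
}

#' Gene IDs called in a DEG table
#' @param deg a `deg_table`.
#' @param direction `"up"`, `"down"`, or `"both"` (default).
#' @return character vector of gene IDs.
#' @export
deg_ids <- function(deg, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  keep <- if (direction == "both") deg$direction %in% c("up", "down")
          else deg$direction %in% direction
  deg$gene_id[keep & !is.na(deg$direction)]
}

#' Venn partition of 2-4 named gene sets
#'
#' Every one of the 2^n - 1 exclusive regions is reported (a region named
#' `"A&B"` holds genes in exactly A and B and no other set); region sizes
#' sum to the size of the union.
#'
#' @param sets named list of 2-4 character vectors.
#' @return Named list of character vectors, one per region.
#' @export
venn_partition <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 4) {
    stop("venn_partition needs 2-4 named sets")
  }
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm))) stop("all sets must be named")
  if (anyDuplicated(nm)) {
    stop("duplicate set name(s): ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 0) {
    member <- matrix(logical(0), 0, length(sets), dimnames = list(NULL, nm))
  }
  if (length(universe) == 1) member <- matrix(member, nrow = 1, dimnames = list(NULL, nm))
  out <- list()
  for (k in seq_len(2^length(sets) - 1)) {
    inset <- as.logical(bitwAnd(k, 2^(seq_along(sets) - 1)))
    region <- paste(nm[inset], collapse = "&")
    sel <- rep(TRUE, length(universe))
    for (j in seq_along(sets)) {
      sel <- sel & (member[, j] == inset[j])
    }
    out[[region]] <- universe[sel]
  }
  out
}
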