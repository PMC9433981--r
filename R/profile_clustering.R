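# Short time-series profile clustering in the STEM style: candidate integer
# model profiles anchored at 0, greedy max-min selection of m representative
# profiles, correlation-based assignment of gene trajectories, and
# profile-level significance from the exact permutation distribution of the
# stage order with a Bonferroni cut-off.

#' Profile-clustering configuration
#'
#' @param unit_change_c maximal absolute unit change between consecutive
#'   stages in a model profile (default 1).
#' @param n_model_profiles_m number of model profiles selected for
#'   clustering (default 15).
#' @param alpha significance level before Bonferroni correction
#'   (default 0.05).
#' @param correction multiplicity correction; only `"bonferroni"` is
#'   implemented.
#' @param max_permutations cap on the exact stage-permutation enumeration
#'   (default 40320 = 8!); more stages than that would require a sampling
#'   scheme this package does not implement.
#' @return list of class `stem_config`.
#' @export
stem_config <- function(unit_change_c = 1, n_model_profiles_m = 15,
                        alpha = 0.05, correction = "bonferroni",
                        max_permutations = 40320) {
  correction <- match.arg(correction, "bonferroni")
  stopifnot(unit_change_c >= 0, n_model_profiles_m >= 1, alpha > 0, alpha < 1)
  structure(list(unit_change_c = as.integer(unit_change_c),
                 n_model_profiles_m = as.integer(n_model_profiles_m),
                 alpha = alpha, correction = correction,
                 max_permutations = as.integer(max_permutations)),
            class = "stem_config")
}

#' Per-gene log2 fold-change trajectories across stages, for one variety
#'
#' For each gene, the mean log2 expression per stage (over that variety's
#' replicates) minus the stage-1 mean, so every trajectory starts at 0 —
#' the y-axis of a STEM profile plot. Genes missing a stage mean are
#' returned as all-`NA` rows (unassignable).
#'
#' @param em normalized [expression_matrix()] with design metadata.
#' @param variety variety name.
#' @return numeric matrix, genes x stages, first column all 0 (or `NA`).
#' @export
fold_change_trajectories <- function(em, variety) {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.null(em$samples)) stop("matrix carries no sample metadata")
  if (!variety %in% em$samples$variety) stop("unknown variety: ", variety)
  X <- log2_values(em)
  M <- sapply(STAGES, function(s) {
    cols <- which(em$samples$variety == variety & em$samples$stage == s)
    if (!length(cols)) return(rep(NA_real_, nrow(X)))
    rowMeans(X[, cols, drop = FALSE], na.rm = TRUE)
  })
  M[is.nan(M)] <- NA_real_
  traj <- M - M[, 1]
  traj[!stats::complete.cases(M), ] <- NA_real_
  dimnames(traj) <- list(rownames(X), STAGES)
  traj
}

#' Enumerate all candidate model profiles
#'
#' Integer trajectories of length `n_stages` starting at 0 with successive
#' differences in `[-unit_change, +unit_change]`; there are
#' `(2c + 1)^(T - 1)` of them, returned in deterministic lexicographic
#' order with `profile_id` = row number.
#'
#' @param n_stages number of time points T (>= 2).
#' @param unit_change maximal unit change c (>= 0).
#' @return integer matrix, one profile per row, rownames = profile IDs.
#' @export
enumerate_candidate_profiles <- function(n_stages = 4, unit_change = 1) {
  stopifnot(n_stages >= 2, unit_change >= 0)
  steps <- as.matrix(expand.grid(rep(list(seq(-unit_change, unit_change)),
                                     n_stages - 1),
                                 KEEP.OUT.ATTRS = FALSE))
  cums <- if (ncol(steps) == 1) steps else t(apply(steps, 1, cumsum))
  traj <- cbind(0L, cums)
  ord <- do.call(order, as.data.frame(traj))
  traj <- traj[ord, , drop = FALSE]
  storage.mode(traj) <- "integer"
  dimnames(traj) <- list(seq_len(nrow(traj)),
                         paste0("t", seq_len(n_stages)))
  traj
}

# Distance used in greedy selection: 1 - Pearson correlation, falling back
# to Euclidean distance when either trajectory is flat (zero variance),
# where correlation is undefined.
profile_distance <- function(p, q) {
  if (stats::sd(p) > 0 && stats::sd(q) > 0) 1 - stats::cor(p, q)
  else sqrt(sum((p - q)^2))
}

lex_less <- function(p, q) {
  d <- p - q
  i <- which(d != 0)
  length(i) > 0 && d[i[1]] < 0
}

#' Greedy max-min selection of m model profiles
#'
#' Starts from the flat (all-zero) profile and repeatedly adds the candidate
#' whose minimum distance to the already-selected set is largest, with ties
#' broken by lexicographic trajectory order; fully deterministic.
#'
#' @param candidates candidate matrix from [enumerate_candidate_profiles()].
#' @param m number of profiles to select.
#' @return integer matrix of `m` selected profiles in selection order, with
#'   rownames `1..m` (the model profile IDs; the flat anchor is profile 1).
#' @export
select_model_profiles <- function(candidates, m) {
  stopifnot(is.matrix(candidates))
  if (m > nrow(candidates)) stop("m exceeds the number of candidate profiles")
  flat <- which(rowSums(candidates != 0) == 0)
  stopifnot(length(flat) == 1)
  selected <- flat
  remaining <- setdiff(seq_len(nrow(candidates)), flat)
  D <- matrix(NA_real_, nrow(candidates), nrow(candidates))
  while (length(selected) < m) {
    best <- NA_integer_
    best_d <- -Inf
    for (i in remaining) {
      di <- min(vapply(selected, function(j) {
        if (is.na(D[i, j])) {
          D[i, j] <<- profile_distance(candidates[i, ], candidates[j, ])
        }
        D[i, j]
      }, numeric(1)))
      if (di > best_d ||
          (di == best_d && lex_less(candidates[i, ], candidates[best, ]))) {
        best <- i
        best_d <- di
      }
    }
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  out <- candidates[selected, , drop = FALSE]
  rownames(out) <- seq_len(m)
  attr(out, "candidate_index") <- selected
  out
}

#' Assign gene trajectories to model profiles
#'
#' Each gene goes to the non-flat model profile with the highest Pearson
#' correlation to its trajectory; zero-variance (or incomplete) trajectories
#' stay unassigned; exact ties go to the lowest profile ID.
#'
#' @param trajectories genes x stages matrix from
#'   [fold_change_trajectories()].
#' @param profiles model profile matrix from [select_model_profiles()]
#'   (rownames = profile IDs).
#' @return Named integer vector of profile IDs (`NA` = unassigned).
#' @export
assign_genes <- function(trajectories, profiles) {
  stopifnot(is.matrix(trajectories), is.matrix(profiles),
            ncol(trajectories) == ncol(profiles))
  ids <- as.integer(rownames(profiles))
  nonflat <- which(apply(profiles, 1, stats::sd) > 0)
  if (!length(nonflat)) stop("no non-flat model profile available for assignment")
  nonflat <- nonflat[order(ids[nonflat])]
  assign <- rep(NA_integer_, nrow(trajectories))
  names(assign) <- rownames(trajectories)
  ok <- stats::complete.cases(trajectories) &
    apply(trajectories, 1, stats::sd) > 0
  if (any(ok)) {
    C <- suppressWarnings(stats::cor(t(trajectories[ok, , drop = FALSE]),
                                     t(profiles[nonflat, , drop = FALSE])))
    assign[ok] <- ids[nonflat][max.col(C, ties.method = "first")]
  }
  assign
}

# All permutations of 1..n in lexicographic order.
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

#' Permutation significance of model profiles
#'
#' For each of the T! orderings of the stages, every trajectory is
#' re-ordered, re-anchored at 0 and re-assigned; a profile's expected count
#' is its mean count over all permutations, and its p-value is the binomial
#' tail `P(X >= observed)` with `X ~ Binomial(n_assigned, expected / n)`.
#' Profiles are significant when `p <= alpha / m` (Bonferroni over the `m`
#' model profiles).
#'
#' @param assignment observed assignment from [assign_genes()].
#' @param trajectories the trajectory matrix the assignment came from.
#' @param profiles the model profile matrix.
#' @param config a [stem_config()].
#' @return list of class `profile_clustering`: `table` (per-profile
#'   data.frame with trajectory, observed, expected, p_value, significant),
#'   `assignment`, `n_assigned`, `config`.
#' @export
profile_significance <- function(assignment, trajectories, profiles,
                                 config = stem_config()) {
  stopifnot(inherits(config, "stem_config"))
  Tn <- ncol(trajectories)
  if (factorial(Tn) > config$max_permutations) {
    stop("T! = ", factorial(Tn), " exceeds max_permutations; a permutation-",
         "sampling mode would be needed and is not implemented")
  }
  ids <- as.integer(rownames(profiles))
  n <- sum(!is.na(assignment))
  observed <- vapply(ids, function(p) sum(assignment == p, na.rm = TRUE), integer(1))
  perms <- permutations(Tn)
  counts <- matrix(0, length(ids), nrow(perms))
  for (k in seq_len(nrow(perms))) {
    tp <- trajectories[, perms[k, ], drop = FALSE]
    tp <- tp - tp[, 1]
    ak <- assign_genes(tp, profiles)
    counts[, k] <- vapply(ids, function(p) sum(ak == p, na.rm = TRUE), integer(1))
  }
  expected <- rowMeans(counts)
  pval <- rep(1, length(ids))
  if (n > 0) {
    pr <- pmin(expected / n, 1)
    pval <- stats::pbinom(observed - 1L, n, pr, lower.tail = FALSE)
  }
  m <- length(ids)
  tab <- data.frame(
    profile_id = ids,
    trajectory = apply(profiles, 1, paste, collapse = ","),
    observed = observed, expected = expected, p_value = pval,
    significant = pval <= config$alpha / m,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, assignment = assignment, n_assigned = n,
                 profiles = profiles, config = config),
            class = "profile_clustering")
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat(sprintf("profile_clustering: %d genes assigned over %d model profiles, %d significant\n",
              x$n_assigned, nrow(x$table), sum(x$table$significant)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Intersection of a profile's gene set with a DEG set
#'
#' @param clustering a `profile_clustering`.
#' @param deg_ids character vector of gene IDs.
#' @param profile_id model profile ID.
#' @return list with `count` and `gene_ids`.
#' @export
cluster_deg_overlap <- function(clustering, deg_ids, profile_id) {
  stopifnot(inherits(clustering, "profile_clustering"))
  if (!profile_id %in% clustering$table$profile_id) {
    stop("unknown profile_id: ", profile_id)
  }
  genes <- names(clustering$assignment)[
    !is.na(clustering$assignment) & clustering$assignment == profile_id]
  shared <- intersect(genes, deg_ids)
  list(count = length(shared), gene_ids = shared)
}
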