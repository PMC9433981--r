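# Synthetic expression experiments with planted ground truth.
#
# The generator emulates the statistical structure of a seed-development
# microarray design: 2 seeded (SD) + 2 seedless (SL) varieties x 4 stages
# (S1-S4) x replicates, a bait transcription factor peaking at S3 in SD
# varieties and flat/low in SL, a set of target genes correlated with the
# bait across the primary and auxiliary datasets, extra DEGs induced at S3
# only, i.i.d. noise genes, and promoters with (targets) or without
# (everything else) planted CArG boxes. Intensities are log-normal: Gaussian
# noise on the log2 scale, exported on the linear scale.

#' Parameters of the synthetic experiment generator
#'
#' Defaults define the reference study conditions used throughout the test
#' suite and the acceptance analyses.
#'
#' @param n_genes total number of genes (default 5000).
#' @param n_targets number of planted bait targets (default 50).
#' @param n_deg_extra number of extra genes up-shifted in SD at S3 only
#'   (default 200).
#' @param varieties data.frame with columns `name`, `seed_class`; default two
#'   seeded ("SD1","SD2") and two seedless ("SL1","SL2") varieties.
#' @param replicates biological replicates per variety x stage (default 3).
#' @param bait_profile_sd,bait_profile_sl log2 stage means (S1..S4) of the
#'   bait in seeded / seedless varieties. Defaults `c(6,6,12,9)` (sharp S3
#'   peak, decrease at S4) and `c(5,5,6,5)` (low, nearly flat).
#' @param target_correlation planted bait-target Pearson correlation rho in
#'   (0, 1] (default 0.9).
#' @param target_amplitude log2 amplitude of the correlated target signal
#'   (default 1.5).
#' @param noise_sd replicate noise standard deviation on the log2 scale
#'   (default 0.5).
#' @param baseline_mean,baseline_sd gene-specific log2 baseline distribution
#'   (default 8 and 1.5).
#' @param deg_log2fc planted log2 fold change of the extra DEGs at S3
#'   (default 2).
#' @param n_aux_datasets number of auxiliary (atlas-like) datasets
#'   (default 2).
#' @param aux_n_samples samples per auxiliary dataset (default 30).
#' @param motif_per_target CArG boxes planted per target promoter
#'   (default 1).
#' @param promoter_length promoter length in bp (default 2000).
#' @param seed integer RNG seed; identical seeds give bitwise-identical
#'   output.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 5000,
                       n_targets = 50,
                       n_deg_extra = 200,
                       varieties = data.frame(
                         name = c("SD1", "SD2", "SL1", "SL2"),
                         seed_class = c("SD", "SD", "SL", "SL"),
                         stringsAsFactors = FALSE),
                       replicates = 3,
                       bait_profile_sd = c(6, 6, 12, 9),
                       bait_profile_sl = c(5, 5, 6, 5),
                       target_correlation = 0.9,
                       target_amplitude = 1.5,
                       noise_sd = 0.5,
                       baseline_mean = 8,
                       baseline_sd = 1.5,
                       deg_log2fc = 2,
                       n_aux_datasets = 2,
                       aux_n_samples = 30,
                       motif_per_target = 1,
                       promoter_length = 2000,
                       seed = 1) {
  p <- list(n_genes = as.integer(n_genes), n_targets = as.integer(n_targets),
            n_deg_extra = as.integer(n_deg_extra), varieties = varieties,
            replicates = as.integer(replicates),
            bait_profile_sd = as.numeric(bait_profile_sd),
            bait_profile_sl = as.numeric(bait_profile_sl),
            target_correlation = target_correlation,
            target_amplitude = target_amplitude,
            noise_sd = noise_sd, baseline_mean = baseline_mean,
            baseline_sd = baseline_sd, deg_log2fc = deg_log2fc,
            n_aux_datasets = as.integer(n_aux_datasets),
            aux_n_samples = as.integer(aux_n_samples),
            motif_per_target = as.integer(motif_per_target),
            promoter_length = as.integer(promoter_length),
            seed = as.integer(seed))
  if (p$n_genes < 2) stop("n_genes must be >= 2")
  if (p$n_targets < 0 || p$n_deg_extra < 0) stop("counts must be non-negative")
  if (p$n_targets + p$n_deg_extra > p$n_genes - 1L) {
    stop("infeasible counts: n_targets + n_deg_extra must be <= n_genes - 1")
  }
  if (!is.data.frame(p$varieties) ||
      !all(c("name", "seed_class") %in% names(p$varieties)) ||
      !all(p$varieties$seed_class %in% SEED_CLASSES)) {
    stop("'varieties' must be a data.frame with columns name, seed_class (SD/SL)")
  }
  if (length(p$bait_profile_sd) != 4 || length(p$bait_profile_sl) != 4) {
    stop("bait profiles must give one log2 mean per stage S1..S4")
  }
  if (p$target_correlation <= 0 || p$target_correlation > 1) {
    stop("target_correlation must lie in (0, 1]")
  }
  if (p$noise_sd <= 0 || p$baseline_sd <= 0) stop("all sds must be > 0")
  if (p$replicates < 1) stop("replicates must be >= 1")
  if (p$promoter_length < 12) stop("promoter_length must allow the widest motif (12 bp)")
  class(p) <- "sim_params"
  p
}

primary_sample_sheet <- function(params) {
  v <- params$varieties
  df <- expand.grid(replicate = seq_len(params$replicates),
                    stage = STAGES, variety = v$name,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[order(match(df$variety, v$name), match(df$stage, STAGES), df$replicate), ]
  data.frame(sample_id = paste(df$variety, df$stage, df$replicate, sep = "_"),
             variety = df$variety,
             seed_class = v$seed_class[match(df$variety, v$name)],
             stage = df$stage, replicate = df$replicate,
             stringsAsFactors = FALSE)
}

random_dna <- function(n, len) {
  chars <- sample(c("A", "C", "G", "T"), n * len, replace = TRUE)
  full <- paste(chars, collapse = "")
  substring(full, (seq_len(n) - 1L) * len + 1L, seq_len(n) * len)
}

contains_carg <- function(seqs) {
  grepl("CC[AT]{6,8}GG", seqs, perl = TRUE)
}

# Background sequences guaranteed free of CArG boxes, by rejection sampling.
carg_free_dna <- function(n, len) {
  seqs <- random_dna(n, len)
  repeat {
    bad <- which(contains_carg(seqs))
    if (!length(bad)) return(seqs)
    seqs[bad] <- random_dna(length(bad), len)
  }
}

random_carg_motif <- function() {
  k <- sample(6:8, 1)
  paste0("CC", paste(sample(c("A", "T"), k, replace = TRUE), collapse = ""), "GG")
}

# Plant `n_motifs` CArG boxes into a motif-free background so that the final
# sequence contains exactly the planted hits (resampled otherwise).
plant_motifs <- function(len, n_motifs, max_tries = 100) {
  for (try in seq_len(max_tries)) {
    seq <- carg_free_dna(1, len)
    motifs <- vapply(seq_len(n_motifs), function(i) random_carg_motif(), character(1))
    widths <- nchar(motifs)
    starts <- integer(n_motifs)
    ok <- TRUE
    occupied <- integer(0)
    for (i in seq_len(n_motifs)) {
      cand <- setdiff(seq_len(len - widths[i] + 1L), occupied)
      # keep a 1-bp gap plus the motif footprint clear of other motifs
      cand <- cand[vapply(cand, function(s) {
        !any(seq(s - 12L, s + widths[i] + 11L) %in% occupied)
      }, logical(1))]
      if (!length(cand)) { ok <- FALSE; break }
      s <- if (length(cand) == 1) cand else sample(cand, 1)
      starts[i] <- s
      occupied <- c(occupied, seq(s, s + widths[i] - 1L))
      substr(seq, s, s + widths[i] - 1L) <- motifs[i]
    }
    if (!ok) next
    hits <- carg_hit_table(seq)
    planted <- data.frame(start = starts, width = widths)
    planted <- planted[order(planted$start, planted$width), , drop = FALSE]
    if (nrow(hits) == n_motifs &&
        all(hits$start == planted$start) && all(hits$width == planted$width)) {
      return(list(sequence = seq,
                  positions = data.frame(start = planted$start,
                                         end = planted$start + planted$width - 1L,
                                         width = planted$width,
                                         strand = "+",
                                         stringsAsFactors = FALSE)))
    }
  }
  stop("failed to plant non-interacting motifs; promoter too short for n_motifs?")
}

#' Generate a synthetic seed-development experiment with planted truth
#'
#' Produces a primary expression matrix over the full SD/SL x stage design,
#' auxiliary co-expression datasets sharing the same gene IDs and planted
#' bait-target correlation structure, promoter sequences (CArG boxes planted
#' only in target promoters), and a ground-truth record.
#'
#' Construction, all on the log2 scale before exponentiation:
#' * bait: stage means from `bait_profile_sd` / `bait_profile_sl` plus
#'   replicate noise;
#' * each target, across SD samples and auxiliary samples:
#'   `baseline + amplitude * (rho * z + sqrt(1 - rho^2) * eps)` where `z` is
#'   the standardized bait trajectory of that dataset and `eps` i.i.d.
#'   standard normal, so the expected bait-target Pearson correlation is
#'   `rho`; targets are additionally down-shifted by `deg_log2fc / 2` in SL
#'   samples at stages S2-S4 (seedless down-regulation);
#' * extra DEGs: `+deg_log2fc` in SD samples at S3 only;
#' * everything else: gene baseline plus i.i.d. noise.
#'
#' @param params a [sim_params()] object.
#' @param with_promoters logical; set `FALSE` to skip promoter synthesis for
#'   expression-only studies.
#' @return list with elements `primary` ([expression_matrix()]), `aux` (list
#'   of [expression_matrix()] without design metadata), `promoters`
#'   (data.frame gene_id/sequence, or `NULL`), and `truth` (list: `bait_id`,
#'   `target_ids`, `deg_ids_by_stage`, `motif_positions`, `params`).
#' @export
generate_experiment <- function(params, with_promoters = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_genes
  ids <- sprintf("gene%05d", seq_len(n))
  bait_id <- ids[1]
  target_ids <- ids[1L + seq_len(params$n_targets)]
  deg_ids <- ids[1L + params$n_targets + seq_len(params$n_deg_extra)]
  baseline <- rnorm(n, params$baseline_mean, params$baseline_sd)
  rho <- params$target_correlation
  amp <- params$target_amplitude

  samples <- primary_sample_sheet(params)
  m <- nrow(samples)
  stage_i <- match(samples$stage, STAGES)
  is_sd <- samples$seed_class == "SD"

  L <- matrix(baseline, n, m) + matrix(rnorm(n * m, 0, params$noise_sd), n, m)
  dimnames(L) <- list(ids, samples$sample_id)
  bait_mean <- ifelse(is_sd, params$bait_profile_sd[stage_i],
                      params$bait_profile_sl[stage_i])
  L[1, ] <- bait_mean + rnorm(m, 0, params$noise_sd)

  if (params$n_targets > 0) {
    sd_cols <- which(is_sd)
    z <- as.numeric(scale(L[1, sd_cols]))
    eps <- matrix(rnorm(params$n_targets * length(sd_cols)),
                  params$n_targets, length(sd_cols))
    sig <- rho * matrix(z, params$n_targets, length(sd_cols), byrow = TRUE) +
      sqrt(1 - rho^2) * eps
    L[target_ids, sd_cols] <- baseline[match(target_ids, ids)] + amp * sig
    sl_late <- which(!is_sd & samples$stage %in% c("S2", "S3", "S4"))
    L[target_ids, sl_late] <- L[target_ids, sl_late] - params$deg_log2fc / 2
  }
  if (params$n_deg_extra > 0) {
    sd_s3 <- which(is_sd & samples$stage == "S3")
    L[deg_ids, sd_s3] <- L[deg_ids, sd_s3] + params$deg_log2fc
  }
  primary <- expression_matrix(2^L, samples = samples, log2 = FALSE)

  aux <- vector("list", params$n_aux_datasets)
  for (d in seq_len(params$n_aux_datasets)) {
    ns <- params$aux_n_samples
    A <- matrix(baseline, n, ns) + matrix(rnorm(n * ns, 0, params$noise_sd), n, ns)
    dimnames(A) <- list(ids, sprintf("aux%d_s%02d", d, seq_len(ns)))
    A[1, ] <- params$baseline_mean + 2 * rnorm(ns)
    if (params$n_targets > 0) {
      z <- as.numeric(scale(A[1, ]))
      eps <- matrix(rnorm(params$n_targets * ns), params$n_targets, ns)
      sig <- rho * matrix(z, params$n_targets, ns, byrow = TRUE) +
        sqrt(1 - rho^2) * eps
      A[target_ids, ] <- baseline[match(target_ids, ids)] + amp * sig
    }
    aux[[d]] <- expression_matrix(2^A, samples = NULL, log2 = FALSE)
  }
  names(aux) <- sprintf("aux%d", seq_len(params$n_aux_datasets))

  promoters <- NULL
  motif_positions <- list()
  if (with_promoters) {
    seqs <- carg_free_dna(n, params$promoter_length)
    names(seqs) <- ids
    if (params$motif_per_target > 0 && params$n_targets > 0) {
      for (g in target_ids) {
        planted <- plant_motifs(params$promoter_length, params$motif_per_target)
        seqs[g] <- planted$sequence
        motif_positions[[g]] <- planted$positions
      }
    }
    promoters <- data.frame(gene_id = ids, sequence = unname(seqs),
                            stringsAsFactors = FALSE)
  }

  truth <- list(bait_id = bait_id, target_ids = target_ids,
                deg_ids_by_stage = list(S1 = character(0), S2 = character(0),
                                        S3 = deg_ids, S4 = character(0)),
                motif_positions = motif_positions, params = params)
  list(primary = primary, aux = aux, promoters = promoters, truth = truth)
}

#' Generate a null experiment (no planted structure)
#'
#' All genes are i.i.d. noise around gene-specific baselines; no targets, no
#' DEGs, no planted motifs (all promoters are rejection-sampled CArG-free).
#' The designated bait is an ordinary noise gene. Used for type-I-error and
#' profile-significance calibration.
#'
#' @inheritParams generate_experiment
#' @return Same shape as [generate_experiment()], with empty truth sets.
#' @export
generate_null <- function(params, with_promoters = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  p0 <- params
  p0$n_targets <- 0L
  p0$n_deg_extra <- 0L
  out <- generate_experiment(p0, with_promoters = with_promoters)
  out$truth$params <- params
  out
}
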