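# Pipeline orchestration: simulate-or-load -> normalize/DEG -> profile
# clustering -> co-expression ranking -> motif scan -> run report. Every
# stage persists its outputs under the run directory, and `run_pipeline()`
# is literally the composition of the stage functions over those persisted
# intermediates, so stage-wise reruns and the `all` command coincide.
# All randomness lives in the simulate stage and is driven by the single
# run seed, so identical config + seed give byte-identical outputs.

#' Build a pipeline run configuration
#'
#' @param mode `"synthetic"` (simulate the input data) or `"files"` (load
#'   them from disk).
#' @param out_dir run directory for all outputs.
#' @param seed global run seed; in synthetic mode it overrides
#'   `sim$seed`.
#' @param sim a [sim_params()] (synthetic mode).
#' @param files list of input paths (files mode): `primary`,
#'   `sample_sheet`, optionally `aux` (named vector of matrix paths) and
#'   `promoters` (FASTA).
#' @param deg a [deg_config()].
#' @param stem a [stem_config()].
#' @param scoring named list of [scoring_config()] arguments; `bait_id`
#'   defaults to the synthetic truth's bait and `datasets` to Pearson on
#'   the primary and first auxiliary dataset and HRR on the second.
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"), out_dir, seed = 1,
                       sim = sim_params(), files = NULL,
                       deg = deg_config(), stem = stem_config(),
                       scoring = list()) {
  mode <- match.arg(mode)
  if (mode == "files" && is.null(files)) stop("files mode needs input paths")
  structure(list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
                 sim = sim, files = files, deg = deg, stem = stem,
                 scoring = scoring),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys `mode`, `out_dir`, `seed`, plus optional sections `sim`,
#' `deg`, `stem`, `scoring`, `files` whose entries are passed to
#' [sim_params()], [deg_config()], [stem_config()] and [run_config()].
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @param out_dir,seed optional overrides.
#' @return A [run_config()].
#' @export
load_run_config <- function(path = NULL, out_dir = NULL, seed = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  sim <- do.call(sim_params, raw$sim %||% list())
  deg <- do.call(deg_config, raw$deg %||% list())
  stem <- do.call(stem_config, raw$stem %||% list())
  cfg <- run_config(mode = raw$mode %||% "synthetic",
                    out_dir = out_dir %||% raw$out_dir %||% "baitrank_run",
                    seed = seed %||% raw$seed %||% 1,
                    sim = sim, files = raw$files, deg = deg, stem = stem,
                    scoring = raw$scoring %||% list())
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_paths <- function(out_dir) {
  list(input = file.path(out_dir, "input"),
       primary = file.path(out_dir, "input", "primary_matrix.tsv"),
       samples = file.path(out_dir, "input", "primary_samples.tsv"),
       aux = function(d) file.path(out_dir, "input", sprintf("%s_matrix.tsv", d)),
       promoters = file.path(out_dir, "input", "promoters.fasta"),
       truth = file.path(out_dir, "input", "truth.json"),
       normalized = file.path(out_dir, "normalized_matrix.tsv"),
       norm_samples = file.path(out_dir, "normalized_samples.tsv"),
       scale_factors = file.path(out_dir, "scale_factors.tsv"),
       deg = function(label) file.path(out_dir, sprintf("deg_%s.tsv", label)),
       venn = file.path(out_dir, "venn_S3.json"),
       profiles = function(v) file.path(out_dir, sprintf("profiles_%s.tsv", v)),
       assignments = function(v) file.path(out_dir, sprintf("assignments_%s.tsv", v)),
       ranking = file.path(out_dir, "ranking.tsv"),
       ranking_summary = file.path(out_dir, "ranking_summary.json"),
       motif_hits = file.path(out_dir, "motif_hits.tsv"),
       motif_bed = file.path(out_dir, "motif_hits.bed"),
       motif_summary = file.path(out_dir, "motif_summary.tsv"),
       report = file.path(out_dir, "run_report.json"))
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

stage_simulate <- function(config) {
  p <- run_paths(config$out_dir)
  dir.create(p$input, recursive = TRUE, showWarnings = FALSE)
  sim <- config$sim
  sim$seed <- config$seed
  xp <- generate_experiment(sim)
  write_expression_matrix(xp$primary, p$primary, sample_sheet_path = p$samples)
  for (d in names(xp$aux)) write_expression_matrix(xp$aux[[d]], p$aux(d))
  write_promoters(xp$promoters, p$promoters)
  truth <- xp$truth
  truth$params$varieties <- as.list(truth$params$varieties)
  truth$params <- unclass(truth$params)
  write_json_report(truth, p$truth)
  invisible(xp)
}

read_inputs <- function(config) {
  p <- run_paths(config$out_dir)
  if (config$mode == "synthetic") {
    primary <- read_expression_matrix(p$primary, p$samples)
    aux_names <- sprintf("aux%d", seq_len(config$sim$n_aux_datasets))
    aux <- lapply(aux_names, function(d) read_expression_matrix(p$aux(d)))
    names(aux) <- aux_names
    promoters <- if (file.exists(p$promoters)) read_promoters(p$promoters) else NULL
    truth <- jsonlite::read_json(p$truth, simplifyVector = TRUE)
    list(primary = primary, aux = aux, promoters = promoters, truth = truth)
  } else {
    f <- config$files
    if (is.null(f$primary) || !file.exists(f$primary)) {
      stop("primary matrix file not found: ", f$primary %||% "<unset>")
    }
    if (is.null(f$sample_sheet) || !file.exists(f$sample_sheet)) {
      stop("sample sheet file not found: ", f$sample_sheet %||% "<unset>")
    }
    primary <- read_expression_matrix(f$primary, f$sample_sheet)
    aux <- list()
    for (d in names(f$aux %||% list())) {
      aux[[d]] <- read_expression_matrix(f$aux[[d]])
    }
    promoters <- if (!is.null(f$promoters)) read_promoters(f$promoters) else NULL
    list(primary = primary, aux = aux, promoters = promoters, truth = NULL)
  }
}

normalize_primary <- function(config, inputs) {
  filtered <- filter_negative_signals(inputs$primary)
  percentile_normalize(filtered, config$deg)
}

stage_deg <- function(config) {
  p <- run_paths(config$out_dir)
  inputs <- read_inputs(config)
  norm <- normalize_primary(config, inputs)
  write_expression_matrix(norm, p$normalized, sample_sheet_path = p$norm_samples)
  sf <- attr(norm, "scale_factors")
  utils::write.table(data.frame(sample_id = names(sf), scale_factor = sf),
                     p$scale_factors, sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- list()
  for (s in STAGES) {
    deg <- differential_expression(norm, "SD", "SL", stage = s, config = config$deg)
    utils::write.table(deg, p$deg(sprintf("SDvsSL_%s", s)), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    counts[[sprintf("SDvsSL_%s", s)]] <- list(
      up = length(deg_ids(deg, "up")), down = length(deg_ids(deg, "down")))
  }
  # single-variety contrast at S3 (first SD vs first SL variety)
  sd_v <- unique(norm$samples$variety[norm$samples$seed_class == "SD"])[1]
  sl_v <- unique(norm$samples$variety[norm$samples$seed_class == "SL"])[1]
  deg_v <- differential_expression(norm, sd_v, sl_v, stage = "S3",
                                   config = config$deg, by = "variety")
  label_v <- sprintf("%svs%s_S3", sd_v, sl_v)
  utils::write.table(deg_v, p$deg(label_v), sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  counts[[label_v]] <- list(up = length(deg_ids(deg_v, "up")),
                            down = length(deg_ids(deg_v, "down")))
  deg_s3 <- read_deg_table(p$deg("SDvsSL_S3"))
  venn_up <- venn_partition(list(SDvsSL = deg_ids(deg_s3, "up"),
                                 varpair = deg_ids(deg_v, "up")))
  venn_down <- venn_partition(list(SDvsSL = deg_ids(deg_s3, "down"),
                                   varpair = deg_ids(deg_v, "down")))
  write_json_report(list(
    up = lapply(venn_up, length), down = lapply(venn_down, length),
    common_up = length(venn_up[["SDvsSL&varpair"]]),
    common_down = length(venn_down[["SDvsSL&varpair"]]),
    varpair_contrast = label_v), p$venn)
  invisible(list(counts = counts, varpair = label_v))
}

read_deg_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  class(df) <- c("deg_table", class(df))
  df
}

deg_union_s3 <- function(config) {
  p <- run_paths(config$out_dir)
  tabs <- list.files(dirname(p$normalized), pattern = "^deg_.*_S3\\.tsv$",
                     full.names = TRUE)
  if (!length(tabs)) stop("profiles stage needs the deg stage outputs; run 'deg' first")
  unique(unlist(lapply(tabs, function(f) deg_ids(read_deg_table(f), "both"))))
}

stage_profiles <- function(config) {
  p <- run_paths(config$out_dir)
  if (!file.exists(p$normalized)) {
    stop("profiles stage needs the normalized matrix; run 'deg' first")
  }
  norm <- read_expression_matrix(p$normalized, p$norm_samples)
  ids <- deg_union_s3(config)
  cand <- enumerate_candidate_profiles(length(STAGES), config$stem$unit_change_c)
  profiles <- select_model_profiles(cand, config$stem$n_model_profiles_m)
  out <- list()
  for (v in unique(norm$samples$variety)) {
    traj <- fold_change_trajectories(norm, v)
    traj <- traj[rownames(traj) %in% ids, , drop = FALSE]
    assignment <- assign_genes(traj, profiles)
    clust <- profile_significance(assignment, traj, profiles, config$stem)
    utils::write.table(clust$table, p$profiles(v), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    utils::write.table(
      data.frame(gene_id = names(assignment), profile_id = assignment),
      p$assignments(v), sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    out[[v]] <- clust
  }
  invisible(out)
}

default_scoring <- function(config, inputs) {
  args <- config$scoring
  if (is.null(args$bait_id)) {
    if (is.null(inputs$truth)) stop("scoring needs a bait_id in files mode")
    args$bait_id <- inputs$truth$bait_id
  }
  if (is.null(args$datasets)) {
    dn <- c("primary", names(inputs$aux))
    measures <- rep("pearson", length(dn))
    if (length(dn) >= 3) measures[length(dn)] <- "hrr"
    args$datasets <- stats::setNames(measures, dn)
  } else {
    args$datasets <- unlist(args$datasets)
  }
  do.call(scoring_config, args)
}

stage_rank <- function(config) {
  p <- run_paths(config$out_dir)
  inputs <- read_inputs(config)
  norm <- normalize_primary(config, inputs)
  aux_norm <- lapply(inputs$aux, function(a) {
    percentile_normalize(filter_negative_signals(a), config$deg)
  })
  sc <- default_scoring(config, inputs)
  datasets <- c(list(primary = norm), aux_norm)
  res <- rank_candidates(datasets, "primary", sc)
  write_ranking(res$ranking, p$ranking)
  summary <- list(n_scored = nrow(res$ranking),
                  n_excluded = nrow(res$excluded),
                  excluded_by_reason = as.list(table(res$excluded$reason)),
                  top_k = sc$top_k, r_min = sc$r_min, hrr_max = sc$hrr_max,
                  sign_mode = sc$sign_mode, seed = config$seed)
  if (!is.null(inputs$truth) && length(inputs$truth$target_ids)) {
    top <- res$ranking$gene_id[res$ranking$in_top_k]
    hits <- intersect(top, inputs$truth$target_ids)
    summary$target_recall <- length(hits) / length(inputs$truth$target_ids)
    summary$target_precision <- length(hits) / length(top)
  }
  write_json_report(summary, p$ranking_summary)
  invisible(res)
}

stage_scan <- function(config) {
  p <- run_paths(config$out_dir)
  inputs <- read_inputs(config)
  if (is.null(inputs$promoters)) stop("scan stage needs promoter sequences")
  hits <- scan_carg(inputs$promoters)
  write_motif_hits(hits, p$motif_hits, bed_path = p$motif_bed)
  utils::write.table(motif_summary(inputs$promoters), p$motif_summary,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(hits)
}

#' Run a single pipeline stage
#'
#' Stages: `"simulate"` (synthetic mode only), `"deg"`, `"profiles"`,
#' `"rank"`, `"scan"`. Later stages read the persisted outputs of earlier
#' ones from the run directory.
#'
#' @param stage stage name.
#' @param config a [run_config()].
#' @return Invisibly, the stage's main in-memory result.
#' @export
pipeline_stage <- function(stage, config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  switch(match.arg(stage, c("simulate", "deg", "profiles", "rank", "scan")),
         simulate = {
           if (config$mode != "synthetic") stop("simulate only applies to synthetic mode")
           stage_simulate(config)
         },
         deg = stage_deg(config),
         profiles = stage_profiles(config),
         rank = stage_rank(config),
         scan = stage_scan(config))
}

#' Run the full pipeline
#'
#' Executes simulate (synthetic mode), deg, profiles, rank and scan in
#' order, writes every intermediate table under `config$out_dir`, and
#' writes plus returns a run report (per-stage gene counts, thresholds,
#' seed, wall time, and — in synthetic mode — recall/precision of the
#' planted targets within the top-K list).
#'
#' @param config a [run_config()].
#' @return The run report, invisibly (also written as
#'   `run_report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  p <- run_paths(config$out_dir)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(mode = config$mode, seed = config$seed,
                 thresholds = list(p_threshold = config$deg$p_threshold,
                                   fc_threshold = config$deg$fc_threshold,
                                   percentile = config$deg$percentile,
                                   n_model_profiles = config$stem$n_model_profiles_m,
                                   alpha = config$stem$alpha))
  stages_run <- character(0)
  on.exit({
    report$incomplete <- TRUE
    report$stages_run <- stages_run
    write_json_report(report, p$report)
  })
  if (config$mode == "synthetic") {
    xp <- stage_simulate(config)
    stages_run <- c(stages_run, "simulate")
    report$n_genes <- nrow(xp$primary$values)
    report$n_primary_samples <- ncol(xp$primary$values)
  }
  degres <- stage_deg(config)
  stages_run <- c(stages_run, "deg")
  report$deg_counts <- degres$counts
  clust <- stage_profiles(config)
  stages_run <- c(stages_run, "profiles")
  report$significant_profiles <- lapply(clust, function(cl) {
    cl$table$profile_id[cl$table$significant]
  })
  rankres <- stage_rank(config)
  stages_run <- c(stages_run, "rank")
  report$n_candidates_scored <- nrow(rankres$ranking)
  summary <- jsonlite::read_json(p$ranking_summary, simplifyVector = TRUE)
  report$target_recall <- summary$target_recall
  report$target_precision <- summary$target_precision
  if (config$mode != "synthetic" && is.null(config$files$promoters)) {
    report$motif_hits <- NULL
  } else {
    hits <- stage_scan(config)
    stages_run <- c(stages_run, "scan")
    report$motif_hits <- nrow(hits)
  }
  report$incomplete <- FALSE
  report$stages_run <- stages_run
  report$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  on.exit()
  write_json_report(report, p$report)
  invisible(report)
}
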