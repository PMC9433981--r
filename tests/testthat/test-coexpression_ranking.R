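make_coexp_em <- function(rows) {
  vals <- do.call(rbind, rows)
  dimnames(vals) <- list(names(rows), sprintf("s%d", seq_len(ncol(vals))))
  expression_matrix(vals, log2 = TRUE)
}

test_that("bait correlations reproduce hand-computed values", {
  em <- make_coexp_em(list(bait = c(1, 3, 2, 4),
                           same = c(1, 3, 2, 4),
                           anti = c(4, 2, 3, 1),
                           x    = c(1, 2, 3, 4),
                           flat = c(5, 5, 5, 5)))
  r <- bait_pearson(em, "bait")
  expect_equal(unname(r["same"]), 1)
  expect_equal(unname(r["anti"]), -1)
  # sum of centred cross-products 4 over sqrt(5 * 5) -> 0.8
  expect_equal(unname(r["x"]), 0.8)
  expect_true(is.na(r["flat"]))
  expect_error(bait_pearson(em, "nope"), "absent")
  expect_error(bait_pearson(make_coexp_em(list(bait = c(2, 2, 2, 2),
                                               g = c(1, 2, 3, 4))), "bait"),
               "flat")
})

test_that("HRR matches the definition on small and random matrices", {
  # reciprocal best pair -> HRR = 1
  em <- make_coexp_em(list(bait = c(1, 2, 3, 4, 2),
                           g    = c(1, 2, 3, 4, 3),
                           far  = c(4, 1, 1, 8, 2)))
  h <- bait_hrr(em, "bait")
  expect_equal(unname(h["g"]), 1)
  expect_true(is.na(h["bait"]))

  # random matrices: equality with the brute-force double-ranking oracle
  for (s in 1:5) {
    em2 <- make_plain_em(n_genes = 50, n_samples = 8, seed = 500 + s)
    h2 <- bait_hrr(em2, "g010")
    expect_equal(h2, oracle_hrr(em2, "g010"))
  }

  # symmetry: the pairwise measure is the same from either endpoint
  em3 <- make_plain_em(n_genes = 12, n_samples = 6, seed = 77)
  from_bait <- bait_hrr(em3, "g003")
  for (g in c("g001", "g007", "g012")) {
    expect_equal(unname(from_bait[g]), unname(bait_hrr(em3, g)["g003"]))
  }
})

test_that("score components follow their definitions", {
  mem <- rbind(c(TRUE, TRUE, TRUE), c(FALSE, FALSE, FALSE), c(TRUE, NA, FALSE))
  a <- concordance_a(mem)
  expect_equal(a, c(1, 0, 1 / 3))

  sim <- rbind(c(0.9, 0.8, 0.5), c(0.9, 0, 0.5), c(0.7, NA, NA),
               c(NA, NA, NA))
  b <- intensity_b(sim)
  expect_equal(as.numeric(b), c(0.36, 0, 0.7, NA))
  expect_identical(unname(attr(b, "n_measured")), c(3, 3, 1, 0))

  vals <- matrix(2^c(8, 6, 9, 7), 4, 2, dimnames = list(paste0("g", 1:4),
                                                        c("s1", "s2")))
  cc <- expression_c(expression_matrix(vals))
  expect_equal(unname(cc["g3"]), 1)      # highest mean
  expect_equal(unname(cc["g1"]), 0.75)   # third-lowest of four
  # scale invariance: a global factor changes no rank fraction
  cc2 <- expression_c(expression_matrix(vals * 1000))
  expect_equal(cc2, cc)

  # random-matrix oracles
  set.seed(91)
  memr <- matrix(sample(c(TRUE, FALSE), 200, replace = TRUE), 50, 4)
  expect_equal(concordance_a(memr), rowSums(memr) / 4)
  simr <- matrix(runif(200), 50, 4)
  expect_equal(as.numeric(intensity_b(simr)), apply(simr, 1, prod))
  emr <- make_plain_em(60, 5, seed = 92)
  expect_equal(unname(expression_c(emr)),
               unname(rank(rowMeans(emr$values)) / 60))
})

test_that("composite ranking sorts, excludes and flags as specified", {
  cfg <- scoring_config("bait", c(d = "pearson"), top_k = 2)
  comp <- data.frame(gene_id = c("g1", "g2", "g3"),
                     a = c(0.5, 1, 1), b = c(0.9, 0.25, 0.05), c = c(1, 1, 1),
                     stringsAsFactors = FALSE)
  rk <- composite_rank(comp, cfg)
  expect_identical(rk$gene_id, c("g1", "g2", "g3"))  # 0.45 > 0.25 > 0.05
  expect_identical(rk$rank, 1:3)
  expect_identical(rk$in_top_k, c(TRUE, TRUE, FALSE))

  # a = 0 everywhere -> empty ranked list
  comp0 <- transform(comp, a = 0)
  expect_identical(nrow(composite_rank(comp0, cfg)), 0L)

  # equal scores: ties broken by higher b, then gene ID
  tie <- data.frame(gene_id = c("gB", "gA", "gC"), a = 1,
                    b = c(0.5, 0.5, 0.8), c = c(0.8, 0.8, 0.5),
                    stringsAsFactors = FALSE)
  expect_identical(composite_rank(tie, cfg)$gene_id, c("gC", "gA", "gB"))

  # demotion: unflagged genes rank below every flagged gene
  cfgd <- scoring_config("bait", c(d = "pearson"), top_k = 2,
                         require_down_in_sl = TRUE)
  compd <- data.frame(gene_id = c("g1", "g2", "g3"), a = 1,
                      b = c(0.9, 0.3, 0.2), c = 1,
                      down_in_sl = c(FALSE, TRUE, TRUE),
                      stringsAsFactors = FALSE)
  expect_identical(composite_rank(compd, cfgd)$gene_id, c("g2", "g3", "g1"))

  # monotonicity: raising one component never worsens the rank
  set.seed(15)
  compr <- data.frame(gene_id = sprintf("g%03d", 1:40),
                      a = sample(c(0.5, 1), 40, TRUE),
                      b = runif(40), c = runif(40), stringsAsFactors = FALSE)
  base <- composite_rank(compr, cfg)
  for (i in sample(40, 5)) {
    up <- compr
    up$b[i] <- min(1, up$b[i] * 1.5)
    new <- composite_rank(up, cfg)
    expect_lte(new$rank[new$gene_id == compr$gene_id[i]],
               base$rank[base$gene_id == compr$gene_id[i]])
  }
})

test_that("the full ranking equals a brute-force recomputation end to end", {
  p <- sim_params(n_genes = 400, n_targets = 15, n_deg_extra = 30, seed = 7)
  xp <- generate_experiment(p, with_promoters = FALSE)
  norm <- percentile_normalize(filter_negative_signals(xp$primary))
  aux <- lapply(xp$aux, function(a) percentile_normalize(filter_negative_signals(a)))
  cfg <- scoring_config(xp$truth$bait_id,
                        c(primary = "pearson", aux1 = "pearson", aux2 = "hrr"),
                        top_k = 30)
  res <- rank_candidates(c(list(primary = norm), aux), "primary", cfg)

  # oracle: per-gene loop over plain stats calls and the HRR oracle
  ids <- rownames(norm$values)
  r1 <- sapply(ids, function(g) cor(log2(norm$values[g, ]),
                                    log2(norm$values[cfg$bait_id, ])))
  r2 <- sapply(ids, function(g) cor(log2(aux$aux1$values[g, ]),
                                    log2(aux$aux1$values[cfg$bait_id, ])))
  h3 <- oracle_hrr(aux$aux2, cfg$bait_id)
  member <- cbind(r1 >= 0.6, r2 >= 0.6, h3 <= 100)
  member[is.na(member)] <- FALSE
  a <- rowSums(member) / 3
  b <- abs(r1) * abs(r2) * (1 / h3)
  cc <- rank(rowMeans(norm$values)) / length(ids)
  score <- a * b * cc
  keep <- ids != cfg$bait_id & a > 0 & !is.na(b)
  oracle_order <- ids[keep][order(-score[keep], -b[keep], ids[keep])]
  expect_identical(res$ranking$gene_id, oracle_order)
  expect_equal(res$ranking$score,
               unname(score[oracle_order]), tolerance = 1e-12)
  expect_setequal(res$ranking$gene_id[res$ranking$in_top_k],
                  head(oracle_order, 30))

  # the bait attains r = 1 with itself and is excluded from candidates
  expect_equal(unname(bait_pearson(norm, cfg$bait_id)[cfg$bait_id]), 1)
  expect_false(cfg$bait_id %in% res$ranking$gene_id)
  expect_true("bait gene" %in% res$excluded$reason)

  # every planted target makes the candidate list here
  expect_true(all(xp$truth$target_ids %in%
                    res$ranking$gene_id[res$ranking$in_top_k]))
})

test_that("down-in-seedless flags reflect planted target structure", {
  p <- sim_params(n_genes = 150, n_targets = 20, n_deg_extra = 0, seed = 23)
  xp <- generate_experiment(p, with_promoters = FALSE)
  norm <- percentile_normalize(filter_negative_signals(xp$primary))
  flags <- down_in_sl_flags(norm)
  # targets are down-shifted in SL at S2-S4; replicate noise can flip a
  # stage sign for the odd gene, so require a large majority, not all
  expect_gte(mean(flags[xp$truth$target_ids]), 0.9)
  expect_gt(mean(flags[xp$truth$target_ids]),
            mean(flags[setdiff(names(flags), xp$truth$target_ids)]))
})
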