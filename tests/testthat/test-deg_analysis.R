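test_that("negative-signal filtering removes and masks exactly the right cells", {
  em <- make_plain_em(n_genes = 6, n_samples = 4, seed = 2)
  em$values[1, ] <- -1                 # all-negative gene -> removed
  em$values[2, 1] <- 0                 # single zero -> masked only
  out <- filter_negative_signals(em)
  expect_identical(rownames(out$values), rownames(em$values)[-1])
  expect_identical(attr(out, "removed_genes"), "g001")
  expect_true(is.na(out$values["g002", 1]))
  expect_true(all(out$values[!is.na(out$values)] > 0))

  # all-positive matrix passes through unchanged
  em2 <- make_plain_em(n_genes = 10, n_samples = 3, seed = 3)
  expect_identical(filter_negative_signals(em2)$values, em2$values)

  # random matrix with 10% negatives: removed set equals a brute-force scan
  set.seed(9)
  em3 <- make_plain_em(n_genes = 200, n_samples = 8, seed = 9)
  em3$values[sample(length(em3$values), 160)] <- -runif(160)
  out3 <- filter_negative_signals(em3)
  removed_oracle <- rownames(em3$values)[
    apply(em3$values, 1, function(x) all(is.na(x) | x <= 0))]
  expect_identical(attr(out3, "removed_genes"), removed_oracle)

  expect_error(filter_negative_signals(make_design_em(log2 = TRUE)),
               "linear scale")
})

test_that("percentile normalization hits its target quantile exactly", {
  vals <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(paste0("g", 1:4), "s1"))
  em <- expression_matrix(vals)
  out <- percentile_normalize(em)
  # linear-interpolation 75th percentile of 1..4 is 3.25
  expect_equal(unname(attr(out, "scale_factors")), 100 / 3.25)

  em2 <- make_plain_em(n_genes = 120, n_samples = 9, seed = 4)
  em2$values[sample(length(em2$values), 40)] <- NA
  out2 <- percentile_normalize(em2)
  q <- apply(out2$values, 2, quantile, 0.75, na.rm = TRUE, type = 7)
  expect_equal(unname(q), rep(100, 9), tolerance = 1e-12)

  # a matrix already at the target is unchanged
  out3 <- percentile_normalize(out2)
  expect_equal(out3$values, out2$values, tolerance = 1e-12)

  em_bad <- em2
  em_bad$values[, 3] <- NA
  expect_error(percentile_normalize(em_bad), colnames(em2$values)[3])
})

test_that("the vectorised Welch test matches stats::t.test gene by gene", {
  em <- make_design_em(n_genes = 60, replicates = 3, seed = 21)
  em$values[sample(length(em$values), 80)] <- NA
  deg <- differential_expression(em, "SD", "SL", stage = "S2")
  X <- log2(em$values)
  sel_a <- em$samples$seed_class == "SD" & em$samples$stage == "S2"
  sel_b <- em$samples$seed_class == "SL" & em$samples$stage == "S2"
  for (i in seq_len(nrow(X))) {
    a <- X[i, sel_a]; b <- X[i, sel_b]
    if (sum(!is.na(a)) < 2 || sum(!is.na(b)) < 2) {
      expect_false(deg$testable[i])
      next
    }
    tt <- t.test(a, b)
    expect_equal(deg$p_value[i], tt$p.value, tolerance = 1e-12)
    expect_equal(deg$log2fc[i], unname(diff(-tt$estimate)), tolerance = 1e-12)
  }
  # pooled-variance variant against var.equal = TRUE
  degp <- differential_expression(em, "SD", "SL", stage = "S2",
                                  config = deg_config(var_equal = TRUE))
  i <- which(degp$testable)[1]
  tt <- t.test(X[i, sel_a], X[i, sel_b], var.equal = TRUE)
  expect_equal(degp$p_value[i], tt$p.value, tolerance = 1e-12)
})

test_that("a planted two-log2-unit shift is called up with a tiny p", {
  set.seed(8)
  samples <- data.frame(sample_id = sprintf("s%02d", 1:12),
                        variety = rep(c("vA", "vC"), each = 6),
                        seed_class = rep(c("SD", "SL"), each = 6),
                        stage = "S3", replicate = rep(1:6, 2),
                        stringsAsFactors = FALSE)
  lv <- rbind(c(rnorm(6, 10, 0.25), rnorm(6, 8, 0.25)),
              matrix(rnorm(12 * 9, 8, 0.25), 9, 12, byrow = TRUE))
  vals <- 2^lv
  dimnames(vals) <- list(sprintf("g%02d", 1:10), samples$sample_id)
  em <- expression_matrix(vals, samples)
  deg <- differential_expression(em, "SD", "SL", stage = "S3")
  expect_identical(deg$direction[1], "up")
  expect_lt(deg$p_value[1], 1e-4)
  expect_equal(deg$log2fc[1], 2, tolerance = 0.5)
  # the signed linear fold change mirrors the log2 fold change
  expect_equal(abs(deg$fold_change), 2^abs(deg$log2fc))
})

test_that("identical groups yield no calls and degenerate genes are defined", {
  em <- make_design_em(n_genes = 30, replicates = 2, seed = 5)
  # make SL values a copy of SD values, gene by gene
  sd_cols <- which(em$samples$seed_class == "SD" & em$samples$stage == "S1")
  sl_cols <- which(em$samples$seed_class == "SL" & em$samples$stage == "S1")
  em$values[, sl_cols] <- em$values[, sd_cols]
  deg <- differential_expression(em, "SD", "SL", stage = "S1")
  expect_true(all(deg$direction == "ns"))
  expect_equal(deg$log2fc, rep(0, 30))

  # zero variance in both groups: equal means -> p = 1, unequal -> p = 0
  em$values[1, c(sd_cols, sl_cols)] <- 256
  em$values[2, sd_cols] <- 1024
  em$values[2, sl_cols] <- 64
  deg2 <- differential_expression(em, "SD", "SL", stage = "S1")
  expect_identical(deg2$p_value[1:2], c(1, 0))
  expect_identical(deg2$direction[1:2], c("ns", "up"))
})

test_that("swapping the groups negates log2fc and swaps directions", {
  em <- make_design_em(n_genes = 50, replicates = 3, seed = 13)
  cfg <- deg_config(fc_threshold = 1.2)
  ab <- differential_expression(em, "SD", "SL", stage = "S4", config = cfg)
  ba <- differential_expression(em, "SL", "SD", stage = "S4", config = cfg)
  expect_equal(ba$log2fc, -ab$log2fc)
  expect_equal(ba$p_value, ab$p_value)
  map <- c(up = "down", down = "up", ns = "ns")
  expect_identical(unname(map[ab$direction]), ba$direction)
  # up/down/ns partition every tested gene exactly once
  expect_true(all(table(ab$direction[ab$testable]) >= 0))
  expect_identical(sum(ab$direction %in% c("up", "down", "ns")), sum(ab$testable))
})

test_that("null data is flagged at about the nominal rate under a p-only rule", {
  rates <- sapply(1:3, function(s) {
    xp <- generate_null(sim_params(n_genes = 2000, seed = 300 + s),
                        with_promoters = FALSE)
    norm <- percentile_normalize(filter_negative_signals(xp$primary))
    deg <- differential_expression(norm, "SD", "SL", stage = "S3",
                                   config = deg_config(fc_threshold = 1))
    mean(deg$direction[deg$testable] %in% c("up", "down"))
  })
  expect_gt(mean(rates), 0.035)
  expect_lt(mean(rates), 0.065)
})

test_that("venn partition matches brute-force membership tabulation", {
  v <- venn_partition(list(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4")))
  expect_length(v[["A&B"]], 2)
  expect_setequal(v[["A"]], "g1")
  expect_setequal(v[["B"]], "g4")

  d <- venn_partition(list(A = c("x", "y"), B = c("z")))
  expect_length(d[["A&B"]], 0)

  set.seed(6)
  sets <- lapply(1:3, function(i) sample(sprintf("g%04d", 1:900), 500))
  names(sets) <- c("A", "B", "C")
  v3 <- venn_partition(sets)
  # conservation: region sizes sum to the union size
  expect_identical(sum(lengths(v3)), length(unique(unlist(sets))))
  # oracle: per-gene membership pattern tabulation
  universe <- unique(unlist(sets))
  pattern <- sapply(universe, function(g) {
    paste(names(sets)[sapply(sets, function(s) g %in% s)], collapse = "&")
  })
  for (region in names(v3)) {
    expect_setequal(v3[[region]], universe[pattern == region])
  }
  expect_error(venn_partition(list(A = "x")), "2-4")
  expect_error(venn_partition(stats::setNames(list("x", "y"), c("A", "A"))),
               "duplicate")
})
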