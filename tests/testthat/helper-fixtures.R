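# Shared fixtures and independent oracles. Oracles deliberately use naive
# enumeration / per-gene loops so they share no code path with the package
# implementation they check.

# Small expression matrix with a full SD/SL x stage design.
make_design_em <- function(n_genes = 20, replicates = 2, seed = 42,
                           log2 = FALSE) {
  set.seed(seed)
  samples <- expand.grid(replicate = seq_len(replicates),
                         stage = c("S1", "S2", "S3", "S4"),
                         variety = c("vA", "vB", "vC", "vD"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = paste(samples$variety, samples$stage, samples$replicate, sep = "_"),
    variety = samples$variety,
    seed_class = ifelse(samples$variety %in% c("vA", "vB"), "SD", "SL"),
    stage = samples$stage, replicate = samples$replicate,
    stringsAsFactors = FALSE)
  vals <- matrix(2^rnorm(n_genes * nrow(samples), 8, 1), n_genes,
                 dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                 samples$sample_id))
  if (log2) vals <- log2(vals)
  expression_matrix(vals, samples = samples, log2 = log2)
}

# Plain matrix without design metadata.
make_plain_em <- function(n_genes = 30, n_samples = 10, seed = 1) {
  set.seed(seed)
  vals <- matrix(2^rnorm(n_genes * n_samples, 8, 1.2), n_genes,
                 dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                 sprintf("s%02d", seq_len(n_samples))))
  expression_matrix(vals)
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]), collapse = "")
}

# Exhaustive CArG oracle: every start x width combination tested with an
# anchored regex on the extracted substring, on the requested strand(s),
# minus-strand hits mapped back to plus coordinates.
oracle_carg <- function(seq, both_strands = TRUE) {
  one_strand <- function(s) {
    L <- nchar(s)
    out <- NULL
    for (w in 10:12) {
      if (L < w) next
      starts <- seq_len(L - w + 1L)
      sub <- substring(s, starts, starts + w - 1)
      hit <- grepl(sprintf("^CC[AT]{%d}GG$", w - 4), sub)
      if (any(hit)) out <- rbind(out, data.frame(start = starts[hit], width = w))
    }
    if (is.null(out)) data.frame(start = integer(0), width = integer(0)) else out
  }
  plus <- one_strand(seq)
  if (!both_strands) return(plus[order(plus$start, plus$width), , drop = FALSE])
  rc <- one_strand(oracle_revcomp(seq))
  L <- nchar(seq)
  minus <- data.frame(start = L - (rc$start + rc$width - 1L) + 1L,
                      width = rc$width)
  both <- unique(rbind(plus, minus))
  both[order(both$start, both$width), , drop = FALSE]
}

# Brute-force HRR oracle: full per-gene neighbour orderings via sort with
# the gene-ID tie-break, double ranking taken literally from the definition.
oracle_hrr <- function(em, bait_id) {
  X <- em$values
  if (!em$log2) X <- log2(X)
  ids <- rownames(X)
  R <- suppressWarnings(cor(t(X), use = "pairwise.complete.obs"))
  neighbour_rank <- function(from, to) {
    r <- R[from, setdiff(ids, from)]
    nb <- names(r)
    ord <- nb[order(-r, nb)]
    match(to, ord)
  }
  out <- sapply(ids, function(g) {
    if (g == bait_id) return(NA_real_)
    max(neighbour_rank(bait_id, g), neighbour_rank(g, bait_id))
  })
  setNames(out, ids)
}
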