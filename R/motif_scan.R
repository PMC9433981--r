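# CArG-box scanning. The consensus CC[A/T]{6-8}GG is the canonical MADS-box
# protein binding site. All matches are reported, including overlapping
# matches and every width (10/11/12 bp) anchored at the same position: the
# scan slides a window per width rather than taking a single greedy regex
# pass, which would undercount nested matches.
#
# Strand note: the A/T degeneracy (IUPAC W) is self-complementary and
# revcomp(CC W{k} GG) = CC W{k} GG, so the minus-strand hit set always maps
# exactly onto the plus-strand set. By default the two are collapsed into a
# single '+' hit per site; `collapse = FALSE` emits both strands.

CARG_WIDTHS <- 10:12

revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# All plus-strand CArG hits of one sequence: data.frame(start, width),
# sorted by (start, width). Lookahead regex per width so overlaps are kept.
carg_hit_table <- function(seq) {
  out <- list()
  for (w in CARG_WIDTHS) {
    pat <- sprintf("(?=CC[AT]{%d}GG)", w - 4L)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    starts <- as.integer(m[m > 0])
    if (length(starts)) {
      out[[length(out) + 1L]] <- data.frame(start = starts, width = w)
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), width = integer(0)))
  df <- do.call(rbind, out)
  df[order(df$start, df$width), , drop = FALSE]
}

#' Scan promoters for CArG boxes (CC[A/T]6-8GG)
#'
#' Reports every match of the consensus on a sequence, for all three widths
#' and all anchors, overlapping matches included. `N` bases never match.
#' Minus-strand hits are computed on the reverse complement and mapped back
#' to plus-strand coordinates; because the motif is strand-symmetric they
#' coincide with the plus-strand hits, which the scanner verifies
#' internally, and by default (`collapse = TRUE`) each site is reported once
#' with strand `"+"`.
#'
#' @param promoters data.frame with columns `gene_id`, `sequence` (as from
#'   [read_promoters()]), or a named character vector of sequences.
#' @param both_strands scan the minus strand as well (default `TRUE`).
#' @param collapse collapse the strand-symmetric duplicate hits to a single
#'   `"+"` entry (default `TRUE`).
#' @return data.frame with columns `gene_id`, `start`, `end` (1-based,
#'   inclusive), `width`, `strand`, `matched_sequence`, sorted by gene (input
#'   order), then `(start, width)`.
#' @export
scan_carg <- function(promoters, both_strands = TRUE, collapse = TRUE) {
  if (is.character(promoters)) {
    promoters <- data.frame(gene_id = names(promoters),
                            sequence = unname(promoters),
                            stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(promoters),
            all(c("gene_id", "sequence") %in% names(promoters)))
  res <- vector("list", nrow(promoters))
  for (i in seq_len(nrow(promoters))) {
    seq <- promoters$sequence[i]
    plus <- carg_hit_table(seq)
    hits <- if (nrow(plus)) {
      data.frame(gene_id = promoters$gene_id[i], start = plus$start,
                 end = plus$start + plus$width - 1L, width = plus$width,
                 strand = "+", stringsAsFactors = FALSE)
    } else {
      empty_hits(promoters$gene_id[i])
    }
    if (both_strands) {
      L <- nchar(seq)
      rc <- carg_hit_table(revcomp(seq))
      minus_start <- L - (rc$start + rc$width - 1L) + 1L
      minus <- data.frame(start = minus_start, width = rc$width)
      minus <- minus[order(minus$start, minus$width), , drop = FALSE]
      if (!identical(unname(as.matrix(minus)), unname(as.matrix(plus)))) {
        stop("internal error: minus-strand CArG hits do not mirror the plus strand for ",
             promoters$gene_id[i])
      }
      if (!collapse && nrow(minus)) {
        hits <- rbind(hits,
                      data.frame(gene_id = promoters$gene_id[i],
                                 start = minus$start,
                                 end = minus$start + minus$width - 1L,
                                 width = minus$width, strand = "-",
                                 stringsAsFactors = FALSE))
      }
    }
    if (nrow(hits)) {
      hits <- hits[order(hits$start, hits$width, hits$strand), , drop = FALSE]
      hits$matched_sequence <- substring(seq, hits$start, hits$end)
    } else {
      hits$matched_sequence <- character(0)
    }
    res[[i]] <- hits
  }
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  if (is.null(out)) out <- cbind(empty_hits(character(0)),
                                 matched_sequence = character(0))
  out
}

empty_hits <- function(gene_id) {
  data.frame(gene_id = gene_id[0], start = integer(0), end = integer(0),
             width = integer(0), strand = character(0),
             stringsAsFactors = FALSE)
}

#' Per-gene CArG-box hit counts
#'
#' @param promoters promoter data.frame (see [scan_carg()]).
#' @param ... passed on to [scan_carg()].
#' @return data.frame with one row per promoter (zero-hit genes included):
#'   `gene_id`, `n_hits`, `positions` (semicolon-separated `start-end`
#'   intervals).
#' @export
motif_summary <- function(promoters, ...) {
  if (is.character(promoters)) {
    promoters <- data.frame(gene_id = names(promoters),
                            sequence = unname(promoters),
                            stringsAsFactors = FALSE)
  }
  hits <- scan_carg(promoters, ...)
  n <- vapply(promoters$gene_id,
              function(g) sum(hits$gene_id == g), integer(1))
  pos <- vapply(promoters$gene_id, function(g) {
    h <- hits[hits$gene_id == g, , drop = FALSE]
    paste(sprintf("%d-%d", h$start, h$end), collapse = ";")
  }, character(1))
  data.frame(gene_id = promoters$gene_id, n_hits = unname(n),
             positions = unname(pos), stringsAsFactors = FALSE)
}

#' Write CArG hits as a 1-based table and (optionally) BED
#'
#' Both conventions are emitted to avoid coordinate confusion: the main
#' table is 1-based inclusive; the BED file uses 0-based half-open starts.
#'
#' @param hits hit table from [scan_carg()].
#' @param path output path for the 1-based tab-separated table.
#' @param bed_path optional output path for the BED-like file.
#' @return Invisibly, `path`.
#' @export
write_motif_hits <- function(hits, path, bed_path = NULL) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = hits$gene_id, chromStart = hits$start - 1L,
                      chromEnd = hits$end, name = hits$matched_sequence,
                      score = hits$width, strand = hits$strand,
                      stringsAsFactors = FALSE)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, na = "NA")
  }
  invisible(path)
}
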