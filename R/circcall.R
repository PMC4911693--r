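# Exonic circRNA annotation from chimeric read pairs.
#
# A back-splice joins the genomic end of a downstream exon (the donor side
# of the circle) to the genomic start of an upstream exon (the acceptor
# side).  In genome space this is strand-symmetric, so matching is done on
# genomic exon boundaries; strand enters only when exon ordinals are put in
# transcript orientation (terminal-exon classification, flanking introns).
# The canonical key of a circle is (chrom, acceptor boundary = genomic min,
# donor boundary = genomic max, strand of the hosting gene).

#' Annotate back-splice junction candidates
#'
#' A chimeric read pair supports the circle over exons i..j of a gene iff:
#' the genomically-upstream segment starts exactly (within `tol`) at the
#' annotated start of exon i, the downstream segment ends exactly at the
#' annotated end of exon j (i <= j, both exons of the *same* gene), the
#' segments are in back-spliced (reversed genomic) order in the read, and
#' the linearly aligned mate — when present — lies inside the circle span
#' on the same chromosome. Reads matching more than one junction (possible
#' when `tol > 0` or when annotations overlap) are ambiguous and dropped.
#'
#' @param reads Data frame of chimeric read pairs ([read_chimeric()] layout).
#' @param genes Named list of [gene_model()] objects.
#' @param tol Splice-site matching tolerance in nt (default 0: precise
#'   splice sites only).
#' @return Data frame of supporting assignments, one row per retained read,
#'   with columns `chrom, start, end, strand, gene_id, exon_from, exon_to,
#'   sample_id, read_id` (exon ordinals in genomic order, 1-based within
#'   the gene). Diagnostics attached as attribute `diagnostics`: counts of
#'   reads rejected for no splice-site match, failed mate check, wrong
#'   segment order, and ambiguity.
#' @export
annotate_backsplices <- function(reads, genes, tol = 0) {
  if (!is.numeric(tol) || length(tol) != 1L || is.na(tol) || tol < 0) {
    stop("`tol` must be a single non-negative number")
  }
  diag <- c(n_no_match = 0L, n_mate_rejected = 0L, n_bad_order = 0L,
            n_ambiguous = 0L)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      gene_id = character(0), exon_from = integer(0),
                      exon_to = integer(0), sample_id = character(0),
                      read_id = character(0), stringsAsFactors = FALSE)
  if (nrow(reads) == 0L || length(genes) == 0L) {
    attr(empty, "diagnostics") <- diag
    return(empty)
  }

  # flat exon boundary table
  ex <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
               idx = seq_len(nrow(g$exons)), start = g$exons$start,
               end = g$exons$end, n_exons = nrow(g$exons),
               stringsAsFactors = FALSE)
  }))
  rownames(ex) <- NULL

  by_chrom <- split(ex, ex$chrom)

  n <- nrow(reads)
  m_gene <- m_strand <- character(n)
  m_start <- m_end <- numeric(n)
  m_from <- m_to <- integer(n)
  hit <- logical(n)
  for (r in seq_len(n)) {
    # upstream segment = smaller genomic start; back-splice order requires
    # the downstream piece to come FIRST in the read (seg1).
    if (reads$seg1_start[r] < reads$seg2_start[r]) {
      diag["n_bad_order"] <- diag["n_bad_order"] + 1L
      next
    }
    exc <- by_chrom[[reads$chrom[r]]]
    if (is.null(exc)) {
      diag["n_no_match"] <- diag["n_no_match"] + 1L
      next
    }
    ia <- which(abs(exc$start - reads$seg2_start[r]) <= tol)
    id <- which(abs(exc$end - reads$seg1_end[r]) <= tol)
    if (length(ia) == 0L || length(id) == 0L) {
      diag["n_no_match"] <- diag["n_no_match"] + 1L
      next
    }
    # all same-gene exon pairs (acceptor index <= donor index)
    pairs <- expand.grid(a = ia, d = id)
    ok <- exc$gene_id[pairs$a] == exc$gene_id[pairs$d] &
      exc$idx[pairs$a] <= exc$idx[pairs$d] &
      exc$start[pairs$a] < exc$end[pairs$d]
    pairs <- pairs[ok, , drop = FALSE]
    if (nrow(pairs) == 0L) {
      diag["n_no_match"] <- diag["n_no_match"] + 1L
      next
    }
    # pair-end linearity check
    mate_chrom <- reads$mate_chrom[r]
    has_mate <- !is.na(mate_chrom) && mate_chrom != "." && nzchar(mate_chrom)
    if (has_mate) {
      ok_mate <- mate_chrom == reads$chrom[r] &&
        isTRUE(reads$mate_linear[r] == 1) &&
        !is.na(reads$mate_start[r]) && !is.na(reads$mate_end[r])
      if (ok_mate) {
        inside <- reads$mate_start[r] >= exc$start[pairs$a] &
          reads$mate_end[r] <= exc$end[pairs$d]
        pairs <- pairs[inside, , drop = FALSE]
      } else {
        pairs <- pairs[0L, , drop = FALSE]
      }
      if (nrow(pairs) == 0L) {
        diag["n_mate_rejected"] <- diag["n_mate_rejected"] + 1L
        next
      }
    }
    pairs <- unique(pairs)
    if (nrow(pairs) > 1L) {
      diag["n_ambiguous"] <- diag["n_ambiguous"] + 1L
      next
    }
    hit[r] <- TRUE
    m_gene[r] <- exc$gene_id[pairs$a]
    m_strand[r] <- exc$strand[pairs$a]
    m_start[r] <- exc$start[pairs$a]
    m_end[r] <- exc$end[pairs$d]
    m_from[r] <- exc$idx[pairs$a]
    m_to[r] <- exc$idx[pairs$d]
  }
  res <- data.frame(chrom = reads$chrom[hit], start = m_start[hit],
                    end = m_end[hit], strand = m_strand[hit],
                    gene_id = m_gene[hit], exon_from = m_from[hit],
                    exon_to = m_to[hit], sample_id = reads$sample_id[hit],
                    read_id = reads$read_id[hit], stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "diagnostics") <- diag
  res
}

#' Apply the back-read support filter
#'
#' A circRNA is reported in a sample iff it is supported there by at least
#' `min_reads` distinct back-spliced read pairs.
#'
#' @param candidates Output of [annotate_backsplices()].
#' @param min_reads Minimum distinct supporting read pairs per sample
#'   (default 2).
#' @return Data frame with one row per circRNA per sample: the canonical
#'   key, hosting gene, exon ordinals, `sample_id` and `back_reads`.
#' @export
filter_support <- function(candidates, min_reads = 2) {
  if (!is.numeric(min_reads) || length(min_reads) != 1L ||
      is.na(min_reads) || min_reads < 1) {
    stop("`min_reads` must be a single number >= 1")
  }
  key_cols <- c("chrom", "start", "end", "strand", "gene_id", "exon_from",
                "exon_to", "sample_id")
  if (nrow(candidates) == 0L) {
    out <- candidates[, key_cols, drop = FALSE]
    out$back_reads <- integer(0)
    return(out)
  }
  dedup <- unique(candidates[, c(key_cols, "read_id")])
  agg <- stats::aggregate(list(back_reads = dedup$read_id),
                          by = dedup[key_cols], FUN = length)
  agg <- agg[agg$back_reads >= min_reads, , drop = FALSE]
  agg <- agg[order(agg$chrom, agg$start, agg$end, agg$gene_id,
                   agg$sample_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Classify circRNAs by exon position in the hosting gene
#'
#' In transcript orientation, a circle is `first_exon` when its acceptor
#' exon is the gene's annotated first exon, `last_exon` when its donor exon
#' is the annotated last exon, and `internal` otherwise. For `first_exon`
#' circles, read coverage upstream of the annotated first exon (evidence
#' that the true first exon lies further upstream) is summarized as
#' `upstream_evidence`: mean depth above `depth_threshold` in a `window` nt
#' window upstream of the first exon.
#'
#' @param circs Data frame from [filter_support()].
#' @param genes Named list of [gene_model()] objects.
#' @param upstream_coverage Optional named list, gene id -> numeric vector
#'   of per-base read depth in the window upstream (transcript orientation)
#'   of the gene's annotated first exon.
#' @param window Window size in nt (default 1000).
#' @param depth_threshold Mean-depth threshold (default 1).
#' @return `circs` with columns `exon_position_class` and
#'   `upstream_evidence` added.
#' @export
classify_exon_position <- function(circs, genes, upstream_coverage = NULL,
                                   window = 1000, depth_threshold = 1) {
  n <- nrow(circs)
  cls <- character(n)
  upev <- logical(n)
  for (i in seq_len(n)) {
    g <- genes[[circs$gene_id[i]]]
    if (is.null(g)) {
      stop(sprintf("circRNA %s:%d-%d refers to unknown gene %s",
                   circs$chrom[i], circs$start[i], circs$end[i],
                   circs$gene_id[i]))
    }
    nex <- nrow(g$exons)
    if (circs$exon_from[i] < 1L || circs$exon_to[i] > nex) {
      stop(sprintf("circRNA exons %d-%d not found in gene %s (%d exons)",
                   circs$exon_from[i], circs$exon_to[i], g$gene_id, nex))
    }
    if (g$strand == "+") {
      is_first <- circs$exon_from[i] == 1L
      is_last <- circs$exon_to[i] == nex
    } else {
      is_first <- circs$exon_to[i] == nex
      is_last <- circs$exon_from[i] == 1L
    }
    cls[i] <- if (is_first) "first_exon" else if (is_last) "last_exon" else "internal"
    if (is_first && !is.null(upstream_coverage) &&
        !is.null(upstream_coverage[[g$gene_id]])) {
      cov <- upstream_coverage[[g$gene_id]]
      cov <- utils::tail(cov, window)
      upev[i] <- mean(cov) > depth_threshold
    }
  }
  circs$exon_position_class <- cls
  circs$upstream_evidence <- upev
  circs
}

#' Attach forward-spliced junction read counts
#'
#' Joins per-locus forward-spliced (linear) junction read counts onto the
#' circRNA table. Junctions absent from `fwd` get zero counts.
#'
#' @param circs Data frame from [filter_support()].
#' @param fwd Data frame with columns `chrom, start, end, strand,
#'   sample_id, fwd_acceptor, fwd_donor` (linear junction-spanning reads at
#'   the acceptor-side and donor-side loci of each circle).
#' @return `circs` with `fwd_acceptor` and `fwd_donor` columns.
#' @export
attach_forward_reads <- function(circs, fwd) {
  key <- function(d) paste(d$chrom, d$start, d$end, d$strand, d$sample_id,
                           sep = "\r")
  idx <- match(key(circs), key(fwd))
  circs$fwd_acceptor <- ifelse(is.na(idx), 0L, fwd$fwd_acceptor[idx])
  circs$fwd_donor <- ifelse(is.na(idx), 0L, fwd$fwd_donor[idx])
  circs
}

#' Call circRNAs end to end
#'
#' Convenience wrapper: [annotate_backsplices()], [filter_support()],
#' [classify_exon_position()], and optional [attach_forward_reads()].
#'
#' @inheritParams annotate_backsplices
#' @inheritParams filter_support
#' @param fwd Optional forward-junction count table.
#' @param ... Passed to [classify_exon_position()].
#' @return Annotated circRNA table.
#' @export
call_circrnas <- function(reads, genes, tol = 0, min_reads = 2, fwd = NULL,
                          ...) {
  cand <- annotate_backsplices(reads, genes, tol = tol)
  circs <- filter_support(cand, min_reads = min_reads)
  circs <- classify_exon_position(circs, genes, ...)
  if (!is.null(fwd)) circs <- attach_forward_reads(circs, fwd)
  else {
    circs$fwd_acceptor <- 0L
    circs$fwd_donor <- 0L
  }
  attr(circs, "diagnostics") <- attr(cand, "diagnostics")
  circs
}
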