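# Junction-level circular/linear statistics and circRNA genomic features.

#' Junction metrics: circ ratio and circular-to-linear ratio (CLR)
#'
#' circ ratio = back / (back + forward); CLR = ratio / (1 - ratio) =
#' back / forward. Both are undefined (NA) when back + forward = 0; the CLR
#' of a junction with back > 0 but no forward reads is flagged infinite.
#' Forward counts observed at the two junction loci of one circle should be
#' averaged before calling (see [circ_junction_metrics()]).
#'
#' @param back,forward Non-negative read counts (vectorized).
#' @return Data frame with `back`, `forward`, `circ_ratio`, `clr`,
#'   `clr_infinite`.
#' @export
junction_metrics <- function(back, forward) {
  if (any(back < 0) || any(forward < 0)) stop("counts must be non-negative")
  total <- back + forward
  ratio <- ifelse(total > 0, back / total, NA_real_)
  clr <- ifelse(total == 0, NA_real_,
                ifelse(forward > 0, back / forward, NA_real_))
  data.frame(back = back, forward = forward, circ_ratio = ratio, clr = clr,
             clr_infinite = total > 0 & forward == 0 & back > 0)
}

#' Junction metrics for an annotated circRNA table
#'
#' The forward-spliced count of a circle is the mean of the counts at its
#' two junction loci (acceptor and donor side), chosen for symmetry.
#'
#' @param circs circRNA table with `back_reads`, `fwd_acceptor`,
#'   `fwd_donor`.
#' @return `circs` with `forward_reads`, `circ_ratio`, `clr`,
#'   `clr_infinite` columns.
#' @export
circ_junction_metrics <- function(circs) {
  fwd <- (circs$fwd_acceptor + circs$fwd_donor) / 2
  jm <- junction_metrics(circs$back_reads, fwd)
  circs$forward_reads <- fwd
  circs$circ_ratio <- jm$circ_ratio
  circs$clr <- jm$clr
  circs$clr_infinite <- jm$clr_infinite
  circs
}

#' Discount hosting-gene RPKM by the circular fraction
#'
#' RPKM_discounted = RPKM x (1 - circ ratio): the linear-only expression of
#' a hosting gene, used to compare hosting against non-hosting genes.
#'
#' @param rpkm RPKM value(s).
#' @param circ_ratio Circular fraction(s) in \[0, 1\].
#' @return Discounted RPKM.
#' @export
discounted_rpkm <- function(rpkm, circ_ratio) {
  if (any(is.na(circ_ratio)) || any(circ_ratio < 0) || any(circ_ratio > 1)) {
    stop("circ_ratio must lie in [0, 1]")
  }
  rpkm * (1 - circ_ratio)
}

#' Genomic features of a circRNA set
#'
#' For each distinct circle: number and lengths of back-spliced exons, and
#' the flanking intron lengths — the intron immediately 5' (transcript
#' orientation) of the acceptor exon and immediately 3' of the donor exon.
#' A circle touching a terminal exon lacks the corresponding flanking
#' intron (NA). Per hosting gene, the number of distinct circular isoforms
#' is counted; genes with >= 2 isoforms are hot-spot genes.
#'
#' @param circs circRNA table (rows may repeat across samples; circles are
#'   deduplicated on the canonical key).
#' @param genes Named list of [gene_model()] objects.
#' @return List with `per_circ` (one row per distinct circle: key columns,
#'   `n_exons`, `exon_lengths` comma-string, `total_exon_len`,
#'   `upstream_intron_len`, `downstream_intron_len`) and `per_gene`
#'   (`gene_id`, `n_isoforms`, `hotspot`).
#' @export
flanking_features <- function(circs, genes) {
  key_cols <- c("chrom", "start", "end", "strand", "gene_id", "exon_from",
                "exon_to")
  uc <- unique(circs[, key_cols, drop = FALSE])
  rownames(uc) <- NULL
  n <- nrow(uc)
  n_exons <- integer(n)
  exon_lengths <- character(n)
  total_len <- numeric(n)
  up_len <- down_len <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    g <- genes[[uc$gene_id[i]]]
    if (is.null(g)) stop(sprintf("unknown hosting gene %s", uc$gene_id[i]))
    idx <- uc$exon_from[i]:uc$exon_to[i]
    ex <- g$exons[idx, , drop = FALSE]
    lens <- ex$end - ex$start
    n_exons[i] <- length(idx)
    exon_lengths[i] <- paste(lens, collapse = ",")
    total_len[i] <- sum(lens)
    introns <- gene_introns(g)  # intron k lies between exons k and k+1
    # genomic-left intron (before exon_from) and genomic-right intron
    left <- if (uc$exon_from[i] > 1L) {
      introns$end[uc$exon_from[i] - 1L] - introns$start[uc$exon_from[i] - 1L]
    } else NA_real_
    right <- if (uc$exon_to[i] < nrow(g$exons)) {
      introns$end[uc$exon_to[i]] - introns$start[uc$exon_to[i]]
    } else NA_real_
    if (g$strand == "+") {
      up_len[i] <- left
      down_len[i] <- right
    } else {
      up_len[i] <- right
      down_len[i] <- left
    }
  }
  per_circ <- cbind(uc, data.frame(
    n_exons = n_exons, exon_lengths = exon_lengths,
    total_exon_len = total_len, upstream_intron_len = up_len,
    downstream_intron_len = down_len, stringsAsFactors = FALSE))
  iso <- table(uc$gene_id)
  per_gene <- data.frame(gene_id = names(iso),
                         n_isoforms = as.integer(iso),
                         stringsAsFactors = FALSE)
  per_gene$hotspot <- per_gene$n_isoforms >= 2L
  per_gene <- per_gene[order(per_gene$gene_id), , drop = FALSE]
  rownames(per_gene) <- NULL
  list(per_circ = per_circ, per_gene = per_gene)
}

#' Flanking introns of a circRNA set as genomic intervals
#'
#' @param circs circRNA table.
#' @param genes Named list of [gene_model()] objects.
#' @return Data frame of distinct flanking-intron intervals (`chrom`,
#'   `start`, `end`, `side` in upstream/downstream).
#' @export
flanking_intron_intervals <- function(circs, genes) {
  key_cols <- c("chrom", "start", "end", "strand", "gene_id", "exon_from",
                "exon_to")
  uc <- unique(circs[, key_cols, drop = FALSE])
  out <- list()
  for (i in seq_len(nrow(uc))) {
    g <- genes[[uc$gene_id[i]]]
    introns <- gene_introns(g)
    if (uc$exon_from[i] > 1L) {
      k <- uc$exon_from[i] - 1L
      out[[length(out) + 1L]] <- data.frame(
        chrom = g$chrom, start = introns$start[k], end = introns$end[k],
        side = if (g$strand == "+") "upstream" else "downstream",
        stringsAsFactors = FALSE)
    }
    if (uc$exon_to[i] < nrow(g$exons)) {
      k <- uc$exon_to[i]
      out[[length(out) + 1L]] <- data.frame(
        chrom = g$chrom, start = introns$start[k], end = introns$end[k],
        side = if (g$strand == "+") "downstream" else "upstream",
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               side = character(0))
  rownames(res) <- NULL
  res
}

#' Sample control introns from expressed non-hosting genes
#'
#' Draws a seeded uniform sample of introns from genes that are expressed
#' (RPKM >= `min_rpkm` in at least one sample) and host no detected
#' circRNA, matched in number to the flanking set.
#'
#' @param genes Named list of [gene_model()] objects.
#' @param hosting_genes Character vector of hosting gene ids to exclude.
#' @param n Number of introns to draw.
#' @param seed Integer seed.
#' @param rpkm Optional gene x sample RPKM matrix for the expression gate.
#' @param min_rpkm Expression threshold (default 1).
#' @return Data frame of intron intervals (`chrom`, `start`, `end`).
#' @export
sample_control_introns <- function(genes, hosting_genes, n, seed,
                                   rpkm = NULL, min_rpkm = 1) {
  pool_genes <- setdiff(names(genes), hosting_genes)
  if (!is.null(rpkm)) {
    expressed <- rownames(rpkm)[apply(rpkm >= min_rpkm, 1, any)]
    pool_genes <- intersect(pool_genes, expressed)
  }
  pool <- do.call(rbind, lapply(pool_genes, function(id) {
    g <- genes[[id]]
    ii <- gene_introns(g)
    if (nrow(ii) == 0L) return(NULL)
    data.frame(chrom = g$chrom, start = ii$start, end = ii$end,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pool) || nrow(pool) == 0L) {
    stop("no control introns available")
  }
  with_seed(seed, {
    idx <- sample.int(nrow(pool), n, replace = nrow(pool) < n)
    out <- pool[idx, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Repeat-element enrichment in flanking vs control introns
#'
#' Counts repeat elements per intron (an element counts when its interval
#' intersects the intron), computes per-kb densities, and compares the
#' flanking and control count distributions with a two-sided Wilcoxon
#' rank-sum test.
#'
#' @param flanking_introns,control_introns Data frames of intron intervals
#'   (`chrom`, `start`, `end`, 0-based half-open).
#' @param repeats Data frame of repeat intervals ([read_bed()] layout).
#' @return List with `flank_counts`, `control_counts` (per-intron element
#'   counts), `flank_density`, `control_density` (elements per kb),
#'   `median_flank`, `median_control`, and `p_value`.
#' @export
alu_enrichment <- function(flanking_introns, control_introns, repeats) {
  if (nrow(control_introns) == 0L) stop("control intron set is empty")
  count_overlaps <- function(introns) {
    gi <- GenomicRanges::GRanges(
      introns$chrom,
      IRanges::IRanges(start = introns$start + 1L, end = introns$end))
    gr <- GenomicRanges::GRanges(
      repeats$chrom,
      IRanges::IRanges(start = repeats$start + 1L, end = repeats$end))
    GenomicRanges::countOverlaps(gi, gr)
  }
  fc <- count_overlaps(flanking_introns)
  cc <- count_overlaps(control_introns)
  fd <- fc / ((flanking_introns$end - flanking_introns$start) / 1000)
  cd <- cc / ((control_introns$end - control_introns$start) / 1000)
  p <- suppressWarnings(stats::wilcox.test(fc, cc, exact = FALSE)$p.value)
  list(flank_counts = fc, control_counts = cc, flank_density = fd,
       control_density = cd, median_flank = stats::median(fc),
       median_control = stats::median(cc), p_value = p)
}
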