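# mRNA-content-aware normalization, pairwise NB differential expression,
# and maternal/zygotic classification across the embryo series.
#
# The size factors account for both sequencing depth and the absolute mRNA
# content of each embryo: factor_s is proportional to
# total_mapped_reads_s / mrna_copies_s, rescaled to geometric mean 1.
# Dividing counts by the factors puts samples on a per-copy scale, so a
# maternal transcript that is merely diluted by zygotic transcription is
# not mistaken for an induced one.
#
# The pairwise test is a deliberately lightweight negative-binomial Wald
# test: per-gene means on the normalized scale, a method-of-moments
# dispersion pooled across the two groups (floored), and a t-reference
# Wald statistic on the log fold change with Benjamini-Hochberg correction.

#' mRNA-content-aware size factors
#'
#' @param ct A [count_table()].
#' @param mrna_copies Named numeric vector of per-sample absolute mRNA
#'   copies (e.g. the `final` column of [estimate_copy_numbers()]).
#' @return Named numeric vector of size factors with geometric mean 1.
#' @export
size_factors <- function(ct, mrna_copies) {
  mrna_copies <- mrna_copies[colnames(ct$counts)]
  if (any(is.na(mrna_copies)) || any(mrna_copies <= 0)) {
    stop("every sample needs a positive mRNA copy estimate")
  }
  f <- ct$total_mapped_reads / mrna_copies
  f / exp(mean(log(f)))
}

#' Pairwise negative-binomial differential expression
#'
#' Tests each gene for differential expression between two stages from
#' replicate count vectors. Counts are divided by their size factors;
#' per-group means and a pooled method-of-moments NB dispersion (floored at
#' `min_disp`) feed a Wald test on the log fold change, referenced against
#' a t distribution with `nA + nB - 2` degrees of freedom. P-values are
#' BH-adjusted across the tested genes. Direction is `up` when fold change
#' > `fc_up` and FDR < `alpha`, `down` when fold change < `fc_down` and
#' FDR < `alpha`, otherwise `ns`.
#'
#' @param counts_a,counts_b Matrices (genes x replicates) of raw counts for
#'   the two stages, same genes in the same order.
#' @param factors_a,factors_b Size factors for the replicate columns.
#' @param min_disp Dispersion floor (default 0.01).
#' @param fc_up,fc_down Fold-change gates for the up/down calls (defaults
#'   2 and 0.5).
#' @param alpha FDR threshold for the calls (default 0.05).
#' @return Data frame: `gene_id`, `mean_a`, `mean_b`, `log2_fold_change`,
#'   `dispersion`, `p_value`, `fdr`, `direction`.
#' @export
pairwise_de <- function(counts_a, counts_b, factors_a, factors_b,
                        min_disp = 0.01, fc_up = 2, fc_down = 0.5,
                        alpha = 0.05) {
  counts_a <- as.matrix(counts_a)
  counts_b <- as.matrix(counts_b)
  if (nrow(counts_a) != nrow(counts_b)) {
    stop("the two stages must cover the same genes")
  }
  na <- ncol(counts_a)
  nb <- ncol(counts_b)
  norm_a <- sweep(counts_a, 2, factors_a, "/")
  norm_b <- sweep(counts_b, 2, factors_b, "/")
  mu_a <- rowMeans(norm_a)
  mu_b <- rowMeans(norm_b)

  mom_disp <- function(norm, mu) {
    if (ncol(norm) < 2L) return(rep(NA_real_, length(mu)))
    v <- apply(norm, 1, stats::var)
    ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
  }
  d_a <- mom_disp(norm_a, mu_a)
  d_b <- mom_disp(norm_b, mu_b)
  disp <- pmax(min_disp, rowMeans(cbind(d_a, d_b), na.rm = TRUE))
  disp[is.na(disp)] <- min_disp

  eps <- 0.5  # pseudo-mean keeps the statistic finite at zero counts
  lfc <- log2((mu_b + eps) / (mu_a + eps))
  # delta-method variance of log(mean) under NB: (mu + disp*mu^2) / (n*mu^2)
  var_log <- function(mu, n) (pmax(mu, eps) + disp * pmax(mu, eps)^2) /
    (n * pmax(mu, eps)^2)
  se <- sqrt(var_log(mu_a, na) + var_log(mu_b, nb)) / log(2)
  stat <- lfc / se
  df <- max(1L, na + nb - 2L)
  p <- 2 * stats::pt(-abs(stat), df = df)
  fdr <- stats::p.adjust(p, method = "BH")
  fc <- 2^lfc
  direction <- ifelse(fc > fc_up & fdr < alpha, "up",
                      ifelse(fc < fc_down & fdr < alpha, "down", "ns"))
  data.frame(gene_id = rownames(counts_a) %||% as.character(seq_along(mu_a)),
             mean_a = mu_a, mean_b = mu_b, log2_fold_change = lfc,
             dispersion = disp, p_value = p, fdr = fdr,
             direction = direction, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Differential expression over consecutive stages of a series
#'
#' Applies the expression gate (normalized RPKM >= `min_rpkm` in at least
#' one sample) once, then runs [pairwise_de()] on every consecutive stage
#' pair.
#'
#' @param ct A [count_table()] (gene rows only).
#' @param factors Named size-factor vector for all samples.
#' @param stages Named character vector mapping sample id -> stage label.
#' @param stage_order Character vector giving the developmental order.
#' @param lengths Named gene lengths in nt (for the RPKM gate).
#' @param min_rpkm Expression gate on normalized RPKM (default 1).
#' @param ... Passed to [pairwise_de()].
#' @return Named list of [pairwise_de()] results, one per consecutive pair
#'   (`"stageA->stageB"`), plus attribute `tested_genes`.
#' @export
de_stage_series <- function(ct, factors, stages, stage_order, lengths,
                            min_rpkm = 1, ...) {
  stages <- stages[colnames(ct$counts)]
  if (any(is.na(stages))) stop("every sample needs a stage label")
  missing_stage <- setdiff(stage_order, unique(stages))
  if (length(missing_stage)) {
    stop(sprintf("stage(s) with no samples: %s",
                 paste(missing_stage, collapse = ", ")))
  }
  rpkm <- compute_rpkm(ct, lengths)
  norm_rpkm <- sweep(rpkm, 2, factors[colnames(rpkm)], "/")
  keep <- apply(norm_rpkm >= min_rpkm, 1, any)
  if (!any(keep)) {
    warning("no genes pass the expression gate")
    return(structure(list(), tested_genes = character(0)))
  }
  genes <- rownames(ct$counts)[keep]
  out <- list()
  for (k in seq_len(length(stage_order) - 1L)) {
    a <- stage_order[k]
    b <- stage_order[k + 1L]
    cols_a <- names(stages)[stages == a]
    cols_b <- names(stages)[stages == b]
    out[[paste0(a, "->", b)]] <- pairwise_de(
      ct$counts[genes, cols_a, drop = FALSE],
      ct$counts[genes, cols_b, drop = FALSE],
      factors[cols_a], factors[cols_b], ...)
  }
  structure(out, tested_genes = genes)
}

#' Classify genes as maternal, zygotic, or undetermined
#'
#' A gene is *maternal* when its mean normalized RPKM peaks in the oocyte
#' and some consecutive-stage comparison at or after the 4-cell stage calls
#' it significantly down. It is *zygotic* when some comparison at or after
#' the 4-cell stage calls it significantly up and the oocyte is not its
#' peak stage. Everything else is *undetermined*.
#'
#' @param de_list Output of [de_stage_series()].
#' @param norm_rpkm Gene x sample normalized RPKM matrix.
#' @param stages Named sample -> stage mapping.
#' @param stage_order Developmental stage order (first element = oocyte).
#' @param four_cell Label of the 4-cell stage (must be in `stage_order`).
#' @return Data frame `gene_id`, `peak_stage`, `class`.
#' @export
classify_maternal_zygotic <- function(de_list, norm_rpkm, stages,
                                      stage_order, four_cell = "4cell") {
  if (!four_cell %in% stage_order) {
    stop(sprintf("4-cell stage label '%s' not found in stage_order",
                 four_cell))
  }
  stages <- stages[colnames(norm_rpkm)]
  stage_mean <- sapply(stage_order, function(st) {
    rowMeans(norm_rpkm[, names(stages)[stages == st], drop = FALSE])
  })
  peak <- stage_order[max.col(stage_mean, ties.method = "first")]

  i4 <- match(four_cell, stage_order)
  # comparisons whose *left* stage is at/after the 4-cell stage, i.e. the
  # change happens after it
  late_pairs <- names(de_list)[vapply(names(de_list), function(nm) {
    a <- sub("->.*$", "", nm)
    match(a, stage_order) >= i4
  }, logical(1))]

  genes <- rownames(norm_rpkm)
  down_late <- up_late <- stats::setNames(rep(FALSE, length(genes)), genes)
  for (nm in late_pairs) {
    de <- de_list[[nm]]
    down_late[de$gene_id[de$direction == "down"]] <- TRUE
    up_late[de$gene_id[de$direction == "up"]] <- TRUE
  }
  oocyte <- stage_order[1L]
  cls <- ifelse(peak == oocyte & down_late, "maternal",
                ifelse(up_late & peak != oocyte, "zygotic", "undetermined"))
  data.frame(gene_id = genes, peak_stage = peak, class = cls,
             row.names = NULL, stringsAsFactors = FALSE)
}
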