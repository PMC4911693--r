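# RPKM and dual spike-in absolute quantification.
#
# Two independent anchors give per-sample absolute mRNA copy numbers:
#   * ERCC route: OLS of log10(RPKM) on log10(attomole) over the retained
#     dilution-panel species, inverted per gene and summed; attomoles are
#     converted to molecules with 1 attomole = 6.02214e5 molecules.
#   * RGC route: for each species of the long-polyA mix, (total RefSeq
#     RPKM / species RPKM) x spiked molecules, averaged over detected
#     species.
# The final per-sample copy number is the fitted value of a log-log OLS of
# the RGC-based on the ERCC-based estimates across all samples, evaluated
# at the sample's ERCC-based estimate and back-transformed.

MOLECULES_PER_ATTOMOLE <- 6.02214e5

#' Compute RPKM
#'
#' RPKM = count / (feature length in kb x total mapped reads in millions).
#'
#' @param ct A [count_table()].
#' @param lengths Named numeric vector of feature lengths in nt.
#' @return Matrix of RPKM values, features x samples.
#' @export
compute_rpkm <- function(ct, lengths) {
  feats <- rownames(ct$counts)
  len <- lengths[feats]
  bad <- feats[is.na(len)]
  if (length(bad)) {
    stop(sprintf("missing length for feature(s): %s",
                 paste(utils::head(bad, 10), collapse = ", ")))
  }
  if (any(len <= 0)) {
    stop(sprintf("non-positive length for feature(s): %s",
                 paste(utils::head(feats[len <= 0], 10), collapse = ", ")))
  }
  sweep(ct$counts / (len / 1000), 2, ct$total_mapped_reads / 1e6, "/")
}

#' ERCC-anchored total mRNA copy number for one sample
#'
#' Fits log10(RPKM) ~ log10(attomole) by ordinary least squares over the
#' ERCC species retained by the input-amount filter (`> min_amount`
#' attomole, strict) that were detected (RPKM > 0), then solves the fitted
#' line for attomole at each gene's RPKM, sums, and converts to molecules.
#' Genes with zero RPKM contribute zero.
#'
#' @param ercc_rpkm Named numeric vector, RPKM per ERCC species.
#' @param panel Spike-in panel data frame ([read_spikein_panel()] layout);
#'   ERCC amounts in attomole per reaction.
#' @param gene_rpkm Named numeric vector, RPKM per gene.
#' @param min_amount Retention threshold in attomole (default 0.001).
#' @param sample_id Label used in error messages.
#' @return List with `slope`, `intercept` (of the log10 RPKM ~ log10
#'   attomole fit), `n_species` used, and `copies` (molecules).
#' @export
ercc_total_copies <- function(ercc_rpkm, panel, gene_rpkm,
                              min_amount = 0.001, sample_id = "sample") {
  ercc <- panel[panel$class == "ERCC", , drop = FALSE]
  amount <- stats::setNames(ercc$amount, ercc$species_id)
  shared <- intersect(names(ercc_rpkm), names(amount))
  amount <- amount[shared]
  rpkm <- ercc_rpkm[shared]
  use <- amount > min_amount & rpkm > 0
  if (sum(use) < 3L) {
    stop(sprintf(
      "sample %s: only %d usable ERCC species (need >= 3 with amount > %g attomole and RPKM > 0)",
      sample_id, sum(use), min_amount))
  }
  x <- log10(amount[use])
  y <- log10(rpkm[use])
  fit <- stats::lm.fit(cbind(1, x), y)
  intercept <- unname(fit$coefficients[1L])
  slope <- unname(fit$coefficients[2L])
  pos <- gene_rpkm > 0
  att <- numeric(length(gene_rpkm))
  att[pos] <- 10^((log10(gene_rpkm[pos]) - intercept) / slope)
  list(slope = slope, intercept = intercept, n_species = sum(use),
       copies = sum(att) * MOLECULES_PER_ATTOMOLE)
}

#' RGC-anchored total mRNA copy number for one sample
#'
#' Each detected species of the long-polyA mix gives an estimate
#' (total RefSeq RPKM / species RPKM) x spiked molecules; the estimates are
#' averaged.
#'
#' @param rgc_rpkm Named numeric vector, RPKM per RGC species.
#' @param spiked_molecules Named numeric vector, molecules spiked per
#'   species.
#' @param total_refseq_rpkm Sum of RPKM over RefSeq genes in the sample.
#' @param sample_id Label used in error messages.
#' @return Estimated total mRNA molecules.
#' @export
rgc_total_copies <- function(rgc_rpkm, spiked_molecules, total_refseq_rpkm,
                             sample_id = "sample") {
  shared <- intersect(names(rgc_rpkm), names(spiked_molecules))
  rpkm <- rgc_rpkm[shared]
  mol <- spiked_molecules[shared]
  use <- rpkm > 0
  if (!any(use)) {
    stop(sprintf("sample %s: no RGC species detected (all RPKM zero)",
                 sample_id))
  }
  mean((total_refseq_rpkm / rpkm[use]) * mol[use])
}

#' Combine the two spike-in routes into final copy numbers
#'
#' Regresses log10(RGC-based) on log10(ERCC-based) over all samples; the
#' final copy number of a sample is the fitted value at its ERCC-based
#' estimate, back-transformed.
#'
#' @param ercc_based Named numeric vector of per-sample ERCC-based copies.
#' @param rgc_based Named numeric vector (same samples) of RGC-based copies.
#' @return List with `final` (named vector of molecules), `slope` and
#'   `intercept` of the combining fit.
#' @export
combine_copy_estimates <- function(ercc_based, rgc_based) {
  rgc_based <- rgc_based[names(ercc_based)]
  ok <- !is.na(ercc_based) & !is.na(rgc_based) & ercc_based > 0 &
    rgc_based > 0
  if (sum(ok) < 3L) {
    stop("need >= 3 samples with positive estimates from both routes")
  }
  x <- log10(ercc_based[ok])
  y <- log10(rgc_based[ok])
  fit <- stats::lm.fit(cbind(1, x), y)
  b0 <- unname(fit$coefficients[1L])
  b1 <- unname(fit$coefficients[2L])
  final <- stats::setNames(rep(NA_real_, length(ercc_based)),
                           names(ercc_based))
  final[ok] <- 10^(b0 + b1 * log10(ercc_based[ok]))
  list(final = final, slope = b1, intercept = b0)
}

#' Effective circRNA length for junction RPKM
#'
#' A back-splicing event is detectable by reads mapping up to
#' `read_length - anchor` nt away from the junction in each direction, so
#' the length term of the junction RPKM is `(read_length - anchor) * 2`
#' (150 bp for 100 bp reads with the default 25 bp anchor segment).
#'
#' @param read_length Read length in nt.
#' @param anchor Minimum anchoring segment length in nt (default 25).
#' @return Effective length in nt.
#' @export
effective_circ_length <- function(read_length, anchor = 25) {
  stopifnot_scalar_number(read_length, "read_length", min = 0)
  stopifnot_scalar_number(anchor, "anchor", min = 0)
  if (read_length <= anchor) {
    stop(sprintf("read_length (%g) must exceed the anchor length (%g)",
                 read_length, anchor))
  }
  (read_length - anchor) * 2
}

#' Junction RPKM of a circRNA
#'
#' @param junction_reads Back-spliced junction read count.
#' @param read_length Read length in nt.
#' @param total_mapped_reads Total mapped reads in the sample.
#' @param anchor Anchor length in nt (default 25).
#' @return RPKM computed with [effective_circ_length()] as the length term.
#' @export
circ_rpkm <- function(junction_reads, read_length, total_mapped_reads,
                      anchor = 25) {
  eff <- effective_circ_length(read_length, anchor)
  junction_reads / ((eff / 1000) * (total_mapped_reads / 1e6))
}

#' Total circRNA copy number in a sample
#'
#' (sum of circRNA junction RPKM / sum of RefSeq gene RPKM) x mRNA copies.
#'
#' @param circ_rpkm_sum Sum of circRNA junction RPKM.
#' @param refseq_rpkm_sum Sum of RefSeq gene RPKM (must be positive).
#' @param mrna_copies Absolute mRNA copy number of the sample.
#' @return circRNA molecules.
#' @export
circ_copy_number <- function(circ_rpkm_sum, refseq_rpkm_sum, mrna_copies) {
  if (!is.numeric(refseq_rpkm_sum) || any(refseq_rpkm_sum <= 0)) {
    stop("refseq_rpkm_sum must be positive")
  }
  (circ_rpkm_sum / refseq_rpkm_sum) * mrna_copies
}

#' Subsample counts to a fixed depth
#'
#' Draws `depth` reads without replacement from the reads underlying a
#' count vector (multivariate hypergeometric), so cross-condition
#' comparisons can be made at the same depth. Deterministic for a given
#' seed.
#'
#' @param counts Named non-negative integer vector, or a [count_table()]
#'   (every sample column is subsampled to `depth`).
#' @param depth Target total (must not exceed the current total).
#' @param seed Integer seed.
#' @return Same type as `counts`.
#' @export
subsample_counts <- function(counts, depth, seed) {
  if (inherits(counts, "count_table")) {
    m <- counts$counts
    for (j in seq_len(ncol(m))) {
      m[, j] <- subsample_counts(m[, j], depth, derive_seed(seed, j))
    }
    return(count_table(m, stats::setNames(rep(depth, ncol(m)), colnames(m)),
                       counts$read_length))
  }
  total <- sum(counts)
  if (depth > total) {
    stop(sprintf("requested depth %g exceeds total %g", depth, total))
  }
  with_seed(seed, {
    out <- counts
    remaining <- total
    left <- depth
    for (i in seq_along(counts)) {
      if (left == 0L) {
        out[i:length(counts)] <- 0L
        break
      }
      # draws for feature i given what is left: hypergeometric
      k <- stats::rhyper(1, counts[i], remaining - counts[i], left)
      out[i] <- k
      left <- left - k
      remaining <- remaining - counts[i]
    }
    out
  })
}

#' ERCC quality-control filter and technical-error estimate
#'
#' Retains ERCC species with RPKM >= `min_rpkm` in more than two samples
#' (i.e. at least `min_samples` = 3), and computes the pairwise Pearson
#' correlation between samples over the retained species as the
#' technical-error estimate.
#'
#' @param ercc_rpkm Matrix of ERCC RPKM, species x samples (>= 2 samples).
#' @param min_rpkm Detection threshold (default 1).
#' @param min_samples Minimum number of samples meeting it (default 3).
#' @return List with `ok` (logical), `retained` (species ids), `pearson`
#'   (sample x sample correlation matrix, or `NULL` on QC failure), and
#'   `mean_pearson` (mean off-diagonal correlation).
#' @export
ercc_qc <- function(ercc_rpkm, min_rpkm = 1, min_samples = 3) {
  if (ncol(ercc_rpkm) < 2L) stop("ercc_qc needs at least 2 samples")
  keep <- rowSums(ercc_rpkm >= min_rpkm) >= min_samples
  retained <- rownames(ercc_rpkm)[keep]
  if (!any(keep)) {
    return(list(ok = FALSE, retained = character(0), pearson = NULL,
                mean_pearson = NA_real_))
  }
  p <- stats::cor(ercc_rpkm[keep, , drop = FALSE],
                  use = "pairwise.complete.obs", method = "pearson")
  mp <- mean(p[upper.tri(p)])
  list(ok = TRUE, retained = retained, pearson = p, mean_pearson = mp)
}

#' Per-sample absolute copy estimates for a whole series
#'
#' Orchestrates the dual spike-in quantification over a count table:
#' computes RPKM, runs the ERCC and RGC routes per sample, combines them,
#' and (when a circRNA table is supplied) converts circRNA junction RPKM
#' sums into absolute circRNA copies.
#'
#' @param ct A [count_table()] whose rows include genes and spike-ins.
#' @param panel Spike-in panel data frame.
#' @param lengths Named numeric vector of feature lengths in nt (genes and
#'   spike-ins).
#' @param circs Optional circRNA table with `sample_id` and `back_reads`.
#' @param anchor Anchor length for the circRNA length term (default 25).
#' @return Data frame, one row per sample: `sample_id`, `ercc_based`,
#'   `rgc_based`, `final`, `circ_copies` (NA without `circs`), and the
#'   per-sample ERCC regression `slope`/`intercept`.
#' @export
estimate_copy_numbers <- function(ct, panel, lengths, circs = NULL,
                                  anchor = 25) {
  rpkm <- compute_rpkm(ct, lengths)
  ercc_ids <- panel$species_id[panel$class == "ERCC"]
  rgc_ids <- panel$species_id[panel$class == "RGC"]
  gene_ids <- setdiff(rownames(rpkm), c(ercc_ids, rgc_ids))
  samples <- colnames(rpkm)
  rgc_mol <- stats::setNames(panel$amount[panel$class == "RGC"],
                             panel$species_id[panel$class == "RGC"])

  ercc_based <- rgc_based <- slope <- intercept <- stats::setNames(
    rep(NA_real_, length(samples)), samples)
  for (s in samples) {
    gene_r <- rpkm[gene_ids, s]
    e <- ercc_total_copies(rpkm[intersect(ercc_ids, rownames(rpkm)), s],
                           panel, gene_r, sample_id = s)
    ercc_based[s] <- e$copies
    slope[s] <- e$slope
    intercept[s] <- e$intercept
    rgc_based[s] <- rgc_total_copies(
      rpkm[intersect(rgc_ids, rownames(rpkm)), s], rgc_mol,
      sum(gene_r), sample_id = s)
  }
  comb <- combine_copy_estimates(ercc_based, rgc_based)

  circ_copies <- stats::setNames(rep(NA_real_, length(samples)), samples)
  if (!is.null(circs) && nrow(circs) > 0L) {
    for (s in samples) {
      sub <- circs[circs$sample_id == s, , drop = FALSE]
      csum <- if (nrow(sub) == 0L) 0 else
        sum(circ_rpkm(sub$back_reads, ct$read_length[[s]],
                      ct$total_mapped_reads[[s]], anchor = anchor))
      circ_copies[s] <- circ_copy_number(csum, sum(rpkm[gene_ids, s]),
                                         comb$final[[s]])
    }
  } else if (!is.null(circs)) {
    circ_copies[] <- 0
  }

  data.frame(sample_id = samples, ercc_based = as.numeric(ercc_based),
             rgc_based = as.numeric(rgc_based),
             final = as.numeric(comb$final[samples]),
             circ_copies = as.numeric(circ_copies),
             slope = as.numeric(slope), intercept = as.numeric(intercept),
             stringsAsFactors = FALSE)
}
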