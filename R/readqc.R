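# Raw-read cleaning for SUPeR-seq libraries.
#
# Rules, applied in order per read:
#   1. discard if more than `lowqual_frac` of bases have Phred quality <=
#      `qual_threshold` (default: >50 % at Q<=5);
#   2. discard if more than `n_frac` of bases are undetermined (N);
#   3. trim adaptor matches (read truncated at the first exact occurrence);
#   4. trim terminal poly(A)/poly(T) runs of at least `polyrun` bases
#      (poly-T at the 5' end, poly-A at the 3' end), one pass;
#   5. discard if the remaining sequence is more than `at_frac` A/T, or
#      shorter than `min_len`.
# Trimming precedes the AT-content test (the protocol's anchored-polyT
# priming makes terminal runs artefactual, so content is judged on the
# insert), and all thresholds are strict inequalities.

#' Clean and trim raw reads
#'
#' @param infile Path to a FASTQ file (Phred+33 qualities).
#' @param outfile Optional path; when given, surviving reads are written
#'   there as FASTQ.
#' @param adaptors Character vector of adaptor sequences to trim.
#' @param qual_threshold Phred score at or below which a base counts as
#'   low quality. Default 5.
#' @param lowqual_frac Discard a read when the low-quality base fraction
#'   exceeds this. Default 0.5.
#' @param n_frac Discard a read when the undetermined (N) base fraction
#'   exceeds this. Default 0.1.
#' @param at_frac Discard a read when the post-trim A/T fraction exceeds
#'   this. Default 0.8.
#' @param polyrun Minimum length of a terminal homopolymer run to trim.
#'   Default 24.
#' @param min_len Minimum post-trim read length. Default 30.
#' @return A list with `reads` (data frame: `id`, `seq`, `qual` of the
#'   surviving, possibly trimmed reads) and `report` (a `qc_report`).
#' @export
clean_reads <- function(infile, outfile = NULL, adaptors = character(),
                        qual_threshold = 5, lowqual_frac = 0.5,
                        n_frac = 0.1, at_frac = 0.8, polyrun = 24,
                        min_len = 30) {
  fq <- Biostrings::readDNAStringSet(infile, format = "fastq",
                                     with.qualities = TRUE)
  reads <- data.frame(id = names(fq),
                      seq = as.character(fq),
                      qual = as.character(S4Vectors::mcols(fq)$qualities),
                      stringsAsFactors = FALSE)
  res <- clean_read_frame(reads, adaptors, qual_threshold, lowqual_frac,
                          n_frac, at_frac, polyrun, min_len)
  if (!is.null(outfile)) write_fastq(res$reads, outfile)
  res
}

# Core cleaning on an in-memory read frame (id, seq, qual).
clean_read_frame <- function(reads, adaptors, qual_threshold, lowqual_frac,
                             n_frac, at_frac, polyrun, min_len) {
  n_input <- nrow(reads)
  report <- c(n_input = n_input, n_discarded_lowqual = 0L,
              n_discarded_undetermined = 0L, n_trimmed_adaptor = 0L,
              n_trimmed_polyAT = 0L, n_discarded_AT = 0L,
              n_discarded_short = 0L, n_output = 0L)
  if (n_input == 0L) {
    return(list(reads = reads, report = structure(as.list(report),
                                                  class = "qc_report")))
  }

  qmat <- lapply(reads$qual, function(q) as.integer(charToRaw(q)) - 33L)
  len <- nchar(reads$seq)
  frac_low <- vapply(seq_len(n_input), function(i) {
    mean(qmat[[i]] <= qual_threshold)
  }, numeric(1))
  drop_low <- frac_low > lowqual_frac
  report["n_discarded_lowqual"] <- sum(drop_low)

  n_count <- vapply(gregexpr("[^ACGTacgt]", reads$seq), function(m) {
    if (m[1L] == -1L) 0L else length(m)
  }, integer(1))
  drop_n <- !drop_low & (n_count / len > n_frac)
  report["n_discarded_undetermined"] <- sum(drop_n)

  keep <- !(drop_low | drop_n)
  reads <- reads[keep, , drop = FALSE]

  if (nrow(reads) > 0L && length(adaptors) > 0L) {
    trimmed <- logical(nrow(reads))
    for (ad in adaptors) {
      hit <- regexpr(ad, reads$seq, fixed = TRUE)
      has <- hit != -1L
      if (any(has)) {
        cut <- as.integer(hit[has]) - 1L
        reads$seq[has] <- substr(reads$seq[has], 1L, cut)
        reads$qual[has] <- substr(reads$qual[has], 1L, cut)
        trimmed <- trimmed | has
      }
    }
    report["n_trimmed_adaptor"] <- sum(trimmed)
  }

  if (nrow(reads) > 0L) {
    lead_t <- attr(regexpr("^T+", reads$seq), "match.length")
    lead_t[lead_t < 0L] <- 0L
    trail_a <- attr(regexpr("A+$", reads$seq), "match.length")
    trail_a[trail_a < 0L] <- 0L
    do_lead <- lead_t >= polyrun
    do_trail <- trail_a >= polyrun
    report["n_trimmed_polyAT"] <- sum(do_lead | do_trail)
    from <- ifelse(do_lead, lead_t + 1L, 1L)
    to <- nchar(reads$seq) - ifelse(do_trail, trail_a, 0L)
    reads$seq <- substr(reads$seq, from, to)
    reads$qual <- substr(reads$qual, from, to)
  }

  if (nrow(reads) > 0L) {
    len2 <- nchar(reads$seq)
    at <- vapply(gregexpr("[ATat]", reads$seq), function(m) {
      if (m[1L] == -1L) 0L else length(m)
    }, integer(1))
    at_fracs <- ifelse(len2 > 0L, at / len2, 1)
    drop_at <- at_fracs > at_frac
    drop_short <- !drop_at & len2 < min_len
    report["n_discarded_AT"] <- sum(drop_at)
    report["n_discarded_short"] <- sum(drop_short)
    reads <- reads[!(drop_at | drop_short), , drop = FALSE]
  }

  report["n_output"] <- nrow(reads)
  rownames(reads) <- NULL
  list(reads = reads, report = structure(as.list(report), class = "qc_report"))
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %d\n", nm, x[[nm]]))
  invisible(x)
}

#' Clean a read pair in sync
#'
#' Runs [clean_reads()] on both mates and drops the mate of every discarded
#' read so the two output files stay synchronized.
#'
#' @param in1,in2 Input FASTQ paths for mate 1 and mate 2.
#' @param out1,out2 Optional output FASTQ paths.
#' @param ... Passed to [clean_reads()].
#' @return List with `reads1`, `reads2` (synchronized surviving reads) and
#'   `report1`, `report2`.
#' @export
clean_read_pairs <- function(in1, in2, out1 = NULL, out2 = NULL, ...) {
  r1 <- clean_reads(in1, outfile = NULL, ...)
  r2 <- clean_reads(in2, outfile = NULL, ...)
  shared <- intersect(r1$reads$id, r2$reads$id)
  k1 <- r1$reads[match(shared, r1$reads$id), , drop = FALSE]
  k2 <- r2$reads[match(shared, r2$reads$id), , drop = FALSE]
  if (!is.null(out1)) write_fastq(k1, out1)
  if (!is.null(out2)) write_fastq(k2, out2)
  list(reads1 = k1, reads2 = k2, report1 = r1$report, report2 = r2$report)
}

write_fastq <- function(reads, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(reads) > 0L) {
    writeLines(as.vector(rbind(paste0("@", reads$id), reads$seq, "+",
                               reads$qual)), con)
  }
  invisible(path)
}

#' Write a QC report as TSV
#'
#' @param report A `qc_report`.
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(
    data.frame(metric = names(report), value = unlist(report)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
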