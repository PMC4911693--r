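# Three-criterion filter for de novo assembled transcript candidates:
# expression (overall RPKM and every replicate above threshold), distance
# from known genes (gene span to transcript span, strand-agnostic), and
# structure (exon count and summed exon length).

#' Filter de novo transcript candidates
#'
#' A candidate survives iff: overall RPKM strictly exceeds `min_rpkm` AND
#' every replicate RPKM strictly exceeds `min_rep_rpkm` (expression); its
#' genomic span is at least `min_dist` nt from the span of every known
#' gene on the same chromosome (distance); and it has at least `min_exons`
#' exons whose summed length strictly exceeds `min_len` nt (structure).
#' Each rejected candidate is tallied under the first criterion it fails,
#' tested in the order expression, distance, structure.
#'
#' @param candidates Data frame with columns `tx_id`, `chrom`, `strand`,
#'   `exons` (comma-separated `start-end` 0-based half-open intervals),
#'   `rpkm_overall`, and `rpkm_reps` (comma-separated per-replicate RPKM).
#' @param known Named list of [gene_model()] objects (known genes).
#' @param min_rpkm Overall RPKM threshold, strict (default 0.5).
#' @param min_rep_rpkm Per-replicate RPKM threshold, strict (default 0.25).
#' @param min_dist Minimum distance to any known gene in nt (default
#'   10000, inclusive: "at least 10 kb").
#' @param min_exons Minimum exon count (default 2, inclusive).
#' @param min_len Summed exon length threshold in nt, strict (default 500).
#' @return List with `kept` (surviving candidates, plus a computed
#'   `nearest_known_distance` column), `rejected` (with a `reason`
#'   column), and `tally` (named counts per first failed criterion).
#' @export
filter_novel <- function(candidates, known, min_rpkm = 0.5,
                         min_rep_rpkm = 0.25, min_dist = 10000,
                         min_exons = 2, min_len = 500) {
  for (v in c(min_rpkm, min_rep_rpkm, min_dist, min_exons, min_len)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("thresholds must be single non-negative numbers")
    }
  }
  spans <- do.call(rbind, lapply(known, function(g) {
    sp <- gene_span(g)
    data.frame(chrom = g$chrom, start = sp[["start"]], end = sp[["end"]],
               stringsAsFactors = FALSE)
  }))
  n <- nrow(candidates)
  reason <- rep(NA_character_, n)
  dist <- rep(Inf, n)
  for (i in seq_len(n)) {
    ex <- parse_exon_string(candidates$exons[i])
    reps <- as.numeric(strsplit(candidates$rpkm_reps[i], ",")[[1L]])
    pass_expr <- candidates$rpkm_overall[i] > min_rpkm &&
      all(reps > min_rep_rpkm)
    if (!is.null(spans)) {
      same <- spans[spans$chrom == candidates$chrom[i], , drop = FALSE]
      if (nrow(same) > 0L) {
        tx_start <- min(ex$start)
        tx_end <- max(ex$end)
        gaps <- pmax(same$start - tx_end, tx_start - same$end, 0)
        dist[i] <- min(gaps)
      }
    }
    pass_dist <- dist[i] >= min_dist
    pass_struct <- nrow(ex) >= min_exons && sum(ex$end - ex$start) > min_len
    if (!pass_expr) reason[i] <- "expression"
    else if (!pass_dist) reason[i] <- "distance"
    else if (!pass_struct) reason[i] <- "structure"
  }
  candidates$nearest_known_distance <- dist
  keep <- is.na(reason)
  kept <- candidates[keep, , drop = FALSE]
  rejected <- candidates[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  rownames(kept) <- rownames(rejected) <- NULL
  tally <- c(expression = sum(reason == "expression", na.rm = TRUE),
             distance = sum(reason == "distance", na.rm = TRUE),
             structure = sum(reason == "structure", na.rm = TRUE))
  list(kept = kept, rejected = rejected, tally = tally)
}

parse_exon_string <- function(s) {
  parts <- strsplit(strsplit(s, ",")[[1L]], "-")
  df <- data.frame(start = as.numeric(vapply(parts, `[`, "", 1L)),
                   end = as.numeric(vapply(parts, `[`, "", 2L)))
  df[order(df$start), , drop = FALSE]
}

#' Read / write novel transcript candidate tables
#'
#' @param path TSV path with the [filter_novel()] candidate columns.
#' @return Data frame of candidates.
#' @export
read_novel_candidates <- function(path) {
  utils::read.delim(path, colClasses = c(
    tx_id = "character", chrom = "character", strand = "character",
    exons = "character", rpkm_overall = "numeric", rpkm_reps = "character"))
}

#' @rdname read_novel_candidates
#' @param candidates Candidate data frame.
#' @export
write_novel_candidates <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
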