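# Independent brute-force oracles. These re-derive expected results from
# first principles, without calling the implementation paths they check.

# Brute-force circRNA caller: tests every read against every exon pair of
# every gene, applies the mate rule and the ambiguity drop, then the
# support filter. Returns a sorted character key set
# "chrom:start:end:gene:from:to:sample:back".
brute_force_circs <- function(reads, genes, tol = 0, min_reads = 2) {
  support <- list()
  for (r in seq_len(nrow(reads))) {
    matches <- list()
    for (g in genes) {
      if (g$chrom != reads$chrom[r]) next
      nex <- nrow(g$exons)
      for (i in seq_len(nex)) {
        for (j in i:nex) {
          if (abs(reads$seg2_start[r] - g$exons$start[i]) > tol) next
          if (abs(reads$seg1_end[r] - g$exons$end[j]) > tol) next
          if (reads$seg1_start[r] < reads$seg2_start[r]) next
          acc <- g$exons$start[i]
          don <- g$exons$end[j]
          if (acc >= don) next
          mc <- reads$mate_chrom[r]
          if (!is.na(mc) && mc != "." && nzchar(mc)) {
            if (mc != reads$chrom[r]) next
            if (!isTRUE(reads$mate_linear[r] == 1)) next
            if (is.na(reads$mate_start[r]) || is.na(reads$mate_end[r])) next
            if (reads$mate_start[r] < acc || reads$mate_end[r] > don) next
          }
          matches[[length(matches) + 1L]] <-
            c(g$gene_id, acc, don, i, j)
        }
      }
    }
    matches <- unique(matches)
    if (length(matches) == 1L) {
      m <- matches[[1L]]
      key <- paste(reads$chrom[r], m[2L], m[3L], m[1L], m[4L], m[5L],
                   reads$sample_id[r], sep = ":")
      support[[key]] <- unique(c(support[[key]], reads$read_id[r]))
    }
  }
  counts <- vapply(support, length, integer(1))
  keep <- counts >= min_reads
  sort(paste0(names(counts)[keep], ":", counts[keep]))
}

circ_table_keys <- function(circs) {
  sort(sprintf("%s:%d:%d:%s:%d:%d:%s:%d", circs$chrom,
               as.integer(circs$start), as.integer(circs$end),
               circs$gene_id, circs$exon_from, circs$exon_to,
               circs$sample_id, circs$back_reads))
}

# Closed-form simple linear regression (no lm/lm.fit).
ols_closed_form <- function(x, y) {
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  c(intercept = b0, slope = b1)
}

# Brute-force novel-transcript criterion re-check (independent of
# filter_novel's implementation; shares only the documented rules).
brute_force_novel <- function(candidates, genes, min_rpkm = 0.5,
                              min_rep_rpkm = 0.25, min_dist = 10000,
                              min_exons = 2, min_len = 500) {
  keep <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    parts <- strsplit(strsplit(candidates$exons[i], ",")[[1L]], "-")
    ss <- as.numeric(sapply(parts, `[`, 1L))
    ee <- as.numeric(sapply(parts, `[`, 2L))
    reps <- as.numeric(strsplit(candidates$rpkm_reps[i], ",")[[1L]])
    ok <- candidates$rpkm_overall[i] > min_rpkm && all(reps > min_rep_rpkm)
    if (ok) {
      for (g in genes) {
        if (g$chrom != candidates$chrom[i]) next
        gs <- min(g$exons$start)
        ge <- max(g$exons$end)
        d <- if (min(ss) > ge) min(ss) - ge
        else if (max(ee) < gs) gs - max(ee)
        else 0
        if (d < min_dist) {
          ok <- FALSE
          break
        }
      }
    }
    ok <- ok && length(ss) >= min_exons && sum(ee - ss) > min_len
    keep[i] <- ok
  }
  keep
}

# Random small circ-calling instance: a few genes plus reads that are
# exact junction reads, jittered ones, cross-gene chimeras and random
# noise, with mates placed inside or outside the circle span.
random_circ_instance <- function(seed, n_genes = 4, n_reads = 300) {
  withr::local_seed(seed)
  genes <- list()
  pos <- 1000
  for (gi in seq_len(n_genes)) {
    n_ex <- sample(3:6, 1L)
    starts <- ends <- numeric(n_ex)
    p <- pos
    for (e in seq_len(n_ex)) {
      starts[e] <- p
      ends[e] <- p + sample(100:250, 1L)
      p <- ends[e] + sample(200:2000, 1L)
    }
    genes[[gi]] <- gene_model(sprintf("g%d", gi), "chr1",
                              sample(c("+", "-"), 1L),
                              data.frame(start = starts, end = ends))
    pos <- p + sample(3000:8000, 1L)
  }
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  reads <- list()
  for (r in seq_len(n_reads)) {
    g <- genes[[sample.int(n_genes, 1L)]]
    nex <- nrow(g$exons)
    i <- sample.int(nex, 1L)
    j <- (i:nex)[sample.int(nex - i + 1L, 1L)]
    jit_a <- sample(c(0L, 0L, 0L, sample(-2:2, 1L)), 1L)
    jit_d <- sample(c(0L, 0L, 0L, sample(-2:2, 1L)), 1L)
    acc <- g$exons$start[i] + jit_a
    don <- g$exons$end[j] + jit_d
    l1 <- sample(30:70, 1L)
    l2 <- 100L - l1
    mate_kind <- sample(c("inside", "outside", "absent"), 1L,
                        prob = c(0.7, 0.2, 0.1))
    span <- don - acc
    if (mate_kind == "inside" && span > 110) {
      ms <- acc + sample.int(span - 105L, 1L)
      me <- ms + 100L
      mchrom <- "chr1"
    } else if (mate_kind == "outside") {
      ms <- don + sample(500:4000, 1L)
      me <- ms + 100L
      mchrom <- "chr1"
    } else {
      ms <- NA_real_
      me <- NA_real_
      mchrom <- "."
    }
    reads[[r]] <- data.frame(
      read_id = sprintf("r%04d", r), sample_id = sample(c("s1", "s2"), 1L),
      chrom = "chr1", seg1_start = don - l1, seg1_end = don,
      seg2_start = acc, seg2_end = acc + l2, strand = g$strand,
      mate_chrom = mchrom, mate_start = ms, mate_end = me,
      mate_linear = 1, stringsAsFactors = FALSE)
  }
  list(genes = genes, reads = do.call(rbind, reads))
}
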