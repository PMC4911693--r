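# Readers and writers for every on-disk format the pipeline touches.
#
# All internal coordinates are 0-based half-open. GTF (1-based inclusive)
# and BED (already 0-based half-open) are converted at the boundary, so
# interval arithmetic inside the package never needs off-by-one fixes.

#' Construct a gene model
#'
#' A gene model is the coordinate frame for junction annotation and feature
#' extraction: a gene's ordered exon intervals on one chromosome and strand.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column data frame (`start`, `end`) of 0-based half-open
#'   exon intervals, sorted by genomic start and non-overlapping.
#' @param known Logical; `FALSE` for de novo (novel) gene models.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, known = TRUE) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons$start <- as.numeric(exons$start)
  exons$end <- as.numeric(exons$end)
  if (nrow(exons) == 0L) stop("gene model needs at least one exon")
  if (any(exons$end <= exons$start)) {
    stop(sprintf("gene %s: exon end must exceed start", gene_id))
  }
  exons <- exons[order(exons$start, exons$end), , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)])) {
    stop(sprintf("gene %s: exons overlap", gene_id))
  }
  structure(
    list(gene_id = as.character(gene_id), chrom = as.character(chrom),
         strand = strand, exons = exons, known = isTRUE(known)),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%s [%d exon%s]%s\n", x$gene_id, x$chrom,
              x$strand, nrow(x$exons), if (nrow(x$exons) == 1L) "" else "s",
              if (x$known) "" else " (novel)"))
  invisible(x)
}

# Introns of a gene model, in genomic order (0-based half-open).
gene_introns <- function(gene) {
  ex <- gene$exons
  if (nrow(ex) < 2L) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1L])
}

gene_span <- function(gene) {
  c(start = min(gene$exons$start), end = max(gene$exons$end))
}

#' Read a gene annotation from GTF
#'
#' Exon records are grouped by `gene_id` and merged into one non-redundant
#' exon chain per gene (overlapping exons from multiple transcripts are
#' unioned). GTF 1-based inclusive coordinates are converted to the internal
#' 0-based half-open convention.
#'
#' @param path Path to a GTF file.
#' @param known Logical flag stored on every returned model.
#' @return Named list of [gene_model()] objects, ordered by gene id.
#' @export
read_gtf <- function(path, known = TRUE) {
  if (!file.exists(path)) stop(sprintf("GTF file not found: %s", path))
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  for (i in body) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L) {
      stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields, got %d",
                   i, length(f)))
    }
    s <- suppressWarnings(as.numeric(f[4L]))
    e <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(s) || is.na(e)) {
      stop(sprintf("malformed GTF line %d: non-numeric coordinates", i))
    }
    if (e < s) {
      stop(sprintf("coordinate error at GTF line %d: end (%s) before start (%s)",
                   i, f[5L], f[4L]))
    }
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) return(structure(list(), names = character(0)))
  ids <- as.character(gr$gene_id)
  out <- lapply(split(seq_along(gr), ids), function(idx) {
    sub <- gr[idx]
    merged <- IRanges::reduce(IRanges::ranges(sub))
    gene_model(
      gene_id = ids[idx[1L]],
      chrom = as.character(GenomicRanges::seqnames(sub))[1L],
      strand = as.character(BiocGenerics::strand(sub))[1L],
      exons = data.frame(start = BiocGenerics::start(merged) - 1L,
                         end = BiocGenerics::end(merged)),
      known = known
    )
  })
  out[order(names(out))]
}

#' Write gene models to GTF
#'
#' @param genes Named list of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  lines <- unlist(lapply(genes, function(g) {
    sprintf('%s\tembryocirc\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            g$chrom, as.integer(g$exons$start) + 1L, as.integer(g$exons$end),
            g$strand, g$gene_id, g$gene_id)
  }), use.names = FALSE)
  writeLines(lines %||% character(0), path)
  invisible(path)
}

#' Read chimeric-segment alignments
#'
#' Reads the tab-separated chimeric dialect used by this package as a
#' stand-in for a fusion-capable aligner's output: one row per read pair
#' whose first mate aligned in two segments. Records whose two segments fall
#' on different chromosomes (trans-chromosomal events, outside the exonic
#' circRNA scope) are skipped; the number skipped is attached as attribute
#' `n_skipped` and raised as a warning.
#'
#' Columns: `read_id, sample_id, chrom, seg1_start, seg1_end, seg2_start,
#' seg2_end, strand, mate_chrom, mate_start, mate_end, mate_linear`.
#' Coordinates are 0-based half-open; a missing mate is encoded as
#' `mate_chrom = "."`.
#'
#' @param path Path to the TSV file.
#' @return Data frame of chimeric read pairs with attribute `n_skipped`.
#' @export
read_chimeric <- function(path) {
  if (!file.exists(path)) stop(sprintf("chimeric file not found: %s", path))
  cols <- c("read_id", "sample_id", "chrom", "seg1_start", "seg1_end",
            "seg2_start", "seg2_end", "strand", "mate_chrom", "mate_start",
            "mate_end", "mate_linear")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("chimeric table schema error: missing column(s) %s",
                 paste(missing, collapse = ", ")))
  }
  df <- df[, cols, drop = FALSE]
  for (nm in c("seg1_start", "seg1_end", "seg2_start", "seg2_end",
               "mate_start", "mate_end", "mate_linear")) {
    df[[nm]] <- suppressWarnings(as.numeric(df[[nm]]))
  }
  # The dialect carries one `chrom` field for both segments; a
  # trans-chromosomal event is encoded as "chromA|chromB" (or with a
  # comma).  Such records are outside the exonic-circRNA scope and are
  # skipped, not errored.  A trans-chromosomal MATE is legal here; the
  # caller's pair-end check rejects it downstream.
  n0 <- nrow(df)
  if (n0 > 0L) {
    df <- df[!grepl("[|,]", df$chrom), , drop = FALSE]
  }
  n_skipped <- n0 - nrow(df)
  if (n_skipped > 0L) {
    warning(sprintf("skipped %d trans-chromosomal chimeric record(s)", n_skipped))
  }
  rownames(df) <- NULL
  attr(df, "n_skipped") <- n_skipped
  df
}

#' Write chimeric-segment alignments
#'
#' @param df Data frame in the layout documented in [read_chimeric()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chimeric <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a count table
#'
#' Carries unique-read counts per feature (genes plus spike-ins) per sample,
#' with the per-sample sequencing metadata needed for RPKM.
#'
#' @param counts Integer matrix, features x samples.
#' @param total_mapped_reads Named numeric vector, one positive total per
#'   sample.
#' @param read_length Named numeric vector (or scalar) of read length in nt.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, total_mapped_reads, read_length) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have feature rownames and sample colnames")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (length(read_length) == 1L) {
    read_length <- stats::setNames(rep(read_length, ncol(counts)), colnames(counts))
  }
  total_mapped_reads <- total_mapped_reads[colnames(counts)]
  read_length <- read_length[colnames(counts)]
  if (any(is.na(total_mapped_reads)) || any(total_mapped_reads <= 0)) {
    stop("every sample needs a positive total_mapped_reads")
  }
  if (any(is.na(read_length)) || any(read_length <= 0)) {
    stop("every sample needs a positive read_length")
  }
  structure(list(counts = counts, total_mapped_reads = total_mapped_reads,
                 read_length = read_length),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Read a count table and its sample metadata sidecar
#'
#' @param path TSV with column `feature_id` then one column per sample.
#' @param meta_path TSV with columns `sample_id`, `total_mapped_reads`,
#'   `read_length`.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, meta_path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (names(df)[1L] != "feature_id") stop("count table must start with feature_id")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$feature_id
  storage.mode(m) <- "double"
  meta <- utils::read.delim(meta_path)
  count_table(m,
              stats::setNames(meta$total_mapped_reads, meta$sample_id),
              stats::setNames(meta$read_length, meta$sample_id))
}

#' Write a count table and its sample metadata sidecar
#'
#' @param ct A [count_table()].
#' @param path Output TSV for the counts.
#' @param meta_path Output TSV for the per-sample metadata.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(ct, path, meta_path) {
  df <- data.frame(feature_id = rownames(ct$counts), ct$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = colnames(ct$counts),
                     total_mapped_reads = as.numeric(ct$total_mapped_reads),
                     read_length = as.numeric(ct$read_length))
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a spike-in panel description
#'
#' Columns: `species_id, class, amount, amount_unit, length, polyA_len`.
#' `class` is `ERCC` (dilution panel, amounts in attomole per lysis
#' reaction) or `RGC` (three-species long-polyA mix, amounts in molecules
#' per reaction).
#'
#' @param path TSV path.
#' @return Data frame of spike-in species.
#' @export
read_spikein_panel <- function(path) {
  df <- utils::read.delim(path, colClasses = c(
    species_id = "character", class = "character", amount = "numeric",
    amount_unit = "character", length = "numeric", polyA_len = "numeric"))
  validate_spikein_panel(df)
  df
}

validate_spikein_panel <- function(df) {
  need <- c("species_id", "class", "amount", "amount_unit", "length",
            "polyA_len")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("spike-in panel missing column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  if (any(df$amount <= 0)) stop("spike-in amounts must be positive")
  if (!all(df$class %in% c("ERCC", "RGC"))) {
    stop("spike-in class must be ERCC or RGC")
  }
  n_rgc <- sum(df$class == "RGC")
  if (n_rgc > 0L && n_rgc != 3L) {
    stop("the RGC mix must contain exactly three species")
  }
  invisible(df)
}

#' @rdname read_spikein_panel
#' @param df Panel data frame.
#' @export
write_spikein_panel <- function(df, path) {
  validate_spikein_panel(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

circ_table_cols <- c("chrom", "start", "end", "strand", "gene_id",
                     "exon_from", "exon_to", "sample_id", "back_reads",
                     "fwd_acceptor", "fwd_donor", "exon_position_class",
                     "upstream_evidence")

#' Write / read the annotated circRNA table
#'
#' A BED-dialect table (0-based half-open, header line retained) with one
#' row per circRNA per sample: the canonical genomic key of the circle
#' (`chrom`, `start` = acceptor boundary, `end` = donor boundary, `strand`),
#' the hosting gene and spanned exon ordinals (genomic order), and junction
#' read counts (back-spliced, plus forward-spliced at the acceptor and donor
#' loci). Re-reading a written table reproduces the records exactly.
#'
#' @param records Data frame of circRNA records.
#' @param path File path.
#' @return `path` (writer) or the records data frame (reader).
#' @export
write_circ_table <- function(records, path) {
  records <- as.data.frame(records)
  for (nm in setdiff(circ_table_cols, names(records))) {
    records[[nm]] <- if (nm == "upstream_evidence") NA else NA_character_
  }
  records <- records[, circ_table_cols, drop = FALSE]
  for (nm in c("start", "end", "exon_from", "exon_to", "back_reads",
               "fwd_acceptor", "fwd_donor")) {
    records[[nm]] <- as.integer(records[[nm]])
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_circ_table
#' @export
read_circ_table <- function(path) {
  df <- utils::read.delim(path, colClasses = c(
    chrom = "character", start = "integer", end = "integer",
    strand = "character", gene_id = "character", exon_from = "integer",
    exon_to = "integer", sample_id = "character", back_reads = "integer",
    fwd_acceptor = "integer", fwd_donor = "integer",
    exon_position_class = "character", upstream_evidence = "logical"))
  df
}

#' Read a BED file of repeat annotations
#'
#' @param path BED path (at least 3 columns; name taken from column 4 when
#'   present).
#' @return Data frame with `chrom`, `start`, `end` (0-based half-open) and
#'   `name`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             name = if (!is.null(gr$name)) as.character(gr$name) else ".",
             stringsAsFactors = FALSE)
}

#' @rdname read_bed
#' @param df Data frame with `chrom`, `start`, `end` and optionally `name`.
#' @export
write_bed <- function(df, path) {
  name <- if ("name" %in% names(df)) df$name else "."
  lines <- sprintf("%s\t%d\t%d\t%s", df$chrom, as.integer(df$start),
                   as.integer(df$end), name)
  writeLines(lines, path)
  invisible(path)
}
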