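# Shared in-code fixtures.

# A five-exon plus-strand gene and a four-exon minus-strand gene.
fixture_genes <- function() {
  gplus <- gene_model("GPLUS", "chr1", "+", data.frame(
    start = c(100, 500, 900, 1400, 2000),
    end = c(200, 650, 1000, 1500, 2150)))
  gminus <- gene_model("GMINUS", "chr2", "-", data.frame(
    start = c(300, 800, 1300, 1900),
    end = c(420, 950, 1450, 2050)))
  # second chr1 gene: lets tests build chimeras spanning two genes
  gsecond <- gene_model("GSECOND", "chr1", "+", data.frame(
    start = c(300, 4500, 5000),
    end = c(420, 4600, 5100)))
  list(GPLUS = gplus, GMINUS = gminus, GSECOND = gsecond)
}

# One chimeric read row in the dialect layout.
chim_row <- function(read_id, sample_id, chrom, seg1, seg2, mate = NULL,
                     strand = "+", mate_linear = 1) {
  data.frame(read_id = read_id, sample_id = sample_id, chrom = chrom,
             seg1_start = seg1[1L], seg1_end = seg1[2L],
             seg2_start = seg2[1L], seg2_end = seg2[2L], strand = strand,
             mate_chrom = if (is.null(mate)) "." else mate$chrom,
             mate_start = if (is.null(mate)) NA_real_ else mate$start,
             mate_end = if (is.null(mate)) NA_real_ else mate$end,
             mate_linear = mate_linear, stringsAsFactors = FALSE)
}

write_tmp_fastq <- function(ids, seqs, quals) {
  path <- withr::local_tempfile(fileext = ".fastq",
                                .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}

q_string <- function(scores) {
  intToUtf8(scores + 33L, multiple = FALSE)
}

# Tiny simulation config for fast end-to-end tests.
small_sim_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_genes = 40, n_circ_hosting = 8,
             n_replicates = 1, depth = 1e5, junction_depth = 40, ...)
}
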