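test_that("GTF coordinates convert to 0-based half-open and exons group per gene", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "gA"; transcript_id "gA.1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "gA"; transcript_id "gA.1";',
    'chr2\tsrc\texon\t51\t90\t.\t-\t.\tgene_id "gB"; transcript_id "gB.1";'),
    path)
  genes <- read_gtf(path)
  expect_named(genes, c("gA", "gB"))
  expect_equal(genes$gA$exons$start, c(100, 300))
  expect_equal(genes$gA$exons$end, c(200, 400))
  expect_equal(genes$gB$strand, "-")
  expect_equal(genes$gB$exons$start, 50)
})

test_that("malformed GTF lines are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "gA";',
    "chr1\tbroken line"), path)
  expect_error(read_gtf(path), "line 2")

  path2 <- withr::local_tempfile(fileext = ".gtf")
  writeLines('chr1\tsrc\texon\t500\t400\t.\t+\t.\tgene_id "gA";', path2)
  expect_error(read_gtf(path2), "coordinate error.*line 1")
})

test_that("GTF round-trip through write_gtf/read_gtf is the identity", {
  genes <- fixture_genes()
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(genes, path)
  back <- read_gtf(path)
  expect_equal(back$GPLUS$exons, genes$GPLUS$exons)
  expect_equal(back$GMINUS$exons, genes$GMINUS$exons)
  expect_equal(back$GMINUS$strand, "-")
})

test_that("gene_model enforces its invariants", {
  expect_error(gene_model("g", "chr1", "+",
                          data.frame(start = 10, end = 10)),
               "exceed")
  expect_error(gene_model("g", "chr1", "*",
                          data.frame(start = 10, end = 20)), "strand")
  expect_error(gene_model("g", "chr1", "+",
                          data.frame(start = c(10, 15), end = c(20, 30))),
               "overlap")
  g <- gene_model("g", "chr1", "+",
                  data.frame(start = c(50, 10), end = c(60, 20)))
  expect_equal(g$exons$start, c(10, 50))
})

test_that("chimeric table round-trips, skips mixed-chromosome records, handles empty files", {
  df <- rbind(
    chim_row("r1", "s1", "chr1", c(900, 960), c(500, 540),
             mate = list(chrom = "chr1", start = 600, end = 700)),
    chim_row("r2", "s1", "chr1", c(900, 960), c(500, 540)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_chimeric(df, path)
  back <- read_chimeric(path)
  expect_equal(attr(back, "n_skipped"), 0L)
  attr(back, "n_skipped") <- NULL
  expect_equal(back, df, ignore_attr = TRUE)
  expect_true(back$mate_linear[1] == 1)

  mixed <- df
  mixed$chrom[2] <- "chr1|chr2"
  write_chimeric(mixed, path)
  expect_warning(back2 <- read_chimeric(path), "trans-chromosomal")
  expect_equal(nrow(back2), 1L)
  expect_equal(attr(back2, "n_skipped"), 1L)

  write_chimeric(df[0, ], path)
  empty <- read_chimeric(path)
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "n_skipped"), 0L)

  bad <- df
  names(bad)[3] <- "chr"
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_chimeric(path), "schema.*chrom")
})

test_that("circRNA table write/read is bit-exact, including zero counts and empty tables", {
  rec <- data.frame(
    chrom = c("chr1", "chr1"), start = c(500L, 500L), end = c(1000L, 1000L),
    strand = "+", gene_id = "GPLUS", exon_from = 2L, exon_to = 3L,
    sample_id = c("s1", "s2"), back_reads = c(3L, 2L),
    fwd_acceptor = c(5L, 0L), fwd_donor = c(7L, 0L),
    exon_position_class = "internal", upstream_evidence = FALSE,
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".bed")
  write_circ_table(rec, path)
  expect_identical(read_circ_table(path), rec)
  # zero forward reads serialized explicitly
  expect_true(any(grepl("\t0\t0\t", readLines(path))))

  write_circ_table(rec[0, ], path)
  lines <- readLines(path)
  expect_length(lines, 1L)  # header only
  expect_equal(nrow(read_circ_table(path)), 0L)
})

test_that("count table round-trips with its metadata sidecar and validates inputs", {
  m <- matrix(c(0L, 5L, 10L, 2L), 2,
              dimnames = list(c("gA", "gB"), c("s1", "s2")))
  ct <- count_table(m, c(s1 = 1e6, s2 = 2e6), 100)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(ct, p1, p2)
  back <- read_count_table(p1, p2)
  expect_equal(back$counts, ct$counts)
  expect_equal(back$total_mapped_reads, ct$total_mapped_reads)
  expect_equal(unname(back$read_length), c(100, 100))

  expect_error(count_table(matrix(-1, dimnames = list("g", "s")),
                           c(s = 1), 100), "non-negative")
  expect_error(count_table(m, c(s1 = 0, s2 = 1e6), 100), "positive")
})

test_that("spike-in panel validates class and the three-species RGC mix", {
  panel <- data.frame(
    species_id = c("E1", "E2", "E3", "RGC-RFP", "RGC-GFP", "RGC-CRE"),
    class = c(rep("ERCC", 3), rep("RGC", 3)),
    amount = c(1, 0.1, 0.01, 1e6, 1e5, 1e4),
    amount_unit = c(rep("attomole", 3), rep("molecules", 3)),
    length = c(500, 700, 900, 1000, 800, 1200),
    polyA_len = c(20, 20, 20, 80, 80, 80), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spikein_panel(panel, path)
  expect_equal(read_spikein_panel(path), panel)
  expect_error(write_spikein_panel(panel[-4, ], path), "three species")
  bad <- panel
  bad$amount[1] <- 0
  expect_error(write_spikein_panel(bad, path), "positive")
})

test_that("BED round-trip preserves 0-based half-open intervals", {
  df <- data.frame(chrom = "chr1", start = c(0L, 150L), end = c(100L, 400L),
                   name = "Alu_synth", stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(df, path)
  expect_equal(read_bed(path), df)
})
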