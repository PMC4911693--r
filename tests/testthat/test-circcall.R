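# GPLUS exons (0-based): 1:[100,200) 2:[500,650) 3:[900,1000) 4:[1400,1500)
# 5:[2000,2150)

test_that("a back-splice read joining exon 3's end to exon 2's start is annotated", {
  genes <- fixture_genes()
  reads <- rbind(
    # donor piece first (end of exon 3), acceptor piece second, mate in exon 2
    chim_row("r1", "s1", "chr1", c(940, 1000), c(500, 540),
             mate = list(chrom = "chr1", start = 520, end = 620)),
    # boundary off by one nt: rejected at tol = 0
    chim_row("r2", "s1", "chr1", c(940, 1001), c(500, 540),
             mate = list(chrom = "chr1", start = 520, end = 620)),
    # mate 5 kb downstream of the donor exon: rejected
    chim_row("r3", "s1", "chr1", c(940, 1000), c(500, 540),
             mate = list(chrom = "chr1", start = 6000, end = 6100)),
    # mate on another chromosome: rejected
    chim_row("r4", "s1", "chr1", c(940, 1000), c(500, 540),
             mate = list(chrom = "chr2", start = 520, end = 620)),
    # segments matching exons of two different genes: no same-gene pair
    chim_row("r5", "s1", "chr1", c(940, 1000), c(300, 340)),
    # absent mate is acceptable
    chim_row("r6", "s1", "chr1", c(940, 1000), c(500, 540)))
  cand <- annotate_backsplices(reads, genes, tol = 0)
  expect_setequal(cand$read_id, c("r1", "r6"))
  expect_equal(unique(cand$gene_id), "GPLUS")
  expect_equal(unique(cand$start), 500)
  expect_equal(unique(cand$end), 1000)
  expect_equal(unique(cand$exon_from), 2L)
  expect_equal(unique(cand$exon_to), 3L)
  d <- attr(cand, "diagnostics")
  expect_equal(unname(d["n_mate_rejected"]), 2L)
  expect_true(d["n_no_match"] >= 2L)
  expect_error(annotate_backsplices(reads, genes, tol = -1), "non-negative")
})

test_that("the support filter keeps junctions per sample at the read-depth threshold", {
  genes <- fixture_genes()
  mk <- function(id, sample) {
    chim_row(id, sample, "chr1", c(940, 1000), c(500, 540))
  }
  reads <- rbind(mk("a1", "sA"),
                 mk("b1", "sB"), mk("b2", "sB"), mk("b3", "sB"),
                 mk("c1", "sC"), mk("c2", "sC"),
                 mk("c2", "sC"))  # duplicated read id counted once
  cand <- annotate_backsplices(reads, genes)
  circs <- filter_support(cand, min_reads = 2)
  expect_setequal(circs$sample_id, c("sB", "sC"))
  expect_equal(circs$back_reads[circs$sample_id == "sB"], 3L)
  expect_equal(circs$back_reads[circs$sample_id == "sC"], 2L)
  all_in <- filter_support(cand, min_reads = 1)
  expect_setequal(all_in$sample_id, c("sA", "sB", "sC"))
  expect_error(filter_support(cand, min_reads = 0), ">= 1")
})

test_that("exon-position classes follow transcript orientation on both strands", {
  genes <- fixture_genes()
  circs <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(500, 100, 1400, 800, 300),
    end = c(1500, 650, 2150, 1450, 950),
    strand = c("+", "+", "+", "-", "-"),
    gene_id = c("GPLUS", "GPLUS", "GPLUS", "GMINUS", "GMINUS"),
    exon_from = c(2L, 1L, 4L, 2L, 1L),
    exon_to = c(4L, 2L, 5L, 3L, 2L),
    sample_id = "s1", back_reads = 2L, stringsAsFactors = FALSE)
  cov <- list(GPLUS = rep(3, 1000))
  out <- classify_exon_position(circs, genes, upstream_coverage = cov)
  # plus strand: genomic first exon = transcript first
  expect_equal(out$exon_position_class,
               c("internal", "first_exon", "last_exon",
                 "internal", "last_exon"))
  expect_equal(out$upstream_evidence, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  # minus strand: transcript-first exon is the genomically last one
  circs_m <- circs[4, ]
  circs_m$exon_from <- 3L
  circs_m$exon_to <- 4L
  circs_m$start <- 1300
  circs_m$end <- 2050
  out_m <- classify_exon_position(circs_m, genes)
  expect_equal(out_m$exon_position_class, "first_exon")
  bad <- circs[1, ]
  bad$exon_to <- 9L
  expect_error(classify_exon_position(bad, genes), "not found")
})

test_that("caller equals the brute-force enumerator on random small instances", {
  for (seed in 1:12) {
    inst <- random_circ_instance(seed)
    cand <- annotate_backsplices(inst$reads, inst$genes, tol = 0)
    circs <- filter_support(cand, min_reads = 2)
    expect_identical(circ_table_keys(circs),
                     brute_force_circs(inst$reads, inst$genes, tol = 0),
                     label = sprintf("instance seed %d", seed))
    expect_true(all(circs$back_reads >= 2))
  }
})

test_that("the circRNA set is invariant under reverse-complementing the locus", {
  inst <- random_circ_instance(99)
  L <- 1e6
  flip_iv <- function(s, e) c(L - e, L - s)
  genes_f <- lapply(inst$genes, function(g) {
    iv <- flip_iv(g$exons$start, g$exons$end)
    ex <- data.frame(start = L - g$exons$end, end = L - g$exons$start)
    gene_model(g$gene_id, g$chrom, if (g$strand == "+") "-" else "+", ex)
  })
  r <- inst$reads
  reads_f <- r
  # a segment [s,e) maps to [L-e, L-s); the downstream piece of the
  # original becomes the upstream piece of the flipped read, so seg1/seg2
  # swap roles to preserve back-spliced order
  reads_f$seg1_start <- L - r$seg2_end
  reads_f$seg1_end <- L - r$seg2_start
  reads_f$seg2_start <- L - r$seg1_end
  reads_f$seg2_end <- L - r$seg1_start
  reads_f$mate_start <- L - r$mate_end
  reads_f$mate_end <- L - r$mate_start
  circs <- filter_support(annotate_backsplices(r, inst$genes), 2)
  circs_f <- filter_support(annotate_backsplices(reads_f, genes_f), 2)
  key <- function(d, flip) {
    s <- if (flip) L - d$end else d$start
    e <- if (flip) L - d$start else d$end
    sort(sprintf("%s:%d:%d:%s:%s:%d", d$chrom, as.integer(s),
                 as.integer(e), d$gene_id, d$sample_id, d$back_reads))
  }
  expect_identical(key(circs_f, TRUE), key(circs, FALSE))
})
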