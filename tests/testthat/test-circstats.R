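test_that("junction metrics define the circ ratio and CLR exactly", {
  m <- junction_metrics(c(1, 0, 0, 5), c(9, 5, 0, 0))
  expect_equal(m$circ_ratio, c(0.1, 0, NA, 1))
  expect_equal(m$clr, c(1 / 9, 0, NA, NA))
  expect_equal(m$clr_infinite, c(FALSE, FALSE, FALSE, TRUE))
  expect_error(junction_metrics(-1, 2), "non-negative")
})

test_that("CLR equals ratio/(1-ratio) wherever both are defined", {
  withr::local_seed(7)
  back <- rpois(500, 5)
  fwd <- rpois(500, 20)
  m <- junction_metrics(back, fwd)
  ok <- !is.na(m$clr) & m$circ_ratio < 1
  expect_equal(m$clr[ok], m$circ_ratio[ok] / (1 - m$circ_ratio[ok]),
               tolerance = 1e-12)
})

test_that("simulated junction ratios land inside the exact binomial interval", {
  # at depth 200, the estimate back/200 should fall in the central exact
  # 95 % band of Binomial(200, r) in at least ~95 % of replicates
  depth <- 200
  n_rep <- 500
  for (r in c(0.05, 0.10, 0.25)) {
    withr::local_seed(round(1000 * r))
    lo <- qbinom(0.025, depth, r) / depth
    hi <- qbinom(0.975, depth, r) / depth
    back <- rbinom(n_rep, depth, r)
    est <- junction_metrics(back, depth - back)$circ_ratio
    expect_gte(mean(est >= lo & est <= hi), 0.93)
  }
})

test_that("discounting removes the circular fraction from hosting-gene RPKM", {
  expect_equal(discounted_rpkm(10, 0.25), 7.5)
  expect_equal(discounted_rpkm(10, 0), 10)
  expect_equal(discounted_rpkm(10, 1), 0)
  expect_error(discounted_rpkm(10, 1.2), "\\[0, 1\\]")
})

test_that("flanking introns, exon counts, and hot-spot genes are read off the gene model", {
  genes <- fixture_genes()
  # GPLUS introns: [200,500) [650,900) [1000,1400) [1500,2000)
  circs <- data.frame(
    chrom = "chr1", start = c(500, 500, 900), end = c(1000, 1500, 1000),
    strand = "+", gene_id = "GPLUS",
    exon_from = c(2L, 2L, 3L), exon_to = c(3L, 4L, 3L),
    sample_id = "s1", back_reads = 2L, stringsAsFactors = FALSE)
  ff <- flanking_features(circs, genes)
  pc <- ff$per_circ
  i <- which(pc$exon_from == 2 & pc$exon_to == 3)
  expect_equal(pc$upstream_intron_len[i], 300)    # intron 1
  expect_equal(pc$downstream_intron_len[i], 400)  # intron 3
  expect_equal(pc$n_exons[i], 2L)
  expect_equal(pc$total_exon_len[i], 150 + 100)
  expect_equal(pc$n_exons[pc$exon_from == 3 & pc$exon_to == 3], 1L)
  expect_equal(ff$per_gene$n_isoforms[ff$per_gene$gene_id == "GPLUS"], 3L)
  expect_true(ff$per_gene$hotspot[ff$per_gene$gene_id == "GPLUS"])

  # minus strand: upstream flanking intron is genomically to the right
  circs_m <- data.frame(chrom = "chr2", start = 800, end = 1450,
                        strand = "-", gene_id = "GMINUS", exon_from = 2L,
                        exon_to = 3L, sample_id = "s1", back_reads = 2L,
                        stringsAsFactors = FALSE)
  pm <- flanking_features(circs_m, genes)$per_circ
  # GMINUS introns: [420,800) [950,1300) [1450,1900)
  expect_equal(pm$upstream_intron_len, 450)
  expect_equal(pm$downstream_intron_len, 380)

  # terminal circle lacks one flanking intron
  circs_t <- circs[1, ]
  circs_t$exon_from <- 1L
  circs_t$start <- 100
  pt <- flanking_features(circs_t, genes)$per_circ
  expect_true(is.na(pt$upstream_intron_len))
})

test_that("flanking-feature intron lengths match a brute-force recomputation on simulated data", {
  cfg <- small_sim_config(seed = 12)
  ann <- simulate_annotation(cfg)
  sim <- suppressWarnings(simulate_embryo_series(cfg, ann))
  circs <- filter_support(annotate_backsplices(sim$chimeric, ann$genes), 2)
  ff <- flanking_features(circs, ann$genes)
  for (i in seq_len(nrow(ff$per_circ))) {
    g <- ann$genes[[ff$per_circ$gene_id[i]]]
    ef <- ff$per_circ$exon_from[i]
    et <- ff$per_circ$exon_to[i]
    left <- if (ef > 1) g$exons$start[ef] - g$exons$end[ef - 1] else NA
    right <- if (et < nrow(g$exons)) g$exons$start[et + 1] - g$exons$end[et]
    else NA
    exp_up <- if (g$strand == "+") left else right
    exp_down <- if (g$strand == "+") right else left
    expect_equal(ff$per_circ$upstream_intron_len[i], exp_up)
    expect_equal(ff$per_circ$downstream_intron_len[i], exp_down)
  }
  med_up <- median(ff$per_circ$upstream_intron_len, na.rm = TRUE)
  truth_flank <- ann$introns[ann$introns$is_flanking, ]
  truth_other <- ann$introns[!ann$introns$is_flanking, ]
  # flanking introns were lengthened by the configured multiplier
  expect_gt(median(truth_flank$end - truth_flank$start),
            2 * median(truth_other$end - truth_other$start))
  expect_gt(med_up, median(truth_other$end - truth_other$start))
})

test_that("repeat counting intersects intervals and detects enrichment", {
  introns <- data.frame(chrom = "chr1", start = c(0, 5000),
                        end = c(1000, 6000))
  reps <- data.frame(chrom = "chr1", start = c(100, 500, 2000),
                     end = c(400, 600, 2300), name = "rep")
  res <- alu_enrichment(introns, introns, reps)
  expect_equal(res$flank_counts, c(2, 0))
  expect_equal(res$flank_density, c(2, 0))
  expect_gt(res$p_value, 0.9)  # identical sets: null
  expect_error(alu_enrichment(introns, introns[0, ], reps), "empty")

  # seeded synthetic: flanking repeat rate 4x control, 200 introns/group
  withr::local_seed(88)
  n <- 200
  mk_introns <- function(rate) {
    starts <- seq(0, by = 10000, length.out = n)
    counts <- rpois(n, rate)
    list(introns = data.frame(chrom = "chrX", start = starts,
                              end = starts + 5000),
         reps = do.call(rbind, lapply(seq_len(n), function(i) {
           if (counts[i] == 0) return(NULL)
           s <- starts[i] + sample.int(4700, counts[i], replace = TRUE)
           data.frame(chrom = "chrX", start = s, end = s + 300,
                      name = "rep")
         })))
  }
  fl <- mk_introns(8)
  ct <- mk_introns(2)
  ct$introns$chrom <- "chrY"
  ct$reps$chrom <- "chrY"
  res2 <- alu_enrichment(fl$introns, ct$introns,
                         rbind(fl$reps, ct$reps))
  expect_lt(res2$p_value, 0.01)
  expect_gt(res2$median_flank, res2$median_control)
})

test_that("control introns are sampled from expressed non-hosting genes, reproducibly", {
  genes <- fixture_genes()
  rpkm <- matrix(c(5, 5, 0.2), 3, 1,
                 dimnames = list(c("GPLUS", "GMINUS", "GSECOND"), "s1"))
  ctrl <- sample_control_introns(genes, hosting_genes = "GPLUS", n = 3,
                                 seed = 4, rpkm = rpkm)
  expect_equal(nrow(ctrl), 3)
  expect_true(all(ctrl$chrom == "chr2"))  # only GMINUS qualifies
  expect_identical(ctrl, sample_control_introns(genes, "GPLUS", 3, 4,
                                                rpkm = rpkm))
  expect_error(sample_control_introns(genes, c("GPLUS", "GMINUS"), 3, 4,
                                      rpkm = rpkm), "no control")
})
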