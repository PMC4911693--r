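make_panel <- function(ercc_amounts, ercc_lengths = NULL) {
  n <- length(ercc_amounts)
  if (is.null(ercc_lengths)) ercc_lengths <- rep(1000, n)
  rbind(
    data.frame(species_id = sprintf("E%02d", seq_len(n)), class = "ERCC",
               amount = ercc_amounts, amount_unit = "attomole",
               length = ercc_lengths, polyA_len = 20,
               stringsAsFactors = FALSE),
    data.frame(species_id = c("RFP", "GFP", "CRE"), class = "RGC",
               amount = c(1e6, 1e5, 1e4), amount_unit = "molecules",
               length = c(1000, 800, 1200), polyA_len = 80,
               stringsAsFactors = FALSE))
}

test_that("RPKM follows the count/(kb x millions) formula and flags bad lengths", {
  m <- matrix(c(10L, 0L), 2, 1, dimnames = list(c("gA", "gB"), "s1"))
  ct <- count_table(m, c(s1 = 1e6), 100)
  r <- compute_rpkm(ct, c(gA = 1000, gB = 500))
  expect_equal(r["gA", "s1"], 10)
  expect_equal(r["gB", "s1"], 0)
  expect_error(compute_rpkm(ct, c(gA = 1000)), "gB")
  expect_error(compute_rpkm(ct, c(gA = 1000, gB = 0)), "gB")
})

test_that("an exact ERCC line recovers 1 attomole as 602,214 molecules", {
  amounts <- c(0.01, 0.1, 1, 10)
  panel <- make_panel(amounts)
  ercc_rpkm <- stats::setNames(10 * amounts, sprintf("E%02d", 1:4))
  gene_rpkm <- c(gA = 4, gB = 6)  # sums to RPKM 10 -> 1 attomole
  est <- ercc_total_copies(ercc_rpkm, panel, gene_rpkm)
  expect_equal(est$slope, 1, tolerance = 1e-12)
  expect_equal(est$copies, 602214, tolerance = 1e-9)

  low <- make_panel(c(1e-4, 5e-4, 1e-3))
  low_rpkm <- stats::setNames(10 * low$amount[1:3], sprintf("E%02d", 1:3))
  expect_error(ercc_total_copies(low_rpkm, low, gene_rpkm), "usable ERCC")
})

test_that("the ERCC fit matches a closed-form least-squares oracle on noisy data", {
  withr::local_seed(31)
  amounts <- 10^seq(-2, 1, length.out = 20)
  panel <- make_panel(amounts)
  rpkm <- 10^(log10(50 * amounts) + rnorm(20, 0, 0.1))
  names(rpkm) <- sprintf("E%02d", 1:20)
  est <- ercc_total_copies(rpkm, panel, c(gA = 5))
  oracle <- ols_closed_form(log10(amounts), log10(rpkm))
  expect_equal(est$slope, unname(oracle["slope"]), tolerance = 1e-9)
  expect_equal(est$intercept, unname(oracle["intercept"]), tolerance = 1e-9)
  # inversion consistency: a gene on the fitted line returns its attomole
  att <- 0.37
  on_line <- 10^(oracle["intercept"] + oracle["slope"] * log10(att))
  est2 <- ercc_total_copies(rpkm, panel, c(g = unname(on_line)))
  expect_equal(est2$copies, att * 6.02214e5, tolerance = 1e-6)
})

test_that("the RGC estimator averages the per-species ratio estimates", {
  mol <- c(RFP = 1e6, GFP = 1e5, CRE = 1e4)
  # self-consistent: every species implies 1e8 molecules
  expect_equal(rgc_total_copies(c(RFP = 100, GFP = 10, CRE = 1), mol, 1e4),
               1e8)
  # only RFP detected
  expect_equal(rgc_total_copies(c(RFP = 100, GFP = 0, CRE = 0), mol, 1e4),
               1e8)
  # two species giving 1e8 and 2e8 average to 1.5e8
  expect_equal(rgc_total_copies(c(RFP = 100, GFP = 5, CRE = 0), mol, 1e4),
               1.5e8)
  expect_error(rgc_total_copies(c(RFP = 0, GFP = 0, CRE = 0), mol, 1e4),
               "no RGC")
})

test_that("combining the two routes reproduces exact linear relations and the OLS oracle", {
  e <- c(s1 = 1e7, s2 = 3e7, s3 = 8e7, s4 = 1.2e8)
  same <- combine_copy_estimates(e, e)
  expect_equal(same$final, e, tolerance = 1e-9)
  tripled <- combine_copy_estimates(e, 3 * e)
  expect_equal(tripled$final, 3 * e, tolerance = 1e-9)

  withr::local_seed(32)
  noisy <- e * 10^rnorm(4, 0, 0.05)
  comb <- combine_copy_estimates(e, noisy)
  oracle <- ols_closed_form(log10(e), log10(noisy))
  expect_equal(comb$slope, unname(oracle["slope"]), tolerance = 1e-9)
  expect_equal(unname(comb$final),
               unname(10^(oracle["intercept"] +
                            oracle["slope"] * log10(e))),
               tolerance = 1e-9)
  expect_error(combine_copy_estimates(e[1:2], e[1:2]), ">= 3")
})

test_that("effective circRNA length and junction RPKM follow the anchored-read model", {
  expect_equal(effective_circ_length(100), 150)
  expect_equal(effective_circ_length(50), 50)
  expect_error(effective_circ_length(25), "exceed")
  # 3 junction reads, 100 bp reads, 1e6 mapped -> 3 / (0.150 x 1) = 20
  expect_equal(circ_rpkm(3, 100, 1e6), 20)
})

test_that("circRNA copy number scales linearly with the mRNA copy number", {
  expect_equal(circ_copy_number(100, 10000, 1e7), 1e5)
  expect_equal(circ_copy_number(0, 10000, 1e7), 0)
  expect_error(circ_copy_number(100, 0, 1e7), "positive")
  x <- circ_copy_number(7, 300, 1e6)
  expect_equal(circ_copy_number(7, 300, 5e6), 5 * x)
})

test_that("subsampling is exact in total, seed-reproducible, and hypergeometric in expectation", {
  counts <- stats::setNames(c(500L, 300L, 150L, 50L), paste0("g", 1:4))
  sub <- subsample_counts(counts, 100, seed = 5)
  expect_equal(sum(sub), 100)
  expect_true(all(sub <= counts))
  expect_identical(sub, subsample_counts(counts, 100, seed = 5))
  expect_error(subsample_counts(counts, 2000, seed = 5), "exceeds")

  n_draws <- 200
  draws <- vapply(seq_len(n_draws), function(s) {
    subsample_counts(counts, 100, seed = s)
  }, numeric(length(counts)))
  N <- sum(counts)
  k <- 100
  expected <- k * counts / N
  v <- k * (counts / N) * (1 - counts / N) * (N - k) / (N - 1)
  sigma_mean <- sqrt(v / n_draws)
  expect_true(all(abs(rowMeans(draws) - expected) < 3 * sigma_mean))
})

test_that("the ERCC QC retention rule requires detection in more than two samples", {
  m <- rbind(
    E1 = c(5, 5, 5, 5),    # retained
    E2 = c(2, 2, 0.5, 0),  # exactly two samples -> excluded
    E3 = c(1, 1, 1, 0.2))  # exactly three -> retained (boundary)
  colnames(m) <- paste0("s", 1:4)
  qc <- ercc_qc(m)
  expect_setequal(qc$retained, c("E1", "E3"))
  m2 <- matrix(c(3, 7, 1, 3, 7, 1), ncol = 2,
               dimnames = list(c("E1", "E2", "E3"), c("a", "b")))
  ident <- ercc_qc(m2, min_samples = 2)
  expect_equal(ident$pearson["a", "b"], 1)
  none <- ercc_qc(m * 0 + 0.1)
  expect_false(none$ok)
  expect_length(none$retained, 0)
})

test_that("ratio quantities are invariant when every count doubles", {
  cfg <- small_sim_config(seed = 41)
  sim <- suppressWarnings(simulate_embryo_series(cfg,
                                                 simulate_annotation(cfg)))
  ct <- sim$count_table
  rpkm1 <- compute_rpkm(ct, sim$gene_lengths)
  ct2 <- count_table(ct$counts * 2L, ct$total_mapped_reads * 2,
                     ct$read_length)
  rpkm2 <- compute_rpkm(ct2, sim$gene_lengths)
  expect_equal(rpkm1, rpkm2, tolerance = 1e-12)
})
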