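# Seeded synthetic embryo series with ground truth for every downstream
# stage of the pipeline.
#
# The generator emulates the study design it is meant to exercise: nine
# developmental stages from mature oocyte to hatched blastocyst with a few
# single-embryo replicates each; per-stage true total mRNA copy numbers on
# the 1e7-1.5e8 molecule scale; a 92-species ERCC-style dilution panel and
# a three-species long-polyA mix at 100:10:1 molecules with roughly
# three-fold higher capture efficiency; endogenous genes following
# maternal / zygotic / constant archetypes with negative-binomial count
# noise; and, for each simulated circle, back-spliced chimeric read pairs
# whose segment boundaries sit exactly on annotated splice sites, plus
# forward-spliced junction reads, split binomially at the junction's true
# circular fraction. A configurable fraction of contaminant chimeras with
# mates outside the circle span exercises the pair-end filter.

#' Simulation configuration
#'
#' All tunables of the synthetic embryo series, with defaults matching the
#' study conditions the package is designed around.
#'
#' @param seed Master seed; the whole simulation is a pure function of the
#'   configuration.
#' @param stages Ordered stage labels (default: the nine-stage series).
#' @param true_total_copies Per-stage true total mRNA molecules (default:
#'   the series 66.4, 29.0, 24.6, 17.0, 15.7, 38.1, 45.9, 104.5, 150.7
#'   million).
#' @param n_replicates Embryos per stage (default 3).
#' @param n_genes Number of endogenous genes (default 300).
#' @param n_circ_hosting Number of circRNA hosting genes (default 40).
#' @param maternal_frac,zygotic_frac Fractions of genes following the
#'   maternal / zygotic archetypes (defaults 0.3 each; the rest constant).
#' @param archetype_fold Fold change of the archetype step (default 8).
#' @param nb_dispersion NB dispersion of gene counts (default 0.1).
#' @param depth Expected mapped reads per sample (default 5e5).
#' @param read_length Read length in nt (default 100).
#' @param n_ercc Number of ERCC-style species (default 92).
#' @param ercc_amount_range Attomole range of the dilution panel (default
#'   1e-4 to 10, log-spaced).
#' @param ercc_efficiency Expected RPKM per attomole for the ERCC class
#'   (default 1000).
#' @param capture_sigma Lognormal capture noise, dex (default 0.1).
#' @param rgc_efficiency_mult Capture efficiency of the long-polyA mix
#'   relative to ERCC (default 3).
#' @param gene_efficiency_mult Capture efficiency of endogenous mRNA
#'   relative to ERCC (default 3: endogenous polyA tails resemble the
#'   long-polyA mix, not the short-tailed ERCCs).
#' @param rgc_molecules Molecules of the most abundant RGC species; the
#'   three species follow `rgc_ratio` (defaults 1e6 and 100:10:1).
#' @param rgc_ratio Molecule ratio of the three RGC species.
#' @param circ_ratio_range Range of per-junction true circular fractions
#'   (default 0.05-0.30).
#' @param junction_depth Junction-spanning reads per circle per sample
#'   (default 60).
#' @param contaminant_frac Fraction of extra contaminant chimeras with
#'   mates outside the circle span (default 0.05).
#' @param hotspot_prob Probability that a hosting gene carries a second
#'   circular isoform (default 0.5).
#' @param flank_multiplier Length multiplier for circle-flanking introns
#'   (default 4).
#' @param repeat_rate Baseline repeat elements per kb of intron (default
#'   0.8).
#' @param flank_repeat_mult Repeat-rate multiplier in flanking introns
#'   (default 4).
#' @param repeat_len Repeat element length in nt (default 300).
#' @param exon_range,exon_len_range,intron_meanlog,intron_sdlog Gene
#'   geometry: exons per gene, exon length range, and the lognormal intron
#'   length model (default median 1.6 kb).
#' @param anchor Aligner anchor segment length in nt (default 25).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       stages = c("oocyte", "zygote", "2cell", "4cell",
                                  "8cell", "morula", "early_blastocyst",
                                  "blastocyst", "hatched_blastocyst"),
                       true_total_copies = c(66.4, 29.0, 24.6, 17.0, 15.7,
                                             38.1, 45.9, 104.5, 150.7) * 1e6,
                       n_replicates = 3,
                       n_genes = 300,
                       n_circ_hosting = 40,
                       maternal_frac = 0.3,
                       zygotic_frac = 0.3,
                       archetype_fold = 8,
                       nb_dispersion = 0.1,
                       depth = 5e5,
                       read_length = 100,
                       n_ercc = 92,
                       ercc_amount_range = c(1e-4, 10),
                       ercc_efficiency = 1000,
                       capture_sigma = 0.1,
                       rgc_efficiency_mult = 3,
                       gene_efficiency_mult = 3,
                       rgc_molecules = 1e6,
                       rgc_ratio = c(100, 10, 1),
                       circ_ratio_range = c(0.05, 0.30),
                       junction_depth = 60,
                       contaminant_frac = 0.05,
                       hotspot_prob = 0.5,
                       flank_multiplier = 4,
                       repeat_rate = 0.8,
                       flank_repeat_mult = 4,
                       repeat_len = 300,
                       exon_range = c(4, 9),
                       exon_len_range = c(120, 300),
                       intron_meanlog = log(1600),
                       intron_sdlog = 0.8,
                       anchor = 25) {
  cfg <- as.list(environment())
  if (length(cfg$stages) == 0L) stop("stage list must be non-empty")
  if (length(cfg$true_total_copies) != length(cfg$stages)) {
    stop("true_total_copies must have one value per stage")
  }
  if (any(cfg$true_total_copies <= 0)) stop("true totals must be positive")
  if (cfg$n_genes < 1) stop("n_genes must be positive")
  if (cfg$n_circ_hosting > cfg$n_genes) {
    stop("n_circ_hosting cannot exceed n_genes")
  }
  if (any(cfg$circ_ratio_range < 0) || any(cfg$circ_ratio_range >= 1)) {
    stop("circ ratios must lie in [0, 1)")
  }
  if (length(cfg$rgc_ratio) != 3L) stop("rgc_ratio needs three values")
  if (cfg$contaminant_frac < 0 || cfg$contaminant_frac >= 1) {
    stop("contaminant_frac must lie in [0, 1)")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a gene annotation and repeat track
#'
#' Lays out multi-exon genes on one synthetic chromosome, designates the
#' circRNA hosting genes together with their circle exon spans (always on
#' internal exons), lengthens the circle-flanking introns by
#' `flank_multiplier`, and scatters repeat elements with an elevated rate
#' in flanking introns.
#'
#' @param cfg A [sim_config()].
#' @return List with `genes` (named list of [gene_model()]), `repeats`
#'   (BED-style data frame), `circ_defs` (the designated circles with
#'   their canonical keys), and `introns` (truth table per intron:
#'   coordinates, flanking status, repeat count).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, 1L), {
    chrom <- "chrS"
    hosting <- sort(sample.int(cfg$n_genes, cfg$n_circ_hosting))
    genes <- vector("list", cfg$n_genes)
    circ_defs <- list()
    introns_truth <- list()
    repeats <- list()
    pos <- 10000

    for (gi in seq_len(cfg$n_genes)) {
      gene_id <- sprintf("G%04d", gi)
      strand <- sample(c("+", "-"), 1L)
      n_ex <- sample(cfg$exon_range[1L]:cfg$exon_range[2L], 1L)
      ex_len <- sample(cfg$exon_len_range[1L]:cfg$exon_len_range[2L], n_ex,
                       replace = TRUE)
      in_len <- pmax(80, round(stats::rlnorm(n_ex - 1L, cfg$intron_meanlog,
                                             cfg$intron_sdlog)))
      is_host <- gi %in% hosting
      circs_here <- list()
      if (is_host) {
        n_iso <- 1L + stats::rbinom(1L, 1L, cfg$hotspot_prob)
        for (k in seq_len(n_iso)) {
          e1 <- resample(2:(n_ex - 2L), 1L)
          e2 <- resample(e1:(n_ex - 1L), 1L)
          circs_here[[k]] <- c(e1, e2)
        }
        circs_here <- unique(circs_here)
        flank_idx <- unique(unlist(lapply(circs_here, function(c2) {
          c(c2[1L] - 1L, c2[2L])  # introns before exon_from / after exon_to
        })))
        in_len[flank_idx] <- in_len[flank_idx] * cfg$flank_multiplier
      } else {
        flank_idx <- integer(0)
      }

      starts <- numeric(n_ex)
      ends <- numeric(n_ex)
      p <- pos
      for (e in seq_len(n_ex)) {
        starts[e] <- p
        ends[e] <- p + ex_len[e]
        p <- ends[e] + if (e < n_ex) in_len[e] else 0
      }
      genes[[gi]] <- gene_model(gene_id, chrom, strand,
                                data.frame(start = starts, end = ends))

      for (k in seq_along(circs_here)) {
        e1 <- circs_here[[k]][1L]
        e2 <- circs_here[[k]][2L]
        circ_defs[[length(circ_defs) + 1L]] <- data.frame(
          circ_id = sprintf("%s.c%d", gene_id, k), gene_id = gene_id,
          chrom = chrom, start = starts[e1], end = ends[e2],
          strand = strand, exon_from = e1, exon_to = e2,
          stringsAsFactors = FALSE)
      }

      if (n_ex > 1L) {
        for (e in seq_len(n_ex - 1L)) {
          i_start <- ends[e]
          i_end <- starts[e + 1L]
          i_len <- i_end - i_start
          is_flank <- e %in% flank_idx
          rate <- cfg$repeat_rate * (i_len / 1000) *
            if (is_flank) cfg$flank_repeat_mult else 1
          n_rep <- stats::rpois(1L, rate)
          if (n_rep > 0L) {
            w <- min(cfg$repeat_len, i_len)
            rs <- sort(sample.int(max(1L, i_len - w), n_rep,
                                  replace = TRUE)) + i_start - 1L
            repeats[[length(repeats) + 1L]] <- data.frame(
              chrom = chrom, start = rs, end = rs + w, name = "Alu_synth",
              stringsAsFactors = FALSE)
          }
          introns_truth[[length(introns_truth) + 1L]] <- data.frame(
            gene_id = gene_id, intron_idx = e, chrom = chrom,
            start = i_start, end = i_end, is_flanking = is_flank,
            n_repeats = n_rep, stringsAsFactors = FALSE)
        }
      }
      pos <- max(ends) + sample(15000:30000, 1L)
    }

    names(genes) <- vapply(genes, `[[`, "", "gene_id")
    repeats <- if (length(repeats)) do.call(rbind, repeats) else
      data.frame(chrom = character(0), start = numeric(0),
                 end = numeric(0), name = character(0))
    list(genes = genes,
         repeats = repeats,
         circ_defs = do.call(rbind, circ_defs),
         introns = do.call(rbind, introns_truth))
  })
}

# Spike-in panel implied by a configuration (deterministic given the seed).
simulate_spikein_panel <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 2L), {
    amounts <- 10^seq(log10(cfg$ercc_amount_range[1L]),
                      log10(cfg$ercc_amount_range[2L]),
                      length.out = cfg$n_ercc)
    ercc <- data.frame(
      species_id = sprintf("ERCC-%05d", seq_len(cfg$n_ercc)),
      class = "ERCC", amount = amounts, amount_unit = "attomole",
      length = sample(250:2000, cfg$n_ercc, replace = TRUE),
      polyA_len = 20, stringsAsFactors = FALSE)
    rgc <- data.frame(
      species_id = c("RGC-RFP", "RGC-GFP", "RGC-CRE"), class = "RGC",
      amount = cfg$rgc_molecules * cfg$rgc_ratio / cfg$rgc_ratio[1L],
      amount_unit = "molecules", length = c(1000, 800, 1200),
      polyA_len = 80, stringsAsFactors = FALSE)
    rbind(ercc, rgc)
  })
}

#' Simulate the embryo series
#'
#' Draws per-sample gene and spike-in counts, emits back-spliced chimeric
#' read pairs and forward-spliced junction counts for every designated
#' circle, and records the complete ground truth.
#'
#' @param cfg A [sim_config()].
#' @param ann Output of [simulate_annotation()].
#' @return List with `count_table` ([count_table()]), `chimeric` (data
#'   frame in the [read_chimeric()] layout), `fwd` (forward-junction
#'   counts per circle per sample), `panel` (spike-in panel),
#'   `gene_lengths` (named vector incl. spike-ins), and `truth` (list:
#'   `samples`, `genes`, `junctions`, `chimeric_reads`, `introns`).
#' @export
simulate_embryo_series <- function(cfg, ann) {
  stopifnot(inherits(cfg, "sim_config"))
  panel <- simulate_spikein_panel(cfg)
  genes <- ann$genes
  gene_ids <- names(genes)
  gene_len <- vapply(genes, function(g) sum(g$exons$end - g$exons$start),
                     numeric(1))
  lengths <- c(gene_len, stats::setNames(panel$length, panel$species_id))

  with_seed(derive_seed(cfg$seed, 3L), {
    n_st <- length(cfg$stages)
    sample_id <- as.vector(t(outer(cfg$stages,
                                   seq_len(cfg$n_replicates),
                                   function(s, r) sprintf("%s_r%d", s, r))))
    sample_stage <- rep(cfg$stages, each = cfg$n_replicates)
    stage_total <- stats::setNames(cfg$true_total_copies, cfg$stages)

    # gene archetypes
    n_mat <- round(cfg$maternal_frac * cfg$n_genes)
    n_zyg <- round(cfg$zygotic_frac * cfg$n_genes)
    cls <- rep("constant", cfg$n_genes)
    pick <- sample.int(cfg$n_genes, n_mat + n_zyg)
    cls[pick[seq_len(n_mat)]] <- "maternal"
    cls[pick[n_mat + seq_len(n_zyg)]] <- "zygotic"
    base_w <- stats::rlnorm(cfg$n_genes, 0, 0.7)
    i4 <- match("4cell", cfg$stages)
    if (is.na(i4)) i4 <- ceiling(n_st / 2)
    stage_mult <- matrix(1, nrow = cfg$n_genes, ncol = n_st,
                         dimnames = list(gene_ids, cfg$stages))
    late <- seq_len(n_st) > i4
    stage_mult[cls == "maternal", late] <- 1 / cfg$archetype_fold
    stage_mult[cls == "zygotic", !late] <- 1 / cfg$archetype_fold

    ercc <- panel[panel$class == "ERCC", ]
    rgc <- panel[panel$class == "RGC", ]
    eff_gene <- cfg$ercc_efficiency * cfg$gene_efficiency_mult
    eff_rgc <- cfg$ercc_efficiency * cfg$rgc_efficiency_mult

    feat_ids <- c(gene_ids, panel$species_id)
    counts <- matrix(0, nrow = length(feat_ids), ncol = length(sample_id),
                     dimnames = list(feat_ids, sample_id))
    gene_att <- matrix(0, nrow = cfg$n_genes, ncol = length(sample_id),
                       dimnames = list(gene_ids, sample_id))
    for (j in seq_along(sample_id)) {
      st <- sample_stage[j]
      A <- stage_total[[st]] / MOLECULES_PER_ATTOMOLE  # attomoles
      w <- base_w * stage_mult[, st]
      att <- A * w / sum(w)
      gene_att[, j] <- att
      mu_gene <- eff_gene * att * (gene_len / 1000) * (cfg$depth / 1e6)
      counts[gene_ids, j] <- stats::rnbinom(cfg$n_genes, mu = mu_gene,
                                            size = 1 / cfg$nb_dispersion)
      ercc_rpkm <- cfg$ercc_efficiency * ercc$amount *
        10^stats::rnorm(nrow(ercc), 0, cfg$capture_sigma)
      counts[ercc$species_id, j] <- stats::rpois(
        nrow(ercc), ercc_rpkm * (ercc$length / 1000) * (cfg$depth / 1e6))
      rgc_att <- rgc$amount / MOLECULES_PER_ATTOMOLE
      rgc_rpkm <- eff_rgc * rgc_att *
        10^stats::rnorm(nrow(rgc), 0, cfg$capture_sigma)
      counts[rgc$species_id, j] <- stats::rpois(
        nrow(rgc), rgc_rpkm * (rgc$length / 1000) * (cfg$depth / 1e6))
    }
    total_mapped <- pmax(colSums(counts), 1)

    # circles: back-spliced chimeras + forward junction reads
    cd <- ann$circ_defs
    true_ratio <- stats::runif(nrow(cd), cfg$circ_ratio_range[1L],
                               cfg$circ_ratio_range[2L])
    chim <- list()
    fwd <- list()
    chim_truth <- list()
    for (ci in seq_len(nrow(cd))) {
      span <- cd$end[ci] - cd$start[ci]
      for (j in seq_along(sample_id)) {
        d <- cfg$junction_depth
        back <- stats::rbinom(1L, d, true_ratio[ci])
        forward <- d - back
        facc <- stats::rbinom(1L, forward, 0.5)
        fwd[[length(fwd) + 1L]] <- data.frame(
          chrom = cd$chrom[ci], start = cd$start[ci], end = cd$end[ci],
          strand = cd$strand[ci], sample_id = sample_id[j],
          fwd_acceptor = facc, fwd_donor = forward - facc,
          stringsAsFactors = FALSE)
        n_cont <- stats::rbinom(1L, back, cfg$contaminant_frac)
        n_tot <- back + n_cont
        if (n_tot == 0L) next
        is_cont <- c(rep(FALSE, back), rep(TRUE, n_cont))
        l1 <- sample(30:(cfg$read_length - 30L), n_tot, replace = TRUE)
        l2 <- cfg$read_length - l1
        mate_len <- min(cfg$read_length, span)
        mate_start <- cd$start[ci] +
          sample.int(max(1L, span - mate_len + 1L), n_tot, replace = TRUE) - 1L
        mate_start[is_cont] <- cd$end[ci] +
          sample(1000:5000, sum(is_cont), replace = TRUE)
        rid <- sprintf("%s|%s|%s%03d", cd$circ_id[ci], sample_id[j],
                       ifelse(is_cont, "cont", "bk"), seq_len(n_tot))
        chim[[length(chim) + 1L]] <- data.frame(
          read_id = rid, sample_id = sample_id[j], chrom = cd$chrom[ci],
          seg1_start = cd$end[ci] - l1, seg1_end = cd$end[ci],
          seg2_start = cd$start[ci], seg2_end = cd$start[ci] + l2,
          strand = cd$strand[ci], mate_chrom = cd$chrom[ci],
          mate_start = mate_start, mate_end = mate_start + mate_len,
          mate_linear = 1L, stringsAsFactors = FALSE)
        chim_truth[[length(chim_truth) + 1L]] <- data.frame(
          read_id = rid, circ_id = cd$circ_id[ci],
          sample_id = sample_id[j], is_contaminant = is_cont,
          stringsAsFactors = FALSE)
      }
    }
    chim <- if (length(chim)) do.call(rbind, chim) else NULL
    fwd <- do.call(rbind, fwd)
    chim_truth <- if (length(chim_truth)) do.call(rbind, chim_truth) else
      NULL

    # warn about circles never reaching the support threshold
    if (!is.null(chim_truth)) {
      real <- chim_truth[!chim_truth$is_contaminant, ]
      per <- table(real$circ_id, real$sample_id)
      unreachable <- setdiff(cd$circ_id,
                             rownames(per)[apply(per >= 2, 1, any)])
    } else {
      unreachable <- cd$circ_id
    }
    if (length(unreachable)) {
      warning(sprintf("circle(s) never reached 2 back reads: %s",
                      paste(unreachable, collapse = ", ")))
    }

    ct <- count_table(counts,
                      stats::setNames(total_mapped, sample_id),
                      stats::setNames(rep(cfg$read_length,
                                          length(sample_id)), sample_id))
    truth <- list(
      samples = data.frame(sample_id = sample_id, stage = sample_stage,
                           true_total_copies = stage_total[sample_stage],
                           row.names = NULL, stringsAsFactors = FALSE),
      genes = data.frame(gene_id = gene_ids, class = cls,
                         length = as.numeric(gene_len),
                         stringsAsFactors = FALSE),
      gene_copies = data.frame(
        gene_id = gene_ids,
        gene_att * MOLECULES_PER_ATTOMOLE,
        check.names = FALSE, stringsAsFactors = FALSE),
      junctions = cbind(cd, data.frame(true_ratio = true_ratio)),
      chimeric_reads = chim_truth,
      introns = ann$introns)
    list(count_table = ct, chimeric = chim, fwd = fwd, panel = panel,
         gene_lengths = lengths, truth = truth)
  })
}

#' Simulate a raw-read FASTQ for the QC stage
#'
#' Emits a small FASTQ exercising every cleaning rule: clean reads,
#' low-quality reads, N-rich reads, reads with terminal poly(A)/poly(T)
#' runs, and AT-rich reads. The sequences carry no alignment meaning.
#'
#' @param cfg A [sim_config()].
#' @param path Output FASTQ path.
#' @param n_reads Total reads (default 200).
#' @return Data frame of the emitted reads with a `kind` truth column,
#'   invisibly; the FASTQ is written to `path`.
#' @export
simulate_qc_fastq <- function(cfg, path, n_reads = 200) {
  with_seed(derive_seed(cfg$seed, 4L), {
    L <- cfg$read_length
    kinds <- sample(c("clean", "lowqual", "nrich", "polyA", "polyT",
                      "atrich"), n_reads, replace = TRUE,
                    prob = c(0.5, 0.1, 0.1, 0.1, 0.1, 0.1))
    rand_seq <- function(n, alphabet = c("A", "C", "G", "T"),
                         prob = NULL) {
      paste(sample(alphabet, n, replace = TRUE, prob = prob),
            collapse = "")
    }
    hi_q <- function(n) paste(rep("I", n), collapse = "")  # Q40
    seqs <- quals <- character(n_reads)
    for (i in seq_len(n_reads)) {
      switch(kinds[i],
        clean = {
          seqs[i] <- rand_seq(L)
          quals[i] <- hi_q(L)
        },
        lowqual = {
          seqs[i] <- rand_seq(L)
          nlow <- ceiling(0.6 * L)
          quals[i] <- paste0(paste(rep("#", nlow), collapse = ""),  # Q2
                             hi_q(L - nlow))
        },
        nrich = {
          nn <- ceiling(0.15 * L)
          seqs[i] <- paste0(paste(rep("N", nn), collapse = ""),
                            rand_seq(L - nn))
          quals[i] <- hi_q(L)
        },
        polyA = {
          seqs[i] <- paste0(rand_seq(L - 30L), paste(rep("A", 30L),
                                                     collapse = ""))
          quals[i] <- hi_q(L)
        },
        polyT = {
          seqs[i] <- paste0(paste(rep("T", 30L), collapse = ""),
                            rand_seq(L - 30L))
          quals[i] <- hi_q(L)
        },
        atrich = {
          seqs[i] <- rand_seq(L, prob = c(0.45, 0.05, 0.05, 0.45))
          quals[i] <- hi_q(L)
        })
    }
    reads <- data.frame(id = sprintf("synthread%04d", seq_len(n_reads)),
                        seq = seqs, qual = quals, kind = kinds,
                        stringsAsFactors = FALSE)
    write_fastq(reads, path)
    invisible(reads)
  })
}

#' Simulate de novo transcript candidates with construction truth
#'
#' Builds candidate transcripts placed relative to the simulated gene
#' annotation so that a known subset passes the three-criterion filter and
#' the rest each fail one designated criterion.
#'
#' @param cfg A [sim_config()].
#' @param ann Output of [simulate_annotation()].
#' @param n_candidates Number of candidates (default 40).
#' @return Data frame of candidates with a `designed_fate` truth column
#'   (`pass`, `expression`, `distance`, `structure`).
#' @export
simulate_novel_candidates <- function(cfg, ann, n_candidates = 40) {
  with_seed(derive_seed(cfg$seed, 5L), {
    genes <- ann$genes
    last_end <- max(vapply(genes, function(g) max(g$exons$end), numeric(1)))
    fates <- sample(c("pass", "expression", "distance", "structure"),
                    n_candidates, replace = TRUE,
                    prob = c(0.4, 0.2, 0.2, 0.2))
    out <- vector("list", n_candidates)
    pos <- last_end + 50000
    for (i in seq_len(n_candidates)) {
      fate <- fates[i]
      start <- pos
      if (fate == "distance") {
        # park the candidate 5 kb past a random gene's span
        g <- genes[[sample.int(length(genes), 1L)]]
        start <- max(g$exons$end) + 5000
      }
      if (fate == "structure") {
        if (stats::runif(1) < 0.5) {
          ex <- data.frame(start = start, end = start + 700)  # 1 exon
        } else {
          ex <- data.frame(start = c(start, start + 1000),
                           end = c(start + 200, start + 1250))  # 450 nt
        }
      } else {
        ex <- data.frame(start = c(start, start + 1500),
                         end = c(start + 400, start + 1900))  # 800 nt
      }
      if (fate == "expression") {
        rp <- stats::runif(1, 0.05, 0.45)
        reps <- c(stats::runif(1, 0.26, 0.6), stats::runif(1, 0.01, 0.2),
                  stats::runif(1, 0.26, 0.6))
      } else {
        rp <- stats::runif(1, 0.6, 5)
        reps <- stats::runif(3, 0.3, 3)
      }
      out[[i]] <- data.frame(
        tx_id = sprintf("NOVEL%03d", i), chrom = "chrS",
        strand = sample(c("+", "-"), 1L),
        exons = paste(sprintf("%d-%d", ex$start, ex$end), collapse = ","),
        rpkm_overall = round(rp, 4),
        rpkm_reps = paste(round(reps, 4), collapse = ","),
        designed_fate = fate, stringsAsFactors = FALSE)
      if (fate != "distance") pos <- pos + 30000
    }
    do.call(rbind, out)
  })
}

#' Write the ground-truth tables
#'
#' @param truth Truth list from [simulate_embryo_series()].
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths with their MD5 checksums.
#' @export
emit_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(truth)) {
    if (is.null(truth[[nm]])) next
    p <- file.path(dir, paste0("truth_", nm, ".tsv"))
    utils::write.table(truth[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  tools::md5sum(paths)
}

#' Run the full simulation and write all inputs to a directory
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory.
#' @return List with the in-memory simulation objects (`ann`, `series`,
#'   `novel`, `qc_reads`) and `files` (named vector of written paths).
#' @export
write_simulation <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- simulate_annotation(cfg)
  series <- simulate_embryo_series(cfg, ann)
  novel <- simulate_novel_candidates(cfg, ann)
  f <- function(...) file.path(dir, ...)
  write_gtf(ann$genes, f("genes.gtf"))
  write_bed(ann$repeats, f("repeats.bed"))
  write_count_table(series$count_table, f("counts.tsv"), f("samples.tsv"))
  if (!is.null(series$chimeric)) {
    write_chimeric(series$chimeric, f("chimeric.tsv"))
  }
  utils::write.table(series$fwd, f("fwd_junctions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_spikein_panel(series$panel, f("spikeins.tsv"))
  write_novel_candidates(novel, f("novel_candidates.tsv"))
  utils::write.table(
    data.frame(feature_id = names(series$gene_lengths),
               length = as.numeric(series$gene_lengths)),
    f("lengths.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  simulate_qc_fastq(cfg, f("reads.fastq"))
  emit_truth(series$truth, f("truth"))
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  list(ann = ann, series = series, novel = novel,
       files = stats::setNames(files, basename(files)))
}
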