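# End-to-end pipeline: simulate -> clean -> circ-call -> quantify -> deg ->
# circ-stats -> novel-filter, driven by one declarative YAML configuration,
# with a run manifest listing every output file and its checksum.

#' Default pipeline configuration
#'
#' @param seed Master seed.
#' @return Nested list accepted by [run_pipeline()]; every module threshold
#'   is surfaced with its default.
#' @export
pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    simulate = as.list(unclass(sim_config(seed = seed))),
    clean = list(qual_threshold = 5, lowqual_frac = 0.5, n_frac = 0.1,
                 at_frac = 0.8, polyrun = 24, min_len = 30),
    circ_call = list(tol = 0, min_reads = 2),
    quantify = list(anchor = 25),
    deg = list(min_rpkm = 1, fc_up = 2, fc_down = 0.5, alpha = 0.05,
               min_disp = 0.01, four_cell = "4cell"),
    circ_stats = list(control_seed = 99, min_rpkm = 1),
    novel_filter = list(min_rpkm = 0.5, min_rep_rpkm = 0.25,
                        min_dist = 10000, min_exons = 2, min_len = 500)
  )
}

#' Run the full pipeline
#'
#' Executes the stages in order against a simulated embryo series, writing
#' every intermediate and final table under `out_dir`, and a run manifest
#' (`manifest.json`) with the configuration hash, seeds, tool version,
#' timestamps, and an MD5 checksum for every output file. The manifest is
#' written even when a stage fails.
#'
#' @param config Path to a YAML configuration file, or a configuration
#'   list as produced by [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with `status` (0 on success, 1 on stage
#'   failure), `manifest`, and (on success) the main result tables.
#' @export
run_pipeline <- function(config, out_dir) {
  t_start <- Sys.time()
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    config_hash <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  } else {
    config_hash <- digest_config(config)
  }
  defaults <- pipeline_config(seed = config$seed %||% 1)
  config <- modify_defaults(defaults, config)
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  status <- 0L
  err <- NULL
  results <- list()
  tryCatch({
    # -- simulate ---------------------------------------------------------
    cfg <- do.call(sim_config, config$simulate[names(config$simulate) %in%
                                                 names(formals(sim_config))])
    sim <- suppressWarnings(write_simulation(cfg, file.path(out_dir, "sim")))

    # -- clean ------------------------------------------------------------
    qc <- do.call(clean_reads, c(
      list(infile = file.path(out_dir, "sim", "reads.fastq"),
           outfile = file.path(out_dir, "clean.fastq")),
      config$clean))
    write_qc_report(qc$report, file.path(out_dir, "qc_report.tsv"))

    # -- circ-call --------------------------------------------------------
    genes <- read_gtf(file.path(out_dir, "sim", "genes.gtf"))
    chim <- read_chimeric(file.path(out_dir, "sim", "chimeric.tsv"))
    fwd <- utils::read.delim(file.path(out_dir, "sim", "fwd_junctions.tsv"))
    circs <- call_circrnas(chim, genes, tol = config$circ_call$tol,
                           min_reads = config$circ_call$min_reads,
                           fwd = fwd)
    write_circ_table(circs, file.path(out_dir, "circ.bed"))

    # -- quantify ---------------------------------------------------------
    ct <- sim$series$count_table
    copies <- estimate_copy_numbers(ct, sim$series$panel,
                                    sim$series$gene_lengths, circs = circs,
                                    anchor = config$quantify$anchor)
    utils::write.table(copies, file.path(out_dir, "copies.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    # -- deg --------------------------------------------------------------
    gene_ids <- sim$series$truth$genes$gene_id
    gct <- count_table(ct$counts[gene_ids, , drop = FALSE],
                       ct$total_mapped_reads, ct$read_length)
    sf <- size_factors(gct, stats::setNames(copies$final, copies$sample_id))
    stages <- stats::setNames(sim$series$truth$samples$stage,
                              sim$series$truth$samples$sample_id)
    de <- de_stage_series(gct, sf, stages, cfg$stages,
                          sim$series$gene_lengths,
                          min_rpkm = config$deg$min_rpkm,
                          min_disp = config$deg$min_disp,
                          fc_up = config$deg$fc_up,
                          fc_down = config$deg$fc_down,
                          alpha = config$deg$alpha)
    rpkm <- compute_rpkm(gct, sim$series$gene_lengths)
    norm_rpkm <- sweep(rpkm, 2, sf, "/")
    classes <- classify_maternal_zygotic(de, norm_rpkm, stages, cfg$stages,
                                         four_cell = config$deg$four_cell)
    utils::write.table(classes, file.path(out_dir, "gene_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(de)) {
      utils::write.table(
        de[[nm]], file.path(out_dir, sprintf("de_%s.tsv",
                                             gsub("->", "_vs_", nm))),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }

    # -- circ-stats -------------------------------------------------------
    cm <- circ_junction_metrics(circs)
    utils::write.table(cm, file.path(out_dir, "junction_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    feats <- flanking_features(circs, genes)
    utils::write.table(feats$per_circ,
                       file.path(out_dir, "circ_features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(feats$per_gene,
                       file.path(out_dir, "hosting_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    flank <- flanking_intron_intervals(circs, genes)
    ctrl <- sample_control_introns(genes, unique(circs$gene_id),
                                   n = nrow(flank),
                                   seed = config$circ_stats$control_seed,
                                   rpkm = rpkm,
                                   min_rpkm = config$circ_stats$min_rpkm)
    repeats <- read_bed(file.path(out_dir, "sim", "repeats.bed"))
    alu <- alu_enrichment(flank, ctrl, repeats)
    utils::write.table(
      data.frame(metric = c("median_flank", "median_control", "p_value"),
                 value = c(alu$median_flank, alu$median_control,
                           alu$p_value)),
      file.path(out_dir, "alu_enrichment.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)

    # -- novel-filter -----------------------------------------------------
    novel <- read_novel_candidates(file.path(out_dir, "sim",
                                             "novel_candidates.tsv"))
    nf <- do.call(filter_novel, c(list(candidates = novel, known = genes),
                                  config$novel_filter))
    write_novel_candidates(nf$kept, file.path(out_dir, "novel_kept.tsv"))
    utils::write.table(
      data.frame(criterion = names(nf$tally), rejected = as.integer(nf$tally)),
      file.path(out_dir, "novel_tally.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)

    results <- list(circs = circs, copies = copies, classes = classes,
                    de = de, features = feats, alu = alu, novel = nf)
  }, error = function(e) {
    status <<- 1L
    err <<- conditionMessage(e)
  })

  outputs <- setdiff(list.files(out_dir, recursive = TRUE,
                                full.names = TRUE),
                     file.path(out_dir, "manifest.json"))
  manifest <- list(
    command = "run_pipeline",
    version = as.character(utils::packageVersion("embryocirc")),
    config_hash = config_hash,
    seed = config$seed,
    status = status,
    error = err,
    started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (status != 0L) {
    warning(sprintf("pipeline failed: %s", err))
  }
  invisible(c(list(status = status, manifest = manifest), results))
}

digest_config <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

modify_defaults <- function(defaults, config) {
  for (nm in names(config)) {
    if (is.list(config[[nm]]) && is.list(defaults[[nm]])) {
      defaults[[nm]] <- modify_defaults(defaults[[nm]], config[[nm]])
    } else {
      defaults[[nm]] <- config[[nm]]
    }
  }
  defaults
}

validate_pipeline_config <- function(config) {
  need <- c("seed", "simulate", "clean", "circ_call", "quantify", "deg",
            "circ_stats", "novel_filter")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    stop(sprintf("pipeline config usage error: missing section(s) %s",
                 paste(missing, collapse = ", ")))
  }
  if (is.null(config$simulate$stages) ||
      length(config$simulate$stages) == 0L) {
    stop("pipeline config usage error: simulate.stages must be non-empty")
  }
  invisible(config)
}
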