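## End-to-end pipeline: simulate -> peaks -> consensus -> scan -> synteny -

#' Extract candidate centromere sequences around primary summits
#'
#' Cuts a `window`-bp sequence centred on the top-ranked primary peak summit
#' of each chromosome (warning when a chromosome has more than one primary
#' peak), clipped at chromosome ends with a warning. Candidate names are the
#' chromosome IDs.
#'
#' @param genome named character vector or [Biostrings::DNAStringSet].
#' @param peaks data.frame from [call_peaks()].
#' @param window extraction width in bp; generous relative to the ~110-bp
#'   functional unit so the anchor alignment has slack.
#' @return named character vector of candidate sequences.
#' @export
extract_candidates <- function(genome, peaks, window = 400L) {
  if (inherits(genome, "DNAStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  prim <- peaks[peaks$tier == "primary", , drop = FALSE]
  if (nrow(prim) == 0L) stop("no primary peaks; cannot extract candidates",
                             call. = FALSE)
  out <- character(0)
  for (chrom in unique(prim$chromosome)) {
    p <- prim[prim$chromosome == chrom, , drop = FALSE]
    if (nrow(p) > 1L) {
      warning(sprintf("%s has %d primary peaks; taking the top-ranked one",
                      chrom, nrow(p)))
      p <- p[which.max(p$area), , drop = FALSE]
    }
    L <- nchar(genome[[chrom]])
    half <- window %/% 2L
    s0 <- p$summit - half; e0 <- s0 + window       # 0-based half-open
    if (s0 < 0L || e0 > L) {
      warning(sprintf("candidate window on %s clipped at a chromosome end", chrom))
      s0 <- max(0L, s0); e0 <- min(L, e0)
    }
    out[chrom] <- substr(genome[[chrom]], s0 + 1L, e0)
  }
  out
}

#' Default run configuration for a fully simulated analysis
#'
#' @param seed root seed.
#' @param outdir output directory.
#' @return a nested configuration list understood by [run_all()].
#' @export
default_run_config <- function(seed = 1L, outdir = tempfile("pointcen_run_")) {
  list(seed = as.integer(seed), outdir = outdir,
       simulate = list(genome = list(), centromere_model = list(),
                       n_syntenic = 1L),
       peaks = list(), consensus = list(window = 110L, candidate_window = 400L),
       scan = list(max_mismatch = 0L),
       synteny = list(gap_tolerance = 5L),
       primary_factor = "ndc80")
}

.apply_overrides <- function(fn, overrides) {
  do.call(fn, overrides[names(overrides) %in% names(formals(fn))])
}

#' Read a run configuration from YAML
#' @param path YAML file.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  utils::modifyList(base, cfg)
}

#' Run the full centromere-discovery pipeline
#'
#' Executes simulate -> coverage -> enrichment/peaks (per factor) ->
#' candidate extraction -> anchor alignment -> consensus annotation ->
#' core-pattern uniqueness scan -> synteny survey, persisting every
#' intermediate in standard formats under `config$outdir` and writing a
#' machine-readable run report (JSON). Identical configuration and seed give
#' metric-identical reports.
#'
#' A configuration must either contain a `simulate` block or point at real
#' data (`paths` block with genome/gff/tracks); supplying both is a
#' configuration error.
#'
#' @param config list from [default_run_config()] / [read_run_config()], or a
#'   YAML path.
#' @return the run report, invisibly (also written to
#'   `outdir/report.json`).
#' @export
run_all <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  if (!is.null(config$simulate) && !is.null(config$paths))
    stop("config error: supply either a simulate block or real-data paths, not both",
         call. = FALSE)
  if (is.null(config$simulate) && is.null(config$paths))
    stop("config error: neither simulate block nor real-data paths present",
         call. = FALSE)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  paths <- character(0)

  ## ---- inputs ---------------------------------------------------------
  if (!is.null(config$simulate)) {
    pc_log("simulate", "generating synthetic genome (seed %d)", seed)
    cen_model <- .apply_overrides(centromere_model,
                                  config$simulate$centromere_model %||% list())
    gcfg_over <- config$simulate$genome %||% list()
    gcfg_over$seed <- seed
    gcfg <- .apply_overrides(synthetic_genome_config, gcfg_over)
    sim <- generate_genome(gcfg, cen_model)
    paths <- c(paths, write_genome_bundle(sim, outdir))
    genome <- sim$genome; genes <- sim$genes; truth <- sim$truth
    factors <- names(gcfg$secondary_sites_per_factor)
    chip_params <- gcfg$chip
    ref <- simulate_reference(truth, genes,
                              n_syntenic = config$simulate$n_syntenic %||% 1L)
    ref_path <- file.path(outdir, "ref_order.tsv")
    write_gene_order_tsv(ref$ref_order, ref_path)
    orth_path <- file.path(outdir, "orthologs.tsv")
    utils::write.table(ref$orthologs, orth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, ref = ref_path, orthologs = orth_path)
  } else {
    p <- config$paths
    pc_log("load", "reading real data from configured paths")
    genome <- Biostrings::readDNAStringSet(p$genome)
    genes <- read_genes_gff3(p$gff)
    truth <- NULL
    factors <- names(p$tracks)
    chip_params <- .apply_overrides(chip_sim_params, config$chip %||% list())
    ref <- list(ref_order = read_gene_order_tsv(p$ref_order),
                orthologs = utils::read.table(p$orthologs, sep = "\t",
                                              col.names = c("gene_a", "gene_b"),
                                              stringsAsFactors = FALSE),
                ref_centromeres = NULL)
    cen_model <- .apply_overrides(centromere_model,
                                  config$centromere_model %||% list())
  }

  ## ---- coverage, enrichment, peaks ------------------------------------
  pk_params <- .apply_overrides(peak_call_params, config$peaks %||% list())
  peaks_by_factor <- list()
  for (factor in factors) {
    if (!is.null(truth)) {
      cov <- simulate_coverage(genome, truth, factor, chip_params, seed = seed)
    } else {
      tr <- config$paths$tracks[[factor]]
      cov <- list(chip = read_bedgraph(tr$chip, chip_params$bin_size),
                  input = read_bedgraph(tr$input, chip_params$bin_size))
    }
    write_bedgraph(cov$chip, file.path(outdir, sprintf("%s_chip.bedgraph", factor)))
    write_bedgraph(cov$input, file.path(outdir, sprintf("%s_input.bedgraph", factor)))
    enr <- compute_enrichment(cov$chip, cov$input, pk_params)
    pk <- classify_intergenic(call_peaks(enr, pk_params), genes)
    write_peaks_bed(pk, file.path(outdir, sprintf("peaks_%s.bed", factor)),
                    name = factor)
    peaks_by_factor[[factor]] <- pk
    pc_log("peaks", "%s: %d primary, %d secondary", factor,
           sum(pk$tier == "primary"), sum(pk$tier == "secondary"))
  }
  summary_pk <- peak_summary(peaks_by_factor, truth,
                             match_distance = chip_params$peak_sd)

  ## ---- consensus ------------------------------------------------------
  primary_factor <- config$primary_factor %||% factors[[1L]]
  cand <- extract_candidates(genome, peaks_by_factor[[primary_factor]],
                             window = config$consensus$candidate_window %||% 400L)
  cand_path <- file.path(outdir, "candidates.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cand), cand_path)
  aln <- anchor_align(cand, window_length = config$consensus$window %||% 110L)
  pfm <- build_pfm(cand, aln)
  ann <- annotate_consensus(pfm)
  write_pfm_jaspar(pfm, file.path(outdir, "consensus_pfm.txt"))
  jsonlite::write_json(list(classes = ann$classes, degenerate = ann$degenerate,
                            elements = ann$elements, core = as.list(ann$core)),
                       file.path(outdir, "consensus.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pc_log("consensus", "elements: %s; core %s",
         paste(sprintf("%d-%d", ann$elements$start, ann$elements$end),
               collapse = ", "),
         if (is.null(ann$core)) "undefined"
         else sprintf("%d-%d", ann$core[["start"]], ann$core[["end"]]))

  ## ---- uniqueness scan ------------------------------------------------
  core_pattern <- model_core_pattern(cen_model)
  hits <- scan_genome(genome, core_pattern,
                      max_mismatch = config$scan$max_mismatch %||% 0L,
                      name = "core_consensus")
  cen_intervals <- if (!is.null(truth)) {
    do.call(rbind, lapply(truth$chromosomes, function(tc)
      data.frame(chromosome = tc$chrom, start = tc$cen_start, end = tc$cen_end)))
  } else {
    prim <- peaks_by_factor[[primary_factor]]
    prim <- prim[prim$tier == "primary", ]
    data.frame(chromosome = prim$chromosome, start = prim$start, end = prim$end)
  }
  uniq <- uniqueness_report(hits, cen_intervals)
  write_hits_bed(uniq$hits, file.path(outdir, "core_hits.bed"),
                 width = nchar(core_pattern))

  ## ---- synteny --------------------------------------------------------
  loci <- lapply(seq_len(nrow(cen_intervals)), function(i)
    locate_centromere(cen_intervals$chromosome[i], cen_intervals$start[i],
                      cen_intervals$end[i], genes))
  surv <- synteny_survey(loci, ref$orthologs, ref$ref_order,
                         ref_centromeres = ref$ref_centromeres,
                         gap_tolerance = config$synteny$gap_tolerance %||% 5L)
  utils::write.table(surv$calls, file.path(outdir, "synteny_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- report ---------------------------------------------------------
  report <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("pointcen")),
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = as.list(c(paths, outdir = outdir)),
    metrics = list(
      peak_summary = summary_pk$per_factor,
      single_peak_chromosomes =
        summary_pk$per_factor$single_peak_chromosomes[
          summary_pk$per_factor$factor == primary_factor],
      element_spans = ann$elements[, c("start", "end")],
      core_span = as.list(ann$core),
      uniqueness = as.list(uniq$counts),
      synteny_summary = as.list(surv$summary)))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pc_log("run", "report written to %s", file.path(outdir, "report.json"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
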