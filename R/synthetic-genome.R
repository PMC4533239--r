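## Synthetic genomes, annotations and ChIP coverage ----------------------

#' Parameters of the binned ChIP coverage simulation
#'
#' Background counts per bin are negative binomial with mean
#' `background_mean` and variance `m * (1 + dispersion * m)`; ChIP counts at a
#' bound site follow the same family with the mean scaled by a Gaussian
#' enrichment kernel, `m * (1 + (fold - 1) * exp(-d^2 / (2 * peak_sd^2)))`.
#'
#' @param bin_size bin width in bp.
#' @param background_mean mean background counts per bin.
#' @param dispersion negative-binomial dispersion alpha (variance
#'   `m + alpha * m^2`); 0 gives Poisson-like noise.
#' @param peak_fold enrichment multiplier at a centromere summit.
#' @param secondary_fold enrichment multiplier at a secondary (non-centromeric)
#'   binding site.
#' @param peak_sd Gaussian kernel width in bp.
#' @return a `chip_sim_params` object.
#' @export
chip_sim_params <- function(bin_size = 50L, background_mean = 100,
                            dispersion = 0.05, peak_fold = 10,
                            secondary_fold = 3, peak_sd = 300) {
  stop_if_not_scalar_count(bin_size, "bin_size")
  stop_if_not_scalar_count(background_mean, "background_mean")
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (peak_fold <= 1 || secondary_fold <= 1)
    stop("peak_fold and secondary_fold must exceed 1", call. = FALSE)
  structure(list(bin_size = as.integer(bin_size), background_mean = background_mean,
                 dispersion = dispersion, peak_fold = peak_fold,
                 secondary_fold = secondary_fold, peak_sd = peak_sd),
            class = "chip_sim_params")
}

#' Configuration of a synthetic genome
#'
#' Defaults emulate a ten-chromosome budding-yeast-like karyotype with one
#' intergenic centromere per chromosome and, per kinetochore factor, the
#' number of extra (secondary) binding sites observed for Cse4, Ndc10 and
#' Cep3 (one, two and six) in addition to the ten shared centromeric sites.
#' Chromosome lengths are scaled down from the megabase range so that a full
#' simulate-and-call round trip runs in seconds.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param gene_length,intergenic_length bp sizes used to tile genes.
#' @param cen_intergenic_length width of the widened intergenic interval that
#'   hosts the centromere window.
#' @param background_at genome-wide AT fraction of non-centromeric sequence.
#' @param secondary_min_cen_distance minimum distance (bp) between a secondary
#'   site and any centromere.
#' @param secondary_sites_per_factor named integer vector, factor -> number of
#'   extra non-centromeric binding sites.
#' @param seed root seed for all draws.
#' @param chip a [chip_sim_params()].
#' @return a `synthetic_genome_config` object.
#' @export
synthetic_genome_config <- function(n_chromosomes = 10L,
                                    chrom_length = 300000L,
                                    gene_length = 1500L,
                                    intergenic_length = 500L,
                                    cen_intergenic_length = 1200L,
                                    background_at = 0.6,
                                    secondary_min_cen_distance = 50000L,
                                    secondary_sites_per_factor =
                                      c(ndc80 = 0L, cse4 = 1L, ndc10 = 2L, cep3 = 6L),
                                    seed = 1L,
                                    chip = chip_sim_params()) {
  for (nm in c("n_chromosomes", "chrom_length", "gene_length",
               "intergenic_length", "cen_intergenic_length"))
    stop_if_not_scalar_count(get(nm), nm)
  if (is.null(names(secondary_sites_per_factor)) ||
      any(names(secondary_sites_per_factor) == ""))
    stop("secondary_sites_per_factor must be a named vector", call. = FALSE)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 gene_length = as.integer(gene_length),
                 intergenic_length = as.integer(intergenic_length),
                 cen_intergenic_length = as.integer(cen_intergenic_length),
                 background_at = background_at,
                 secondary_min_cen_distance = as.integer(secondary_min_cen_distance),
                 secondary_sites_per_factor = secondary_sites_per_factor,
                 seed = as.integer(seed), chip = chip),
            class = "synthetic_genome_config")
}

.random_dna <- function(n, at = 0.6) {
  p <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a synthetic genome with planted centromeres
#'
#' Builds `n_chromosomes` chromosomes tiled with non-overlapping genes on
#' alternating strands, widens one roughly central intergenic interval per
#' chromosome and plants a centromere window (sampled from `cen_model`)
#' strictly inside it. Every chromosome and the centromere placement are drawn
#' from child seeds of `config$seed`, so regenerating with the same
#' configuration is bit-identical and adding chromosomes does not disturb
#' existing ones.
#'
#' All internal coordinates are 0-based half-open; GFF3 output is 1-based
#' inclusive.
#'
#' @param config a [synthetic_genome_config()].
#' @param cen_model a [centromere_model()].
#' @return list with `genome` (named [Biostrings::DNAStringSet]), `genes`
#'   (a [GenomicRanges::GRanges] of gene features) and `truth` (planted-truth
#'   list; see [write_truth()]).
#' @export
generate_genome <- function(config = synthetic_genome_config(),
                            cen_model = centromere_model()) {
  stopifnot(inherits(config, "synthetic_genome_config"),
            inherits(cen_model, "centromere_model"))
  if (config$cen_intergenic_length < cen_model$window_length + 2L)
    stop("centromeric intergenic interval is shorter than the centromere window",
         call. = FALSE)

  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  seqs <- character(config$n_chromosomes)
  gene_rows <- list()
  truth_chr <- list()

  for (ci in seq_len(config$n_chromosomes)) {
    res <- with_seed(child_seed(config$seed, "chrom", ci), {
      L <- config$chrom_length
      gl <- config$gene_length; il <- config$intergenic_length
      unit <- gl + il
      dna <- .random_dna(L, config$background_at)

      ## tile genes: [intergenic gene]* with one widened centromeric gap
      ## replacing the intergenic interval closest to the chromosome middle.
      n_units <- (L - il) %/% unit
      gene_starts <- il + (seq_len(n_units) - 1L) * unit  # 0-based
      mid_unit <- which.min(abs(gene_starts - L / 2))
      ## widen: shift genes after mid_unit right by (cen_gap - il)
      extra <- config$cen_intergenic_length - il
      gene_starts[seq_len(n_units) > mid_unit] <-
        gene_starts[seq_len(n_units) > mid_unit] + extra
      keep <- gene_starts + gl <= L
      gene_starts <- gene_starts[keep]
      n_genes <- length(gene_starts)
      genes <- data.frame(
        chrom = chroms[ci],
        start = gene_starts, end = gene_starts + gl,  # 0-based half-open
        gene = sprintf("nc%02dg%03d", ci, seq_len(n_genes)),
        strand = rep(c("+", "-"), length.out = n_genes),
        stringsAsFactors = FALSE)

      gap_start <- gene_starts[mid_unit] + gl
      gap_end <- gene_starts[mid_unit + 1L]
      stopifnot(gap_end - gap_start == config$cen_intergenic_length)

      ## place the window with jitter, keeping a margin inside the interval
      win <- cen_model$window_length
      margin <- min(100L, (gap_end - gap_start - win) %/% 2L)
      off_lo <- gap_start + margin
      off_hi <- gap_end - win - margin
      cen_start <- if (off_hi > off_lo) sample(off_lo:off_hi, 1L) else off_lo
      cen <- sample_centromere(cen_model)
      substr(dna, cen_start + 1L, cen_start + win) <- cen$sequence

      core0 <- cen_start + cen_model$core_start - 1L
      elements <- cen$elements
      elements$genome_start <- cen_start + elements$start - 1L  # 0-based
      elements$genome_end <- cen_start + elements$end           # half-open
      list(dna = dna, genes = genes,
           truth = list(chrom = chroms[ci],
                        cen_start = cen_start, cen_end = cen_start + win,
                        window_sequence = cen$sequence,
                        core_start = core0,
                        core_end = core0 + (cen_model$core_end - cen_model$core_start + 1L),
                        elements = elements,
                        flank_left = genes$gene[mid_unit],
                        flank_right = genes$gene[mid_unit + 1L]))
    })
    seqs[ci] <- res$dna
    gene_rows[[ci]] <- res$genes
    truth_chr[[chroms[ci]]] <- res$truth
  }

  genes_df <- do.call(rbind, gene_rows)
  genome <- Biostrings::DNAStringSet(stats::setNames(seqs, chroms))

  genes <- GenomicRanges::GRanges(
    seqnames = genes_df$chrom,
    ranges = IRanges::IRanges(start = genes_df$start + 1L, end = genes_df$end),
    strand = genes_df$strand,
    ID = genes_df$gene, type = "gene",
    seqlengths = stats::setNames(rep(config$chrom_length, length(chroms)), chroms))

  ## secondary binding sites per factor, in intergenic space far from any
  ## centromere and well separated from each other.
  cen_mid <- vapply(truth_chr, function(t) (t$cen_start + t$cen_end) / 2, numeric(1))
  secondary <- list()
  for (factor in names(config$secondary_sites_per_factor)) {
    k <- config$secondary_sites_per_factor[[factor]]
    secondary[[factor]] <- if (k == 0L) {
      data.frame(chrom = character(0), pos = integer(0))
    } else {
      with_seed(child_seed(config$seed, "secondary", factor), {
        ## candidate positions: midpoints of ordinary intergenic intervals
        cand <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
          g <- gene_rows[[ci]]
          mids <- (g$end[-nrow(g)] + g$start[-1L]) %/% 2L
          data.frame(chrom = chroms[ci], pos = mids)
        }))
        ok <- abs(cand$pos - cen_mid[match(cand$chrom, names(cen_mid))]) >=
          config$secondary_min_cen_distance
        cand <- cand[ok, , drop = FALSE]
        picked <- cand[0, ]
        cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
        for (i in seq_len(nrow(cand))) {
          row <- cand[i, , drop = FALSE]
          if (nrow(picked) == 0L ||
              all(row$chrom != picked$chrom | abs(row$pos - picked$pos) >= 5000L)) {
            picked <- rbind(picked, row)
            if (nrow(picked) == k) break
          }
        }
        if (nrow(picked) < k)
          stop(sprintf("could not place %d secondary sites for factor %s", k, factor),
               call. = FALSE)
        picked[order(picked$chrom, picked$pos), , drop = FALSE]
      })
    }
  }

  truth <- list(config_seed = config$seed,
                window_length = cen_model$window_length,
                chromosomes = truth_chr,
                secondary_sites = secondary)
  list(genome = genome, genes = genes, truth = truth)
}

#' Simulate binned ChIP and input coverage for one factor
#'
#' Input coverage is negative-binomial background; ChIP coverage multiplies
#' the background mean by a Gaussian enrichment kernel around every planted
#' site for the factor: all centromeres (at `peak_fold`) plus the factor's
#' secondary sites (at `secondary_fold`).
#'
#' @param genome named [Biostrings::DNAStringSet] (only lengths are used).
#' @param truth planted truth from [generate_genome()].
#' @param factor factor label; must appear in the truth's secondary-site map.
#' @param params a [chip_sim_params()].
#' @param seed integer seed.
#' @return list with `chip` and `input`, both [coverage_track()] objects.
#' @export
simulate_coverage <- function(genome, truth, factor, params = chip_sim_params(),
                              seed = 1L) {
  stopifnot(inherits(params, "chip_sim_params"))
  if (!factor %in% names(truth$secondary_sites))
    stop(sprintf("unknown factor '%s'; truth knows: %s", factor,
                 paste(names(truth$secondary_sites), collapse = ", ")), call. = FALSE)
  if (!all(names(truth$chromosomes) %in% names(genome)))
    stop("truth chromosomes must be a subset of genome chromosomes", call. = FALSE)

  size <- if (params$dispersion > 0) 1 / params$dispersion else Inf
  rnb <- function(n, mu) {
    if (is.finite(size)) stats::rnbinom(n, mu = mu, size = size)
    else stats::rpois(n, mu)
  }

  bins <- list(); chip <- list(); input <- list()
  for (chrom in names(genome)) {
    res <- with_seed(child_seed(seed, "coverage", factor, chrom), {
      len <- Biostrings::width(genome)[match(chrom, names(genome))]
      n_bins <- ceiling(len / params$bin_size)
      centers <- (seq_len(n_bins) - 0.5) * params$bin_size

      kernel <- rep(0, n_bins)
      add_site <- function(pos, fold) {
        g <- (fold - 1) * exp(-(centers - pos)^2 / (2 * params$peak_sd^2))
        pmax(kernel, g)
      }
      tc <- truth$chromosomes[[chrom]]
      if (!is.null(tc))
        kernel <- add_site((tc$cen_start + tc$cen_end) / 2, params$peak_fold)
      sec <- truth$secondary_sites[[factor]]
      sec <- sec[sec$chrom == chrom, , drop = FALSE]
      for (i in seq_len(nrow(sec)))
        kernel <- add_site(sec$pos[i], params$secondary_fold)

      mu_chip <- params$background_mean * (1 + kernel)
      list(chip = rnb(n_bins, mu_chip),
           input = rnb(n_bins, rep(params$background_mean, n_bins)))
    })
    chip[[chrom]] <- res$chip
    input[[chrom]] <- res$input
  }
  list(chip = coverage_track(chip, params$bin_size),
       input = coverage_track(input, params$bin_size))
}

## Reference gene order with planted rearrangements ----------------------

#' Simulate an ancestor-like reference gene order
#'
#' Starting from the synthetic genome's own gene order, applies one reciprocal
#' translocation per "broken" centromere, cutting exactly at the centromeric
#' intergenic interval: reference chromosome i keeps the left arm of query
#' chromosome i and receives the right arm of the next broken chromosome (a
#' cyclic exchange). The two genes flanking a broken centromere therefore end
#' up on different reference chromosomes, so the locus is a synteny breakpoint
#' by construction. `n_syntenic` centromeres (taken from the last chromosomes)
#' are left intact and receive a reference centromere between the orthologs of
#' their flanks; every other reference chromosome receives its centromere at
#' an unrelated position, emulating ancestral centromere loci that are no
#' longer centromeric in the query genome.
#'
#' @param truth planted truth from [generate_genome()].
#' @param genes gene [GenomicRanges::GRanges] from [generate_genome()].
#' @param n_syntenic how many centromere loci keep conserved gene order.
#' @return list with `ref_order` (named list of ordered reference gene-ID
#'   vectors), `orthologs` (data.frame gene_a/gene_b), and `ref_centromeres`
#'   (data.frame chrom/after: the centromere lies after that many genes).
#' @export
simulate_reference <- function(truth, genes, n_syntenic = 1L) {
  chroms <- names(truth$chromosomes)
  n <- length(chroms)
  if (n_syntenic < 0L || n_syntenic > n)
    stop("n_syntenic must lie in [0, n_chromosomes]", call. = FALSE)
  ## query gene order per chromosome, split at the centromere
  ord <- lapply(chroms, function(ch) {
    g <- genes[GenomicRanges::seqnames(genes) == ch]
    g <- g[order(GenomicRanges::start(g))]
    ids <- g$ID
    tc <- truth$chromosomes[[ch]]
    cut <- match(tc$flank_left, ids)
    list(left = ids[seq_len(cut)], right = ids[(cut + 1L):length(ids)])
  })
  names(ord) <- chroms

  broken <- if (n_syntenic < n) seq_len(n - n_syntenic) else integer(0)
  intact <- setdiff(seq_len(n), broken)

  ref_order <- vector("list", n)
  ref_cen <- data.frame(chrom = paste0("anc", seq_len(n)), after = NA_integer_)
  for (i in seq_len(n)) {
    if (i %in% intact) {
      ref_order[[i]] <- c(ord[[i]]$left, ord[[i]]$right)
      ref_cen$after[i] <- length(ord[[i]]$left)
    } else if (length(broken) == 1L) {
      ## no translocation partner: reversing the right arm still separates
      ## the two centromere-flanking genes in the reference order
      ref_order[[i]] <- c(ord[[i]]$left, rev(ord[[i]]$right))
      ref_cen$after[i] <- max(1L, length(ord[[i]]$left) %/% 3L)
    } else {
      j <- broken[(match(i, broken) %% length(broken)) + 1L]  # next broken, cyclic
      ref_order[[i]] <- c(ord[[i]]$left, ord[[j]]$right)
      ## ancestral centromere at an unrelated junction: a third of the way
      ## into the left arm, away from both cut points.
      ref_cen$after[i] <- max(1L, length(ord[[i]]$left) %/% 3L)
    }
  }
  names(ref_order) <- ref_cen$chrom
  all_ids <- unlist(lapply(ord, function(o) c(o$left, o$right)), use.names = FALSE)
  orthologs <- data.frame(gene_a = all_ids, gene_b = all_ids,
                          stringsAsFactors = FALSE)
  list(ref_order = ref_order, orthologs = orthologs, ref_centromeres = ref_cen)
}

## File I/O --------------------------------------------------------------

#' Write a synthetic genome bundle to disk
#'
#' FASTA via Biostrings; genes and centromere features as GFF3 (1-based) via
#' rtracklayer; truth as JSON.
#'
#' @param sim result of [generate_genome()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a named vector of paths.
#' @export
write_genome_bundle <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(outdir, "genome.fa"),
             gff = file.path(outdir, "genes.gff3"),
             truth = file.path(outdir, "truth.json"))
  Biostrings::writeXStringSet(sim$genome, paths[["fasta"]])
  cens <- do.call(rbind, lapply(sim$truth$chromosomes, function(tc)
    data.frame(chrom = tc$chrom, start = tc$cen_start, end = tc$cen_end)))
  cen_gr <- GenomicRanges::GRanges(
    seqnames = factor(cens$chrom, levels = GenomeInfoDb::seqlevels(sim$genes)),
    ranges = IRanges::IRanges(start = cens$start + 1L, end = cens$end),
    strand = "*", ID = paste0("CEN_", cens$chrom), type = "centromere",
    seqinfo = GenomeInfoDb::seqinfo(sim$genes))
  feats <- c(sim$genes, cen_gr)
  rtracklayer::export(feats, paths[["gff"]], format = "gff3")
  write_truth(sim$truth, paths[["truth"]])
  invisible(paths)
}

#' Write / read planted truth as JSON
#' @param truth truth list from [generate_genome()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth$chromosomes <- lapply(truth$chromosomes, function(tc) {
    tc$elements <- as.data.frame(tc$elements, stringsAsFactors = FALSE)
    tc
  })
  truth$secondary_sites <- lapply(truth$secondary_sites, function(s) {
    s <- as.data.frame(s, stringsAsFactors = FALSE)
    if (nrow(s) == 0L) data.frame(chrom = character(0), pos = integer(0)) else s
  })
  truth
}

#' Read gene annotations from GFF3
#'
#' @param path GFF3 file.
#' @param feature_type feature type to keep (default "gene").
#' @return a [GenomicRanges::GRanges].
#' @export
read_genes_gff3 <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr[gr$type == feature_type]
}
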