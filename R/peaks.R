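## Binned coverage, ChIP/input enrichment, peak calling ------------------

#' A binned coverage track
#'
#' @param bins named list of non-negative per-bin count vectors, one per
#'   chromosome.
#' @param bin_size bin width in bp (shared by all chromosomes).
#' @return a `coverage_track` object.
#' @export
coverage_track <- function(bins, bin_size) {
  stop_if_not_scalar_count(bin_size, "bin_size")
  if (is.null(names(bins)) || any(names(bins) == ""))
    stop("bins must be a named list (one entry per chromosome)", call. = FALSE)
  for (chrom in names(bins)) {
    b <- bins[[chrom]]
    if (!is.numeric(b) || any(b < 0) || anyNA(b))
      stop(sprintf("counts for %s must be non-negative numbers", chrom), call. = FALSE)
  }
  structure(list(bins = bins, bin_size = as.integer(bin_size)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage track: %d chromosome(s), bin %d bp, %d bins total\n",
              length(x$bins), x$bin_size, sum(lengths(x$bins))))
  invisible(x)
}

#' Write / read a coverage track as bedGraph
#'
#' Four-column bedGraph, 0-based half-open, one line per bin.
#'
#' @param track a [coverage_track()].
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  n_bins <- lengths(track$bins)
  starts <- unlist(lapply(n_bins, function(n)
    (seq_len(n) - 1L) * track$bin_size + 1L), use.names = FALSE)
  gr <- GenomicRanges::GRanges(
    rep(names(track$bins), n_bins),
    IRanges::IRanges(start = starts, width = track$bin_size),
    score = as.numeric(unlist(track$bins, use.names = FALSE)))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_bedgraph
#' @param bin_size bin width used to re-expand runs of equal-valued bins that
#'   bedGraph writers may have merged.
#' @export
read_bedgraph <- function(path, bin_size) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  bins <- list()
  for (chrom in as.character(unique(GenomicRanges::seqnames(gr)))) {
    g <- gr[GenomicRanges::seqnames(gr) == chrom]
    g <- g[order(GenomicRanges::start(g))]
    starts <- GenomicRanges::start(g) - 1L
    widths <- GenomicRanges::width(g)
    if (any((starts %% bin_size) != 0L) || any(widths %% bin_size != 0L))
      stop("bedGraph intervals are not aligned to bin_size", call. = FALSE)
    n_bins <- (max(starts + widths)) %/% bin_size
    v <- rep(0, n_bins)
    for (i in seq_along(starts)) {
      b0 <- starts[i] %/% bin_size
      v[(b0 + 1L):(b0 + widths[i] %/% bin_size)] <- g$score[i]
    }
    bins[[chrom]] <- v
  }
  coverage_track(bins, bin_size)
}

#' Peak-calling parameters
#'
#' Thresholds are expressed as fold over the genome-wide median of the
#' smoothed enrichment, which is robust because enriched bins are a tiny
#' fraction of the genome.
#'
#' @param pseudocount added to both chip and input counts before the ratio.
#' @param smooth_bins centred moving-average window (odd).
#' @param primary_threshold fold over median for a primary peak.
#' @param secondary_threshold fold over median to enter a peak at all
#'   (must be below `primary_threshold`).
#' @param merge_gap bins: runs separated by at most this many sub-threshold
#'   bins are merged.
#' @param min_width bins: narrower regions are dropped.
#' @return a `peak_call_params` object.
#' @export
peak_call_params <- function(pseudocount = 1, smooth_bins = 11L,
                             primary_threshold = 4, secondary_threshold = 1.75,
                             merge_gap = 2L, min_width = 3L) {
  if (smooth_bins < 1L || smooth_bins %% 2L == 0L)
    stop("smooth_bins must be an odd positive integer", call. = FALSE)
  if (secondary_threshold >= primary_threshold)
    stop("secondary_threshold must be below primary_threshold", call. = FALSE)
  structure(list(pseudocount = pseudocount, smooth_bins = as.integer(smooth_bins),
                 primary_threshold = primary_threshold,
                 secondary_threshold = secondary_threshold,
                 merge_gap = as.integer(merge_gap), min_width = as.integer(min_width)),
            class = "peak_call_params")
}

.moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  h <- (k - 1L) %/% 2L
  ## centred moving average with edge shrinkage (partial windows at the ends)
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Compute smoothed ChIP/input enrichment
#'
#' Per bin, `(chip + pseudocount) / (input + pseudocount)`, then a centred
#' moving average over `smooth_bins` bins. Because the signal is a ratio,
#' depth differences between the chip and input libraries cancel to first
#' order; no additional library-size scaling is applied.
#'
#' @param chip,input [coverage_track()] objects with identical binning.
#' @param params a [peak_call_params()] (pseudocount and smoothing are used).
#' @return an `enrichment_track` object (list of per-bin ratios + bin_size).
#' @export
compute_enrichment <- function(chip, input, params = peak_call_params()) {
  stopifnot(inherits(chip, "coverage_track"), inherits(input, "coverage_track"))
  if (chip$bin_size != input$bin_size ||
      !setequal(names(chip$bins), names(input$bins)) ||
      !all(lengths(chip$bins)[names(input$bins)] == lengths(input$bins)))
    stop("chip and input tracks must share chromosomes, bin counts and bin_size",
         call. = FALSE)
  pc <- params$pseudocount
  ratios <- lapply(stats::setNames(names(chip$bins), names(chip$bins)), function(chrom) {
    r <- (chip$bins[[chrom]] + pc) / (input$bins[[chrom]] + pc)
    .moving_average(r, params$smooth_bins)
  })
  structure(list(ratios = ratios, bin_size = chip$bin_size),
            class = "enrichment_track")
}

#' Call enrichment peaks with primary/secondary tiers
#'
#' Maximal runs of bins above `secondary_threshold x` the genome-wide median
#' enrichment are merged across gaps of at most `merge_gap` bins and dropped
#' below `min_width` bins. A peak is primary when its maximum enrichment
#' reaches `primary_threshold x` the median. Summits are the leftmost argmax
#' bin's centre; peaks are returned sorted by area (sum of enrichment - 1)
#' descending.
#'
#' @param enrichment an enrichment track from [compute_enrichment()].
#' @param params a [peak_call_params()].
#' @return data.frame with columns chromosome, start, end (0-based half-open),
#'   summit, max_enrichment, area, tier, intergenic (NA until
#'   [classify_intergenic()] is applied).
#' @export
call_peaks <- function(enrichment, params = peak_call_params()) {
  stopifnot(inherits(enrichment, "enrichment_track"))
  all_vals <- unlist(enrichment$ratios, use.names = FALSE)
  if (length(all_vals) == 0L) stop("empty enrichment track", call. = FALSE)
  if (all(all_vals == all_vals[1L]) && all_vals[1L] == 0) {
    warning("all-zero enrichment track; no peaks called")
    return(.empty_peaks())
  }
  med <- stats::median(all_vals)
  thr_sec <- params$secondary_threshold * med
  thr_pri <- params$primary_threshold * med
  bs <- enrichment$bin_size

  rows <- list()
  for (chrom in names(enrichment$ratios)) {
    e <- enrichment$ratios[[chrom]]
    above <- e > thr_sec
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    segs <- data.frame(start = starts[r$values], end = ends[r$values])
    ## merge across small gaps
    if (nrow(segs) > 1L) {
      keep_open <- segs$start[-1L] - segs$end[-nrow(segs)] - 1L <= params$merge_gap
      grp <- cumsum(c(TRUE, !keep_open))
      segs <- do.call(rbind, lapply(split(segs, grp), function(s)
        data.frame(start = min(s$start), end = max(s$end))))
    }
    segs <- segs[segs$end - segs$start + 1L >= params$min_width, , drop = FALSE]
    for (i in seq_len(nrow(segs))) {
      b0 <- segs$start[i]; b1 <- segs$end[i]
      vals <- e[b0:b1]
      imax <- which.max(vals)  # leftmost argmax
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = chrom,
        start = (b0 - 1L) * bs, end = b1 * bs,
        summit = (b0 + imax - 2L) * bs + bs %/% 2L,
        max_enrichment = max(vals),
        area = sum(vals - 1),
        tier = if (max(vals) >= thr_pri) "primary" else "secondary",
        intergenic = NA,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(.empty_peaks())
  peaks <- do.call(rbind, rows)
  peaks <- peaks[order(-peaks$area), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

.empty_peaks <- function() {
  data.frame(chromosome = character(0), start = integer(0), end = integer(0),
             summit = integer(0), max_enrichment = numeric(0), area = numeric(0),
             tier = character(0), intergenic = logical(0),
             stringsAsFactors = FALSE)
}

#' Flag peaks whose summit is intergenic
#'
#' A summit is intergenic when it lies in no gene's half-open interval; a
#' summit exactly at a gene's (half-open) end coordinate is intergenic.
#'
#' @param peaks data.frame from [call_peaks()].
#' @param genes gene annotations as a [GenomicRanges::GRanges] (1-based).
#' @return the peaks data.frame with the `intergenic` column set (NA, with a
#'   warning, for peaks on chromosomes absent from the annotation).
#' @export
classify_intergenic <- function(peaks, genes) {
  if (nrow(peaks) == 0L) return(peaks)
  ann_chroms <- as.character(unique(GenomicRanges::seqnames(genes)))
  g_chrom <- as.character(GenomicRanges::seqnames(genes))
  g_start0 <- GenomicRanges::start(genes) - 1L   # 0-based half-open
  g_end0 <- GenomicRanges::end(genes)
  for (i in seq_len(nrow(peaks))) {
    chrom <- peaks$chromosome[i]
    if (!chrom %in% ann_chroms) {
      warning(sprintf("no annotations for %s; intergenic flag unknown", chrom))
      peaks$intergenic[i] <- NA
      next
    }
    s <- peaks$summit[i]
    hit <- g_chrom == chrom & g_start0 <= s & s < g_end0
    peaks$intergenic[i] <- !any(hit)
  }
  peaks
}

#' Summarise called peaks, optionally against planted truth
#'
#' @param peaks_by_factor named list of peak data.frames (one per factor).
#' @param truth optional planted truth from [generate_genome()].
#' @param match_distance bp: a peak matches a planted site when its summit is
#'   within this distance of the site centre.
#' @return list with `per_factor` (data.frame: factor, n_primary,
#'   n_secondary, single_peak_chromosomes, and when truth is given recall and
#'   precision of site recovery) and `chromosomes` (chromosome names seen).
#' @export
peak_summary <- function(peaks_by_factor, truth = NULL, match_distance = 300) {
  rows <- lapply(names(peaks_by_factor), function(factor) {
    p <- peaks_by_factor[[factor]]
    prim <- p[p$tier == "primary", , drop = FALSE]
    single <- if (nrow(prim)) sum(table(prim$chromosome) == 1L) else 0L
    row <- data.frame(factor = factor,
                      n_primary = sum(p$tier == "primary"),
                      n_secondary = sum(p$tier == "secondary"),
                      single_peak_chromosomes = single,
                      stringsAsFactors = FALSE)
    if (!is.null(truth)) {
      sites <- do.call(rbind, lapply(truth$chromosomes, function(tc)
        data.frame(chrom = tc$chrom, pos = (tc$cen_start + tc$cen_end) / 2)))
      sec <- truth$secondary_sites[[factor]]
      if (!is.null(sec) && nrow(sec))
        sites <- rbind(sites, data.frame(chrom = sec$chrom, pos = sec$pos))
      matched_site <- vapply(seq_len(nrow(sites)), function(k)
        any(p$chromosome == sites$chrom[k] &
              abs(p$summit - sites$pos[k]) <= match_distance), logical(1))
      matched_peak <- vapply(seq_len(nrow(p)), function(k)
        any(sites$chrom == p$chromosome[k] &
              abs(sites$pos - p$summit[k]) <= match_distance), logical(1))
      row$recall <- mean(matched_site)
      row$precision <- if (nrow(p)) mean(matched_peak) else NA_real_
    }
    row
  })
  list(per_factor = do.call(rbind, rows),
       chromosomes = sort(unique(unlist(lapply(peaks_by_factor,
                                               function(p) p$chromosome)))))
}

#' Write peaks as BED6+ with summit, tier and intergenic columns
#'
#' @param peaks data.frame from [call_peaks()].
#' @param path output file.
#' @param name track/factor name written in the BED name column.
#' @export
write_peaks_bed <- function(peaks, path, name = "peak") {
  df <- data.frame(chrom = peaks$chromosome, start = peaks$start, end = peaks$end,
                   name = name, score = round(100 * peaks$max_enrichment),
                   strand = ".", summit = peaks$summit, tier = peaks$tier,
                   intergenic = peaks$intergenic)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
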