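## Degenerate motif scanning, uniqueness, element mutagenesis ------------

#' Scan a genome for a degenerate IUPAC motif
#'
#' Every window is compared against the pattern with set-aware Hamming
#' semantics: a position mismatches when the subject base is outside the
#' code's base set (so one mismatch against `S` is meaningful). Both strands
#' are scanned by default; reverse-strand hits are reported at the forward
#' coordinates of the window start. Overlapping hits are all reported, and a
#' palindromic site yields two hits with distinct strand fields.
#'
#' @param genome named character vector or [Biostrings::DNAStringSet].
#' @param pattern IUPAC string (the motif).
#' @param max_mismatch maximum set-aware mismatches.
#' @param strands `"both"` or `"forward"`.
#' @param name motif label carried into the result.
#' @return data.frame of hits: chromosome, position (1-based forward start),
#'   strand, mismatches; sorted by (chromosome, position, strand).
#' @export
scan_genome <- function(genome, pattern, max_mismatch = 0L, strands = "both",
                        name = "motif") {
  strands <- match.arg(strands, c("both", "forward"))
  if (inherits(genome, "DNAStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  if (length(genome) == 0L) stop("genome is empty", call. = FALSE)
  pat <- assert_iupac(pattern)
  m <- length(pat)
  if (all(nchar(genome) < m)) {
    warning("pattern is longer than every chromosome; no hits possible")
    return(.empty_hits())
  }

  scan_one_strand <- function(chars5, pat_chars) {
    ## mismatch count per window start via shifted sums of per-position misses
    L <- length(chars5)
    n_win <- L - length(pat_chars) + 1L
    if (n_win <= 0L) return(integer(0))
    mism <- numeric(n_win)
    for (j in seq_along(pat_chars)) {
      miss <- !.iupac_allowed_matrix[pat_chars[j], chars5]
      mism <- mism + miss[j:(j + n_win - 1L)]
    }
    mism
  }

  rc_pattern <- strsplit(revcomp(pattern), "", fixed = TRUE)[[1L]]
  rows <- list()
  for (chrom in names(genome)) {
    s5 <- encode_seq5(genome[[chrom]])
    if (length(s5) < m) next
    fw <- scan_one_strand(s5, pat)
    hit <- which(fw <= max_mismatch)
    if (length(hit))
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = chrom, position = hit, strand = "+",
        mismatches = as.integer(fw[hit]), stringsAsFactors = FALSE)
    if (strands == "both") {
      ## a reverse-strand occurrence at forward window [p, p+m) is a forward
      ## match of the reverse-complemented pattern
      rv <- scan_one_strand(s5, rc_pattern)
      hit <- which(rv <= max_mismatch)
      if (length(hit))
        rows[[length(rows) + 1L]] <- data.frame(
          chromosome = chrom, position = hit, strand = "-",
          mismatches = as.integer(rv[hit]), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(.empty_hits())
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$chromosome, hits$position, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "motif") <- name
  attr(hits, "width") <- m
  hits
}

.empty_hits <- function() {
  structure(data.frame(chromosome = character(0), position = integer(0),
                       strand = character(0), mismatches = integer(0),
                       stringsAsFactors = FALSE),
            width = 0L)
}

#' Partition motif hits into centromeric and elsewhere
#'
#' A hit is "at a centromere" when its full match window intersects any of the
#' supplied intervals.
#'
#' @param hits data.frame from [scan_genome()].
#' @param intervals data.frame with chromosome/start/end columns, 0-based
#'   half-open.
#' @param width match width (taken from the hits attribute when present).
#' @return list with `counts` (`at_centromere`, `elsewhere`) and `hits` with
#'   an added logical `at_centromere` column.
#' @export
uniqueness_report <- function(hits, intervals, width = attr(hits, "width")) {
  if (nrow(hits) == 0L)
    return(list(counts = c(at_centromere = 0L, elsewhere = 0L), hits = hits))
  if (is.null(width)) stop("match width unknown; pass `width`", call. = FALSE)
  at <- vapply(seq_len(nrow(hits)), function(i) {
    h0 <- hits$position[i] - 1L       # 0-based window [h0, h0 + width)
    any(intervals$chromosome == hits$chromosome[i] &
          intervals$start < h0 + width & h0 < intervals$end)
  }, logical(1))
  hits$at_centromere <- at
  list(counts = c(at_centromere = sum(at), elsewhere = sum(!at)), hits = hits)
}

#' Parse a mutation specification like "21-23a"
#'
#' The window-frame naming used for element mutagenesis: 1-based inclusive
#' columns and a replacement base, e.g. `21-23a` replaces columns 21 to 23
#' with A. Accepts a hyphen or an en-dash and an optional space before the
#' base.
#'
#' @param text character scalar.
#' @return a `mutation_spec` list: start, end, base.
#' @export
parse_mutation_spec <- function(text) {
  norm <- gsub("–", "-", trimws(text))
  m <- regmatches(norm, regexec("^([0-9]+)-([0-9]+) ?([acgtACGT])$", norm))[[1L]]
  if (length(m) != 4L)
    stop(sprintf("cannot parse mutation spec '%s' (expected <int>-<int><base>)", text),
         call. = FALSE)
  start <- as.integer(m[2L]); end <- as.integer(m[3L])
  if (start > end)
    stop(sprintf("mutation spec '%s': start exceeds end", text), call. = FALSE)
  structure(list(start = start, end = end, base = toupper(m[4L])),
            class = "mutation_spec")
}

#' Apply a window-frame mutation to a sequence
#'
#' Replaces columns `start..end` with the specification's base; everything
#' else, and the length, is unchanged.
#'
#' @param window character scalar (the centromere window).
#' @param spec a [parse_mutation_spec()] result or a spec string.
#' @return mutated sequence.
#' @examples
#' apply_mutation("ACGTACGT", "3-4a")  # "ACAAACGT"
#' @export
apply_mutation <- function(window, spec) {
  if (is.character(spec)) spec <- parse_mutation_spec(spec)
  stopifnot(inherits(spec, "mutation_spec"))
  if (spec$end > nchar(window))
    stop(sprintf("mutation %d-%d%s is out of range for a %d-base window",
                 spec$start, spec$end, tolower(spec$base), nchar(window)),
         call. = FALSE)
  out <- window
  substr(out, spec$start, spec$end) <-
    paste(rep(spec$base, spec$end - spec$start + 1L), collapse = "")
  out
}

#' Write motif hits as BED6 (score = mismatch count)
#'
#' @param hits data.frame from [scan_genome()].
#' @param path output file.
#' @param width match width.
#' @export
write_hits_bed <- function(hits, path, width = attr(hits, "width")) {
  nm <- attr(hits, "motif")
  if (is.null(nm)) nm <- "motif"
  df <- data.frame(chrom = hits$chromosome, start = hits$position - 1L,
                   end = hits$position - 1L + width, name = nm,
                   score = hits$mismatches, strand = hits$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
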