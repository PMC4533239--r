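## Ungapped alignment, PFM construction and consensus annotation ---------

## Point-centromere consensus elements have fixed spacing, so candidate
## sequences are aligned without gaps: each sequence gets one integer offset
## and the objective is the summed per-column majority count.

.check_set <- function(sequences) {
  if (length(sequences) < 2L) stop("need at least two sequences", call. = FALSE)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must have unique names", call. = FALSE)
  invisible(sequences)
}

.seq_matrix <- function(sequences, offsets, window_length) {
  ## rows = sequences, columns = alignment columns, integer codes 1..4
  t(vapply(seq_along(sequences), function(i) {
    w <- substr(sequences[i], offsets[i] + 1L, offsets[i] + window_length)
    v <- encode_seq5(w)
    if (any(v == 5L))
      stop(sprintf("sequence '%s' has non-ACGT characters inside the aligned window",
                   names(sequences)[i]), call. = FALSE)
    v
  }, integer(window_length)))
}

.alignment_score <- function(mat) {
  ## sum over columns of the majority base count
  sum(apply(mat, 2L, function(col) max(tabulate(col, nbins = 4L))))
}

#' Ungapped anchor alignment of candidate centromere sequences
#'
#' Finds per-sequence offsets placing a `window_length`-column ungapped block
#' so that the total column-consensus score (sum over columns of the majority
#' base count) is maximal. When the product of offset choices is at most
#' `exact_limit` the search is exhaustive; otherwise the alignment is seeded
#' by anchoring every sequence on the most widely shared k-mer, remaining
#' sequences are added greedily against the growing profile, and leave-one-out
#' align-to-profile passes iterate until the offsets stop changing. Ties are
#' broken toward the
#' lexicographically smallest offset vector, so the result is deterministic.
#'
#' @param sequences named character vector (A/C/G/T), each at least
#'   `window_length` long.
#' @param window_length number of alignment columns.
#' @param exact_limit maximum number of offset tuples for the exhaustive
#'   branch.
#' @param max_passes cap on refinement passes.
#' @return list with `offsets` (0-based integer vector, named),
#'   `window_length`, and `score`.
#' @export
anchor_align <- function(sequences, window_length, exact_limit = 1e6,
                         max_passes = 20L) {
  .check_set(sequences)
  window_length <- as.integer(window_length)
  lens <- nchar(sequences)
  short <- lens < window_length
  if (any(short))
    stop(sprintf("sequence(s) shorter than the window: %s",
                 paste(names(sequences)[short], collapse = ", ")), call. = FALSE)
  n_off <- lens - window_length + 1L
  W <- window_length

  enc <- lapply(seq_along(sequences), function(i) {
    v <- encode_seq5(sequences[[i]])
    if (any(v == 5L))
      stop(sprintf("sequence '%s' has non-ACGT characters", names(sequences)[i]),
           call. = FALSE)
    v
  })
  ## all windows of sequence i as a W x n_off[i] integer matrix
  win_mat <- function(i) {
    idx <- outer(seq_len(W), 0:(n_off[i] - 1L), "+")
    matrix(enc[[i]][idx], nrow = W)
  }
  col_majority_sum <- function(mat_rows) {
    ## mat_rows: n x W matrix of base codes; returns the consensus score
    sum(apply(mat_rows, 2L, function(col) max(tabulate(col, nbins = 4L))))
  }
  windows_of <- function(offs) {
    t(vapply(seq_along(sequences), function(i)
      enc[[i]][(offs[i] + 1L):(offs[i] + W)], integer(W)))
  }

  if (prod(as.numeric(n_off)) <= exact_limit) {
    ## exhaustive search, lexicographic tuple order (first maximum found is
    ## the lexicographically smallest)
    best <- NULL; best_score <- -Inf
    offs <- rep(0L, length(sequences))
    repeat {
      sc <- col_majority_sum(windows_of(offs))
      if (sc > best_score) { best_score <- sc; best <- offs }
      k <- length(offs)
      while (k >= 1L) {
        if (offs[k] + 1L < n_off[k]) { offs[k] <- offs[k] + 1L; break }
        offs[k] <- 0L; k <- k - 1L
      }
      if (k < 1L) break
    }
    offsets <- best; score <- best_score
  } else {
    ## profile score of every offset of sequence i against counts `prof` (4 x W)
    best_offset_vs_profile <- function(i, prof) {
      Vm <- win_mat(i)
      sc <- colSums(matrix(prof[cbind(as.vector(Vm), rep(seq_len(W), ncol(Vm)))],
                           nrow = W))
      which.max(sc) - 1L  # leftmost maximum
    }
    profile_counts <- function(idx, offs) {
      mat <- t(vapply(idx, function(i)
        enc[[i]][(offs[i] + 1L):(offs[i] + W)], integer(W)))
      vapply(seq_len(W), function(c) tabulate(mat[, c], nbins = 4L), integer(4L))
    }

    ## seed: anchor on the most widely shared k-mer. Conserved elements make
    ## one short word recur across nearly all candidates, and anchoring on it
    ## is far more robust than seeding from a single sequence pair, whose
    ## best chance agreement in long AT-rich contexts can outscore the true
    ## signal.
    k <- min(8L, W)
    upper <- toupper(sequences)
    kmer_sets <- lapply(upper, function(s) {
      n_k <- nchar(s) - k + 1L
      unique(substring(s, seq_len(n_k), seq_len(n_k) + k - 1L))
    })
    support <- table(unlist(kmer_sets, use.names = FALSE))
    anchor <- names(support)[support == max(support)]
    anchor <- sort(anchor)[1L]                     # deterministic tie-break
    delta <- (W - k) %/% 2L                        # centre the word
    offsets <- rep(NA_integer_, length(sequences))
    for (i in seq_along(sequences)) {
      p <- regexpr(anchor, upper[[i]], fixed = TRUE)[1L]
      if (p > 0L)
        offsets[i] <- min(max(p - 1L - delta, 0L), lens[i] - W)
    }
    anchored <- which(!is.na(offsets))
    if (length(anchored) < 2L) {
      anchored <- order(lens, seq_along(lens))[1:2]
      offsets[anchored] <- 0L
    }
    for (i in setdiff(seq_along(sequences), anchored)) {
      prof <- profile_counts(anchored, offsets)
      offsets[i] <- best_offset_vs_profile(i, prof)
      anchored <- c(anchored, i)
    }
    for (pass in seq_len(max_passes)) {
      changed <- FALSE
      for (i in seq_along(sequences)) {
        prof <- profile_counts(setdiff(seq_along(sequences), i), offsets)
        o <- best_offset_vs_profile(i, prof)
        if (o != offsets[i]) { offsets[i] <- o; changed <- TRUE }
      }
      if (!changed) break
    }
    score <- col_majority_sum(windows_of(offsets))
  }
  names(offsets) <- names(sequences)
  list(offsets = offsets, window_length = W, score = score)
}

#' Build a position frequency matrix from an ungapped alignment
#'
#' @param sequences named character vector.
#' @param alignment result of [anchor_align()], or NULL when the sequences are
#'   already equal-length aligned windows.
#' @return a `pfm` object: 4 x L integer matrix (rows A, C, G, T) with
#'   attribute `n_sequences`.
#' @export
build_pfm <- function(sequences, alignment = NULL) {
  .check_set(sequences)
  if (is.null(alignment)) {
    if (length(unique(nchar(sequences))) != 1L)
      stop("without an alignment, sequences must be equal length", call. = FALSE)
    alignment <- list(offsets = rep(0L, length(sequences)),
                      window_length = nchar(sequences[[1L]]))
  }
  if (any(alignment$offsets + alignment$window_length > nchar(sequences)))
    stop("alignment window exceeds a sequence", call. = FALSE)
  mat <- .seq_matrix(sequences, alignment$offsets, alignment$window_length)
  counts <- vapply(seq_len(ncol(mat)), function(c)
    tabulate(mat[, c], nbins = 4L), integer(4L))
  rownames(counts) <- c("A", "C", "G", "T")
  structure(counts, n_sequences = length(sequences), class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("position frequency matrix: %d columns, %d sequences\n",
              ncol(x), attr(x, "n_sequences")))
  invisible(x)
}

#' Thresholds for consensus position classification
#'
#' Positions identical in all sequences are `invariant`; positions whose
#' majority base fraction falls in `[high_min, high_max]` are `high` (with ten
#' sequences, eight or nine identical); positions containing only A and T are
#' `at_only`; positions with a G+C fraction of at least `gc_rich_min` are
#' `gc_rich`; everything else is unclassified. Precedence: invariant > high >
#' at_only > gc_rich.
#'
#' @param invariant_min fraction for the invariant class.
#' @param high_min,high_max inclusive band for the high class.
#' @param gc_rich_min G+C fraction for the GC-rich class.
#' @param element_min_len minimum run (columns) of invariant/high positions
#'   reported as a consensus element.
#' @param core_min_run minimum classified-run length that anchors the core
#'   span; 1 makes the core span every classified column however isolated.
#' @return a `classify_thresholds` object.
#' @export
classify_thresholds <- function(invariant_min = 1.0, high_min = 0.80,
                                high_max = 0.90, gc_rich_min = 0.80,
                                element_min_len = 5L, core_min_run = 5L) {
  if (!(0 < high_min && high_min <= high_max && high_max < invariant_min &&
        invariant_min <= 1))
    stop("need 0 < high_min <= high_max < invariant_min <= 1", call. = FALSE)
  structure(list(invariant_min = invariant_min, high_min = high_min,
                 high_max = high_max, gc_rich_min = gc_rich_min,
                 element_min_len = as.integer(element_min_len),
                 core_min_run = as.integer(core_min_run)),
            class = "classify_thresholds")
}

#' Classify each alignment column by conservation and composition
#'
#' @param pfm a [build_pfm()] result.
#' @param thresholds a [classify_thresholds()].
#' @return character vector over columns with values `invariant`, `high`,
#'   `at_only`, `gc_rich`, `unclassified`.
#' @export
classify_positions <- function(pfm, thresholds = classify_thresholds()) {
  stopifnot(inherits(pfm, "pfm"))
  n <- attr(pfm, "n_sequences")
  vapply(seq_len(ncol(pfm)), function(c) {
    counts <- pfm[, c]
    maxf <- max(counts) / n
    gcf <- (counts[["C"]] + counts[["G"]]) / n
    if (maxf >= thresholds$invariant_min) "invariant"
    else if (maxf >= thresholds$high_min && maxf <= thresholds$high_max) "high"
    else if (counts[["C"]] == 0L && counts[["G"]] == 0L) "at_only"
    else if (gcf >= thresholds$gc_rich_min) "gc_rich"
    else "unclassified"
  }, character(1))
}

#' Derive a degenerate IUPAC consensus from a PFM
#'
#' Per column, the IUPAC code of the set of bases whose frequency is at least
#' `include_min`; an empty set gives `N`. The default 0.15 means that with ten
#' sequences a base must occur at least twice to enter the code, suppressing
#' singleton noise.
#'
#' @param pfm a [build_pfm()] result.
#' @param include_min inclusion frequency, in (0, 1).
#' @return IUPAC string over all columns.
#' @export
derive_degenerate_consensus <- function(pfm, include_min = 0.15) {
  stopifnot(inherits(pfm, "pfm"))
  if (!(include_min > 0 && include_min < 1))
    stop("include_min must lie in (0, 1)", call. = FALSE)
  n <- attr(pfm, "n_sequences")
  paste(vapply(seq_len(ncol(pfm)), function(c) {
    iupac_code_for(rownames(pfm)[pfm[, c] / n >= include_min])
  }, character(1)), collapse = "")
}

.runs_of <- function(flags) {
  ## data.frame of start/end (1-based inclusive) for TRUE runs
  if (!any(flags)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(flags)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Annotate a PFM: column classes, degenerate consensus, elements, core
#'
#' Elements are maximal runs of invariant/high columns of at least
#' `element_min_len` columns. The core spans from the first to the last
#' classified run of at least `core_min_run` columns (isolated
#' chance-classified columns in unconserved flanks do not stretch it).
#'
#' @param pfm a [build_pfm()] result.
#' @param thresholds a [classify_thresholds()].
#' @param include_min consensus inclusion frequency, see
#'   [derive_degenerate_consensus()].
#' @return a `consensus_annotation` list: `classes`, `degenerate`, `elements`
#'   (data.frame start/end/pattern, 1-based inclusive), `core` (c(start, end)
#'   or NULL, with a warning, when nothing is classified).
#' @export
annotate_consensus <- function(pfm, thresholds = classify_thresholds(),
                               include_min = 0.15) {
  classes <- classify_positions(pfm, thresholds)
  degenerate <- derive_degenerate_consensus(pfm, include_min)

  el_runs <- .runs_of(classes %in% c("invariant", "high"))
  el_runs <- el_runs[el_runs$end - el_runs$start + 1L >= thresholds$element_min_len, ,
                     drop = FALSE]
  elements <- if (nrow(el_runs)) {
    data.frame(start = el_runs$start, end = el_runs$end,
               pattern = vapply(seq_len(nrow(el_runs)), function(i)
                 substr(degenerate, el_runs$start[i], el_runs$end[i]), character(1)),
               stringsAsFactors = FALSE)
  } else data.frame(start = integer(0), end = integer(0), pattern = character(0))

  cl_runs <- .runs_of(classes != "unclassified")
  cl_runs <- cl_runs[cl_runs$end - cl_runs$start + 1L >= thresholds$core_min_run, ,
                     drop = FALSE]
  core <- if (nrow(cl_runs)) c(start = min(cl_runs$start), end = max(cl_runs$end))
  else {
    warning("no classified runs; core undefined")
    NULL
  }
  structure(list(classes = classes, degenerate = degenerate,
                 elements = elements, core = core),
            class = "consensus_annotation")
}

#' @export
print.consensus_annotation <- function(x, ...) {
  cat(sprintf("consensus annotation over %d columns\n", length(x$classes)))
  if (!is.null(x$core))
    cat(sprintf("  core: %d-%d (%d bp)\n", x$core[["start"]], x$core[["end"]],
                x$core[["end"]] - x$core[["start"]] + 1L))
  for (i in seq_len(nrow(x$elements)))
    cat(sprintf("  element %d: %d-%d  %s\n", i, x$elements$start[i],
                x$elements$end[i], x$elements$pattern[i]))
  invisible(x)
}

#' Merge two position frequency matrices column-wise
#'
#' Element-wise count addition; the merged matrix represents the union of the
#' two aligned sets (e.g. centromeres of two sister species).
#'
#' @param pfm_a,pfm_b [build_pfm()] results with equal column counts.
#' @return a `pfm`.
#' @export
merge_consensus <- function(pfm_a, pfm_b) {
  stopifnot(inherits(pfm_a, "pfm"), inherits(pfm_b, "pfm"))
  if (ncol(pfm_a) != ncol(pfm_b))
    stop("cannot merge PFMs with different column counts", call. = FALSE)
  out <- unclass(pfm_a) + unclass(pfm_b)
  structure(out, n_sequences = attr(pfm_a, "n_sequences") + attr(pfm_b, "n_sequences"),
            class = "pfm")
}

#' Write a PFM as JASPAR-style 4-row matrix text
#'
#' @param pfm a [build_pfm()] result.
#' @param path output file.
#' @param name motif name written in the header line.
#' @export
write_pfm_jaspar <- function(pfm, path, name = "consensus") {
  lines <- c(sprintf(">%s", name),
             vapply(c("A", "C", "G", "T"), function(b)
               sprintf("%s  [ %s ]", b, paste(pfm[b, ], collapse = " ")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read an aligned or unaligned candidate set from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_candidate_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
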