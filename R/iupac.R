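## IUPAC degenerate nucleotide alphabet ---------------------------------

#' IUPAC nucleotide codes and their base sets
#'
#' The fifteen degenerate DNA codes plus N. `S = {C,G}`, `K = {G,T}`,
#' `W = {A,T}`, `D = {A,G,T}` ("not C") and so on.
#'
#' @format a named list of character vectors (code -> base set).
#' @export
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Base set of a single IUPAC code
#' @param code single IUPAC letter.
#' @return character vector of concrete bases.
#' @export
iupac_base_set <- function(code) {
  s <- IUPAC_CODES[[toupper(code)]]
  if (is.null(s)) stop(sprintf("'%s' is not an IUPAC nucleotide code", code), call. = FALSE)
  s
}

#' IUPAC code for a set of bases
#' @param bases character vector drawn from A/C/G/T; empty set gives "N".
#' @return single IUPAC letter.
#' @export
iupac_code_for <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  if (length(bases) == 0L) return("N")
  key <- paste(bases, collapse = "")
  map <- c(A = "A", C = "C", G = "G", T = "T",
           AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
           CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N")
  code <- map[[key]]
  if (is.null(code)) stop("bases must be a subset of A/C/G/T", call. = FALSE)
  code
}

assert_iupac <- function(pattern, what = "pattern") {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  bad <- setdiff(chars, names(IUPAC_CODES))
  if (length(bad) > 0L)
    stop(sprintf("%s contains non-IUPAC characters: %s", what,
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  invisible(chars)
}

## 5-letter encoding used by the scanner: A=1 C=2 G=3 T=4 N=5.
.BASE5 <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)

encode_seq5 <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  idx <- .BASE5[chars]
  if (anyNA(idx))
    stop("sequence contains characters outside A/C/G/T/N", call. = FALSE)
  unname(idx)
}

## allowed[code_char, base5] -- TRUE when a subject base satisfies the code.
## Subject 'N' matches only pattern 'N' (an unknown base is never evidence
## for a motif).
.iupac_allowed_matrix <- local({
  m <- matrix(FALSE, nrow = length(IUPAC_CODES), ncol = 5L,
              dimnames = list(names(IUPAC_CODES), names(.BASE5)))
  for (code in names(IUPAC_CODES)) {
    m[code, IUPAC_CODES[[code]]] <- TRUE
    m[code, "N"] <- identical(code, "N")
  }
  m
})

## row-index lookup so pattern characters and base codes can be combined in
## one integer index matrix
.iupac_row <- stats::setNames(seq_along(names(IUPAC_CODES)), names(IUPAC_CODES))

#' Match a degenerate IUPAC pattern against an equal-length window
#'
#' A window matches when every base lies inside the base set of the
#' corresponding pattern code. A window `N` matches only a pattern `N`.
#'
#' @param pattern IUPAC string.
#' @param window sequence window over A/C/G/T/N, same length as `pattern`.
#' @return logical scalar.
#' @examples
#' iupac_match("SGGKTAA", "GGGGTAA")   # TRUE
#' iupac_match("SGGKTAA", "AGGGTAA")   # FALSE (A is not in S = {C,G})
#' @export
iupac_match <- function(pattern, window) {
  pat <- assert_iupac(pattern)
  win <- encode_seq5(window)
  if (length(pat) != length(win))
    stop("pattern and window must have equal length", call. = FALSE)
  all(.iupac_allowed_matrix[cbind(.iupac_row[pat], win)])
}

#' Per-position mismatch profile of a pattern against a window
#' @keywords internal
iupac_mismatch_count <- function(pattern, window) {
  pat <- assert_iupac(pattern)
  win <- encode_seq5(window)
  if (length(pat) != length(win))
    stop("pattern and window must have equal length", call. = FALSE)
  sum(!.iupac_allowed_matrix[cbind(.iupac_row[pat], win)])
}

#' Expand a degenerate pattern to all concrete A/C/G/T strings
#'
#' Used by test oracles; refuses astronomically large expansions.
#'
#' @param pattern IUPAC string.
#' @param max_expansions safety cap.
#' @return character vector of concrete patterns.
#' @export
iupac_expand <- function(pattern, max_expansions = 65536L) {
  chars <- assert_iupac(pattern)
  sets <- lapply(chars, iupac_base_set)
  n <- prod(vapply(sets, length, integer(1)))
  if (n > max_expansions)
    stop(sprintf("pattern expands to %g concrete strings (cap %d)", n, max_expansions),
         call. = FALSE)
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste, collapse = "")
}

#' Reverse complement of a possibly degenerate sequence
#' @param sequence IUPAC string.
#' @return character scalar.
#' @export
revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}
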