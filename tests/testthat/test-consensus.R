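test_that("identical sequences align at offset zero with a perfect score", {
  seqs <- stats::setNames(rep("ACGTACGTAA", 10), paste0("s", 1:10))
  aln <- anchor_align(seqs, window_length = 10L)
  expect_true(all(aln$offsets == 0L))
  expect_identical(aln$score, 10L * 10L)  # every column has consensus n
})

test_that("a small alignment matches the exhaustively enumerated optimum", {
  seqs <- c(a = "AACGTA", b = "ACGTAA", c = "CACGTT")
  aln <- anchor_align(seqs, window_length = 4L)
  expect_identical(unname(aln$offsets), c(1L, 0L, 1L))
  expect_identical(aln$score, 12L)  # "ACGT" three times
  ref <- oracle_align(seqs, 4L)
  expect_identical(unname(aln$offsets), ref$offsets)
  expect_identical(aln$score, as.integer(ref$score))
})

test_that("the exact branch equals exhaustive enumeration on random sets", {
  set.seed(23)
  for (trial in 1:40) {
    k <- sample(2:4, 1L)
    W <- sample(4:6, 1L)
    seqs <- stats::setNames(
      vapply(seq_len(k), function(i) random_dna_string(sample(W:12, 1L)),
             character(1)),
      paste0("s", seq_len(k)))
    aln <- anchor_align(seqs, window_length = W)
    ref <- oracle_align(seqs, W)
    expect_identical(aln$score, as.integer(ref$score))
    expect_identical(unname(aln$offsets), ref$offsets)
  }
})

test_that("sequences shorter than the window are reported by name", {
  expect_error(anchor_align(c(a = "ACGTACGT", b = "ACG"), 5L), "b")
})

test_that("planted windows are recovered from long embedding contexts", {
  model <- centromere_model()
  set.seed(31)
  offsets_true <- integer(10)
  seqs <- character(10)
  for (i in 1:10) {
    w <- sample_centromere(model)$sequence
    off <- sample(0:390, 1L)
    ctx <- random_dna_string(500, at = 0.6)
    substr(ctx, off + 1L, off + 110L) <- w
    offsets_true[i] <- off
    seqs[i] <- ctx
  }
  names(seqs) <- paste0("cand", 1:10)
  aln <- anchor_align(seqs, window_length = 110L)
  ## all windows recovered in the same planted frame: the alignment is free
  ## to settle on a common frame shift, but it must be identical across
  ## sequences and small enough that the conserved core stays in the window
  shift <- aln$offsets - offsets_true
  expect_true(all(shift == shift[1L]))
  expect_lte(abs(shift[1L]), 19L)
})

test_that("PFM counts are per-column base tallies that always sum to n", {
  seqs <- c(s1 = "AAG", s2 = "AAG", s3 = "ACG", s4 = "ATG", s5 = "ACC",
            s6 = "AGG")
  pfm <- build_pfm(seqs)
  expect_identical(unname(pfm[, 1L]), c(6L, 0L, 0L, 0L))
  expect_identical(unname(pfm["C", 2L]), 2L)
  expect_true(all(colSums(pfm) == 6L))
  set.seed(5)
  rnd <- stats::setNames(vapply(1:7, function(i) random_dna_string(12),
                                character(1)), paste0("r", 1:7))
  expect_true(all(colSums(build_pfm(rnd)) == 7L))
  expect_error(build_pfm(c(a = "ANG", b = "ACG")), "non-ACGT")
})

test_that("column classification follows the precedence rules", {
  ## columns: A10 | A9C1 | A8T2 | A5T5 | G5C4A1 | A7C3 | G6C4
  pfm <- structure(matrix(c(10, 0, 0, 0,
                            9, 1, 0, 0,
                            8, 0, 0, 2,
                            5, 0, 0, 5,
                            1, 4, 5, 0,
                            7, 3, 0, 0,
                            0, 4, 6, 0), nrow = 4,
                          dimnames = list(c("A", "C", "G", "T"), NULL)),
                   n_sequences = 10L, class = "pfm")
  cls <- classify_positions(pfm)
  expect_identical(cls, c("invariant", "high", "high", "at_only", "gc_rich",
                          "unclassified", "gc_rich"))
  ## each column receives exactly one class from the known vocabulary
  expect_true(all(cls %in% c("invariant", "high", "at_only", "gc_rich",
                             "unclassified")))
})

test_that("degenerate consensus includes exactly the frequent bases", {
  pfm <- structure(matrix(c(0, 4, 6, 0,
                            10, 0, 0, 0,
                            4, 0, 3, 3,
                            1, 0, 0, 9), nrow = 4,
                          dimnames = list(c("A", "C", "G", "T"), NULL)),
                   n_sequences = 10L, class = "pfm")
  expect_identical(derive_degenerate_consensus(pfm, 0.15), "SADT")
  ## monotone: raising include_min never enlarges a column's base set
  set.seed(3)
  seqs <- sample_centromere_set(centromere_model(), 10)
  p <- build_pfm(seqs)
  sizes <- function(im) {
    cons <- strsplit(derive_degenerate_consensus(p, im), "")[[1L]]
    vapply(cons, function(cd) length(iupac_base_set(cd)), integer(1))
  }
  s1 <- sizes(0.05); s2 <- sizes(0.15); s3 <- sizes(0.35)
  expect_true(all(s2 <= s1) && all(s3 <= s2))
})

test_that("annotation recovers the planted element and core layout", {
  set.seed(42)
  seqs <- sample_centromere_set(centromere_model(), 10)
  ann <- annotate_consensus(build_pfm(seqs))
  expect_identical(ann$elements$start, c(20L, 45L))
  expect_identical(ann$elements$end, c(26L, 52L))
  expect_identical(unname(ann$core["start"]), 20L)
  expect_identical(unname(ann$core["end"]), 89L)
})

test_that("element recovery holds at the designed rate across many sets", {
  ## one-sided exact binomial check of: recovery rate >= 99%
  model <- centromere_model()
  set.seed(1)
  n_trials <- 1000L
  hits <- 0L
  for (i in seq_len(n_trials)) {
    ann <- annotate_consensus(build_pfm(sample_centromere_set(model, 10)))
    ok <- nrow(ann$elements) == 2L &&
      identical(ann$elements$start, c(20L, 45L)) &&
      identical(ann$elements$end, c(26L, 52L))
    hits <- hits + ok
  }
  expect_gte(hits, stats::qbinom(0.001, n_trials, 0.99))
})

test_that("a featureless PFM yields no elements and an undefined core", {
  pfm <- structure(matrix(5L, nrow = 4, ncol = 8,
                          dimnames = list(c("A", "C", "G", "T"), NULL)),
                   n_sequences = 20L, class = "pfm")
  expect_warning(ann <- annotate_consensus(pfm), "core undefined")
  expect_identical(nrow(ann$elements), 0L)
  expect_null(ann$core)
})

test_that("merging PFMs adds counts and preserves the planted layout", {
  set.seed(8)
  model <- centromere_model()
  pa <- build_pfm(sample_centromere_set(model, 10))
  pb <- build_pfm(sample_centromere_set(model, 10))
  zero <- structure(matrix(0L, nrow = 4, ncol = ncol(pa),
                           dimnames = dimnames(pa)),
                    n_sequences = 0L, class = "pfm")
  expect_equal(unclass(merge_consensus(pa, zero)), unclass(pa))
  merged <- merge_consensus(pa, pb)
  expect_true(all(colSums(merged) == 20L))
  expect_identical(attr(merged, "n_sequences"), 20L)
  ## with n = 20 the "all but one" column sits at 0.95, so the high band is
  ## widened accordingly for the merged annotation
  thr <- classify_thresholds(high_max = 0.95)
  ann <- annotate_consensus(merged, thr)
  expect_identical(ann$elements$start, c(20L, 45L))
  expect_identical(ann$elements$end, c(26L, 52L))
  expect_error(merge_consensus(pa, build_pfm(c(a = "ACGT", b = "ACGT"))),
               "column counts")
})

test_that("PFMs serialise to JASPAR-style text", {
  set.seed(2)
  pfm <- build_pfm(sample_centromere_set(centromere_model(), 10))
  path <- withr::local_tempfile(fileext = ".txt")
  write_pfm_jaspar(pfm, path, name = "core")
  lines <- readLines(path)
  expect_identical(lines[1L], ">core")
  expect_length(lines, 5L)
  a_counts <- as.integer(strsplit(gsub(".*\\[ | \\]", "", lines[2L]), " ")[[1L]])
  expect_identical(a_counts, unname(pfm["A", ]))
})
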