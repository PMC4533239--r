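test_that("forward scanning finds degenerate matches at the right positions", {
  hits <- scan_genome(c(chr = "AAGGGGTAACC"), "SGGKTAA", max_mismatch = 0L,
                      strands = "forward")
  expect_identical(hits$position, 3L)
  expect_identical(hits$strand, "+")
  expect_identical(hits$mismatches, 0L)

  hits <- scan_genome(c(chr = "ACGT"), "NNN", strands = "forward")
  expect_identical(hits$position, c(1L, 2L))
})

test_that("a pattern longer than every chromosome warns and yields nothing", {
  expect_warning(h <- scan_genome(c(chr = "ACGT"), "ACGTACGT"), "longer")
  expect_identical(nrow(h), 0L)
})

test_that("scanning equals the expansion oracle on random genomes", {
  set.seed(61)
  patterns <- c("SGGKTAA", "ACGDDWWT", "WWSKA")
  for (trial in 1:12) {
    genome <- list(c1 = random_dna_string(sample(500:2000, 1L)),
                   c2 = random_dna_string(sample(200:800, 1L)))
    genome <- stats::setNames(as.character(genome), names(genome))
    for (pat in patterns) {
      got <- scan_genome(genome, pat, max_mismatch = 0L)
      ref <- oracle_scan_exact(genome, pat)
      expect_identical(got$chromosome, ref$chromosome)
      expect_identical(got$position, ref$position)
      expect_identical(got$strand, ref$strand)
    }
  }
})

test_that("mismatch-tolerant scanning equals the window oracle", {
  set.seed(77)
  for (trial in 1:6) {
    genome <- c(c1 = random_dna_string(400))
    for (mm in 0:2) {
      got <- scan_genome(genome, "SGGKTAA", max_mismatch = mm)
      ref <- oracle_scan_windows(genome, "SGGKTAA", max_mismatch = mm)
      expect_identical(got$position, ref$position)
      expect_identical(got$strand, ref$strand)
      expect_identical(got$mismatches, ref$mismatches)
    }
  }
})

test_that("mismatch counting agrees with Biostrings on ambiguous patterns", {
  set.seed(13)
  genome <- c(c1 = random_dna_string(3000))
  subject <- Biostrings::DNAString(genome[["c1"]])
  for (pat in c("SGGKTAA", "ACGDDWWT")) {
    for (mm in 0:1) {
      got <- scan_genome(genome, pat, max_mismatch = mm, strands = "forward")
      ref <- Biostrings::matchPattern(pat, subject, max.mismatch = mm,
                                      fixed = FALSE)
      expect_identical(got$position, Biostrings::start(ref))
    }
  }
})

test_that("reverse-strand hits mirror forward hits on the reverse complement", {
  set.seed(29)
  g <- random_dna_string(600)
  m <- 8L
  fwd_on_rc <- scan_genome(c(c1 = revcomp(g)), "ACGDDWWT", strands = "forward")
  rev_hits <- scan_genome(c(c1 = g), "ACGDDWWT")
  rev_hits <- rev_hits[rev_hits$strand == "-", ]
  mapped <- sort(nchar(g) - (rev_hits$position + m - 1L) + 1L)
  expect_identical(mapped, sort(fwd_on_rc$position))
})

test_that("uniqueness reports partition hits by interval overlap", {
  hits <- structure(data.frame(chromosome = c("c1", "c1"),
                               position = c(11L, 101L),
                               strand = "+", mismatches = 0L),
                    width = 10L)
  intervals <- data.frame(chromosome = "c1", start = 5L, end = 30L)
  rep <- uniqueness_report(hits, intervals)
  expect_identical(unname(rep$counts), c(1L, 1L))
  expect_identical(rep$hits$at_centromere, c(TRUE, FALSE))
  empty <- uniqueness_report(scan_genome(c(c1 = "AAAA"), "CCCC",
                                         strands = "forward"), intervals,
                             width = 4L)
  expect_identical(unname(empty$counts), c(0L, 0L))
})

test_that("the planted core consensus is unique to the centromeres", {
  fx <- default_fixture()
  pattern <- model_core_pattern(fx$model)
  expect_identical(nchar(pattern), 70L)
  hits <- scan_genome(fx$genome, pattern, max_mismatch = 0L)
  cens <- do.call(rbind, lapply(fx$truth$chromosomes, function(tc)
    data.frame(chromosome = tc$chrom, start = tc$cen_start, end = tc$cen_end)))
  rep <- uniqueness_report(hits, cens)
  expect_identical(unname(rep$counts[["elsewhere"]]), 0L)
  expect_identical(unname(rep$counts[["at_centromere"]]), 10L)
})

test_that("mutation specs parse the window-frame naming", {
  s <- parse_mutation_spec("21-23a")
  expect_identical(s$start, 21L); expect_identical(s$end, 23L)
  expect_identical(s$base, "A")
  expect_identical(parse_mutation_spec("45-47t")$base, "T")
  expect_identical(parse_mutation_spec("37-39 g")$base, "G")
  expect_identical(parse_mutation_spec("32–34c")$end, 34L)  # en-dash
  expect_error(parse_mutation_spec("23-21a"), "exceeds")
  expect_error(parse_mutation_spec("21..23a"), "cannot parse")
})

test_that("mutations replace exactly the named columns", {
  expect_identical(apply_mutation("ACGTACGT", "3-4a"), "ACAAACGT")
  expect_error(apply_mutation("ACGT", "5-6a"), "out of range")
  ## idempotent, and commutative for non-overlapping specs
  w <- "ACGTACGTACGT"
  expect_identical(apply_mutation(apply_mutation(w, "2-4c"), "2-4c"),
                   apply_mutation(w, "2-4c"))
  expect_identical(apply_mutation(apply_mutation(w, "2-4c"), "7-9g"),
                   apply_mutation(apply_mutation(w, "7-9g"), "2-4c"))
  expect_identical(nchar(apply_mutation(w, "2-4c")), nchar(w))
})

test_that("element mutations destroy exactly the targeted element matches", {
  model <- centromere_model()
  set.seed(1)
  killers_I <- c("21-23a", "24-26c")
  killer_II <- "45-47t"
  controls <- c("32-34c", "37-39g")
  for (i in 1:300) {
    w <- sample_centromere(model)$sequence
    for (mut in killers_I) {
      mw <- apply_mutation(w, mut)
      expect_false(iupac_match("SGGKTAA", substr(mw, 20, 26)))
      expect_true(iupac_match("ACGDDWWT", substr(mw, 45, 52)))
    }
    mw <- apply_mutation(w, killer_II)
    expect_true(iupac_match("SGGKTAA", substr(mw, 20, 26)))
    expect_false(iupac_match("ACGDDWWT", substr(mw, 45, 52)))
    for (mut in controls) {
      mw <- apply_mutation(w, mut)
      expect_true(iupac_match("SGGKTAA", substr(mw, 20, 26)))
      expect_true(iupac_match("ACGDDWWT", substr(mw, 45, 52)))
    }
  }
})

test_that("hits serialise to BED6 with mismatch scores", {
  hits <- scan_genome(c(chr = "AAGGGGTAACC"), "SGGKTAA", strands = "forward",
                      name = "NaCDEI")
  path <- withr::local_tempfile(fileext = ".bed")
  write_hits_bed(hits, path)
  fields <- strsplit(readLines(path), "\t")[[1L]]
  expect_identical(fields, c("chr", "2", "9", "NaCDEI", "0", "+"))
})
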