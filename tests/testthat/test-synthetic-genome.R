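test_that("a fully forced model produces its literal element sequence", {
  m <- forced_model()
  for (seed in 1:3)
    expect_identical(sample_centromere(m, seed = seed)$sequence, "ACGT")
})

test_that("model construction rejects inconsistent layouts", {
  expect_error(element_spec("x", 5, 3, "AA"), ">= start")
  expect_error(element_spec("x", 1, 3, "AAAA"), "length")
  expect_error(centromere_model(elements = list(
    element_spec("a", 20, 26, "SGGKTAA"),
    element_spec("b", 25, 32, "ACGDDWWT"))), "overlap")
  expect_error(centromere_model(elements = list(
    element_spec("a", 10, 16, "SGGKTAA"))), "outside the core")
  expect_error(centromere_model(window_length = 80), "core")
})

test_that("sampled windows always satisfy the element patterns", {
  m <- centromere_model()
  set.seed(7)
  for (i in 1:200) {
    s <- sample_centromere(m)
    expect_true(iupac_match("SGGKTAA", substr(s$sequence, 20, 26)))
    expect_true(iupac_match("ACGDDWWT", substr(s$sequence, 45, 52)))
    expect_identical(nchar(s$sequence), 110L)
  }
})

test_that("window sampling is seed-reproducible", {
  m <- centromere_model()
  expect_identical(sample_centromere(m, seed = 1)$sequence,
                   sample_centromere(m, seed = 1)$sequence)
  diffs <- vapply(2:6, function(s)
    sample_centromere(m, seed = 1)$sequence != sample_centromere(m, seed = s)$sequence,
    logical(1))
  expect_true(all(diffs))
})

test_that("at_content counts A and T over the full length", {
  expect_identical(at_content("ATAT"), 1.0)
  expect_identical(at_content("ACGT"), 0.5)
  expect_identical(at_content("AATACGTTTA"), 0.8)
  expect_lt(at_content("ANAT"), 1.0)  # N is not AT
  expect_error(at_content(""), "non-empty")
})

test_that("conventional CDEII spacers respect the strict AT bound", {
  cm <- conventional_cen_model()
  set.seed(11)
  for (i in 1:300) {
    s <- sample_cdeII(cm)
    expect_gt(at_content(s), cm$cdeII_min_at)
    expect_true(nchar(s) >= 70 && nchar(s) <= 170)
  }
  full <- sample_conventional_centromere(cm, seed = 5)
  expect_identical(full$sequence, paste0(full$cdeI, full$cdeII, full$cdeIII))
  expect_true(iupac_match(cm$cdeI_pattern, full$cdeI))
  expect_true(iupac_match(cm$cdeIII_pattern, full$cdeIII))
})

test_that("generated genomes respect dimensions and intergenic placement", {
  cfg <- synthetic_genome_config(n_chromosomes = 1L, chrom_length = 30000L,
                                 secondary_sites_per_factor = c(ndc80 = 0L),
                                 secondary_min_cen_distance = 8000L, seed = 3L)
  sim <- generate_genome(cfg)
  expect_length(sim$genome, 1L)
  expect_identical(Biostrings::width(sim$genome), 30000L)
  expect_gt(length(sim$genes), 0L)
  tc <- sim$truth$chromosomes$chr1
  expect_identical(tc$cen_end - tc$cen_start, 110L)
  ## the centromere overlaps no gene
  g0 <- GenomicRanges::start(sim$genes) - 1L
  g1 <- GenomicRanges::end(sim$genes)
  expect_false(any(g0 < tc$cen_end & tc$cen_start < g1))
  ## the planted window is present verbatim in the chromosome
  expect_identical(substr(as.character(sim$genome[[1]]), tc$cen_start + 1L,
                          tc$cen_end), tc$window_sequence)
})

test_that("a centromere cannot be planted into a too-narrow interval", {
  expect_error(generate_genome(
    synthetic_genome_config(cen_intergenic_length = 100L)), "shorter")
})

test_that("generation is deterministic and chromosome streams are independent", {
  cfg2 <- synthetic_genome_config(n_chromosomes = 2L, chrom_length = 40000L,
                                  secondary_min_cen_distance = 8000L, seed = 9L)
  cfg3 <- synthetic_genome_config(n_chromosomes = 3L, chrom_length = 40000L,
                                  secondary_min_cen_distance = 8000L, seed = 9L)
  a <- generate_genome(cfg2); b <- generate_genome(cfg2); c3 <- generate_genome(cfg3)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)
  ## adding a chromosome leaves existing chromosomes' draws untouched
  expect_identical(as.character(a$genome[["chr1"]]), as.character(c3$genome[["chr1"]]))
  expect_identical(a$truth$chromosomes$chr2$cen_start, c3$truth$chromosomes$chr2$cen_start)
})

test_that("the genome bundle round-trips through FASTA/GFF3/JSON", {
  cfg <- synthetic_genome_config(n_chromosomes = 2L, chrom_length = 40000L,
                                 secondary_min_cen_distance = 8000L, seed = 13L)
  sim <- generate_genome(cfg)
  dir <- withr::local_tempdir()
  paths <- write_genome_bundle(sim, dir)
  genome2 <- Biostrings::readDNAStringSet(paths[["fasta"]])
  expect_identical(as.character(genome2), as.character(sim$genome))
  genes2 <- read_genes_gff3(paths[["gff"]])
  expect_identical(length(genes2), length(sim$genes))
  expect_identical(GenomicRanges::start(genes2), GenomicRanges::start(sim$genes))
  expect_identical(genes2$ID, sim$genes$ID)
  truth2 <- read_truth(paths[["truth"]])
  expect_identical(truth2$chromosomes$chr1$cen_start,
                   sim$truth$chromosomes$chr1$cen_start)
  expect_identical(truth2$chromosomes$chr2$window_sequence,
                   sim$truth$chromosomes$chr2$window_sequence)
  ## writing twice is byte-identical
  dir2 <- withr::local_tempdir()
  paths2 <- write_genome_bundle(generate_genome(cfg), dir2)
  expect_identical(readLines(paths[["fasta"]]), readLines(paths2[["fasta"]]))
  expect_identical(readLines(paths[["truth"]]), readLines(paths2[["truth"]]))
})

test_that("coverage simulation matches its negative-binomial background", {
  fx <- default_fixture()
  cov <- simulate_coverage(fx$genome, fx$truth, "ndc80", fx$config$chip, seed = 1L)
  params <- fx$config$chip
  ## background bins: exclude +-3 peak_sd around every planted site
  bg <- unlist(lapply(names(cov$input$bins), function(chrom) {
    tc <- fx$truth$chromosomes[[chrom]]
    centers <- (seq_along(cov$chip$bins[[chrom]]) - 0.5) * params$bin_size
    keep <- abs(centers - (tc$cen_start + tc$cen_end) / 2) > 3 * params$peak_sd
    cov$chip$bins[[chrom]][keep]
  }))
  expect_lt(abs(mean(bg) / params$background_mean - 1), 0.05)
  ## input is pure background everywhere
  expect_lt(abs(mean(unlist(cov$input$bins)) / params$background_mean - 1), 0.05)
})

test_that("secondary sites are elevated and the near-flat limit is flat", {
  fx <- default_fixture()
  cov <- simulate_coverage(fx$genome, fx$truth, "ndc10", fx$config$chip, seed = 2L)
  params <- fx$config$chip
  sec <- fx$truth$secondary_sites$ndc10
  expect_identical(nrow(sec), 2L)
  for (i in seq_len(nrow(sec))) {
    b <- floor(sec$pos[i] / params$bin_size) + 1L
    expect_gte(mean(cov$chip$bins[[sec$chrom[i]]][(b - 1L):(b + 1L)]),
               2 * params$background_mean)
  }
  ## fold -> 1 limit: chip and input come from the same distribution
  flat <- chip_sim_params(peak_fold = 1 + 1e-9, secondary_fold = 1 + 1e-9)
  cov0 <- simulate_coverage(fx$genome, fx$truth, "cep3", flat, seed = 3L)
  expect_lt(abs(mean(unlist(cov0$chip$bins)) / mean(unlist(cov0$input$bins)) - 1),
            0.02)
})

test_that("coverage simulation rejects unknown factors", {
  fx <- default_fixture()
  expect_error(simulate_coverage(fx$genome, fx$truth, "nonesuch", fx$config$chip),
               "unknown factor")
})

test_that("the simulated reference breaks synteny at exactly the chosen loci", {
  fx <- default_fixture()
  ref <- simulate_reference(fx$truth, fx$genes, n_syntenic = 1L)
  ## every query gene appears exactly once in the reference order
  all_ref <- unlist(ref$ref_order, use.names = FALSE)
  expect_identical(sort(all_ref), sort(ref$orthologs$gene_a))
  expect_identical(anyDuplicated(all_ref), 0L)
  ## flanks of the intact centromere are adjacent in the reference
  intact <- fx$truth$chromosomes$chr10
  ch <- which(vapply(ref$ref_order, function(o)
    intact$flank_left %in% o, logical(1)))
  o <- ref$ref_order[[ch]]
  expect_identical(match(intact$flank_right, o) - match(intact$flank_left, o), 1L)
  ## flanks of a broken centromere are on different reference chromosomes
  broken <- fx$truth$chromosomes$chr1
  chl <- which(vapply(ref$ref_order, function(o) broken$flank_left %in% o, logical(1)))
  chr <- which(vapply(ref$ref_order, function(o) broken$flank_right %in% o, logical(1)))
  expect_false(chl == chr)
})
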