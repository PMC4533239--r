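## Shared fixtures and independent reference implementations (oracles).

## One default synthetic fixture per test run, built lazily and cached: the
## ten-chromosome study layout at a fixed seed.
.fixture_env <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (!is.null(.fixture_env$sim)) return(.fixture_env$sim)
  cfg <- synthetic_genome_config(seed = 42L)
  model <- centromere_model()
  sim <- generate_genome(cfg, model)
  .fixture_env$sim <- list(config = cfg, model = model, genome = sim$genome,
                           genes = sim$genes, truth = sim$truth)
  .fixture_env$sim
}

fixture_peaks <- function(factor) {
  key <- paste0("peaks_", factor)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  fx <- default_fixture()
  cov <- simulate_coverage(fx$genome, fx$truth, factor, fx$config$chip, seed = 42L)
  enr <- compute_enrichment(cov$chip, cov$input)
  pk <- classify_intergenic(call_peaks(enr), fx$genes)
  .fixture_env[[key]] <- pk
  pk
}

## tiny centromere model whose output is fully forced (no degeneracy)
forced_model <- function() {
  centromere_model(window_length = 4L,
                   elements = list(element_spec("e1", 1L, 4L, "ACGT")),
                   core_start = 1L, core_end = 4L)
}

random_dna_string <- function(n, at = 0.5) {
  p <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## ---- oracle: peak calling by explicit scan ---------------------------

## Independent re-derivation of the caller contract: threshold every bin
## against the genome-wide median, merge runs across small gaps explicitly,
## drop narrow regions, tier by max enrichment.
brute_force_peaks <- function(enrichment, params) {
  vals <- unlist(enrichment$ratios, use.names = FALSE)
  med <- median(vals)
  rows <- list()
  for (chrom in names(enrichment$ratios)) {
    e <- enrichment$ratios[[chrom]]
    above <- which(e > params$secondary_threshold * med)
    if (length(above) == 0L) next
    ## group bins whose gaps are <= merge_gap
    grp <- cumsum(c(1L, diff(above) > params$merge_gap + 1L))
    for (g in split(above, grp)) {
      b0 <- min(g); b1 <- max(g)
      if (b1 - b0 + 1L < params$min_width) next
      vals_g <- e[b0:b1]
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = chrom,
        start = (b0 - 1L) * enrichment$bin_size,
        end = b1 * enrichment$bin_size,
        summit = (b0 + which.max(vals_g) - 2L) * enrichment$bin_size +
          enrichment$bin_size %/% 2L,
        max_enrichment = max(vals_g),
        tier = if (max(vals_g) >= params$primary_threshold * med) "primary"
               else "secondary",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), summit = integer(0),
                      max_enrichment = numeric(0), tier = character(0)))
  df <- do.call(rbind, rows)
  df[order(df$chromosome, df$start), , drop = FALSE]
}

make_enrichment <- function(ratios, bin_size = 50L) {
  structure(list(ratios = ratios, bin_size = as.integer(bin_size)),
            class = "enrichment_track")
}

## ---- oracle: exhaustive ungapped alignment ---------------------------

oracle_align <- function(sequences, window_length) {
  n_off <- nchar(sequences) - window_length + 1L
  grid <- do.call(expand.grid, lapply(rev(n_off), function(k) 0:(k - 1L)))
  grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]
  ## expand.grid varies the first column fastest; after reversal the LAST
  ## offset varies fastest, i.e. rows come in lexicographic order.
  best <- NULL; best_score <- -Inf
  for (r in seq_len(nrow(grid))) {
    offs <- as.integer(grid[r, ])
    wins <- vapply(seq_along(sequences), function(i)
      substr(sequences[[i]], offs[i] + 1L, offs[i] + window_length), character(1))
    chars <- do.call(rbind, strsplit(wins, ""))
    sc <- sum(apply(chars, 2L, function(col) max(table(col))))
    if (sc > best_score) { best_score <- sc; best <- offs }
  }
  list(offsets = best, score = best_score)
}

## ---- oracle: motif scan by pattern expansion -------------------------

oracle_scan_exact <- function(genome, pattern) {
  variants <- iupac_expand(pattern, max_expansions = 4096L)
  rows <- list()
  for (chrom in names(genome)) {
    s <- genome[[chrom]]
    for (strand in c("+", "-")) {
      pat_set <- if (strand == "+") variants else vapply(variants, revcomp, character(1))
      for (v in unique(pat_set)) {
        ## lookahead so overlapping occurrences are all reported
        found <- gregexpr(paste0("(?=", v, ")"), s, perl = TRUE)[[1L]]
        found <- found[found > 0L]
        for (p in found)
          rows[[length(rows) + 1L]] <- data.frame(
            chromosome = chrom, position = as.integer(p), strand = strand,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(chromosome = character(0), position = integer(0),
                      strand = character(0)))
  df <- unique(do.call(rbind, rows))
  df <- df[order(df$chromosome, df$position, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## overlapping fixed-string matches (gregexpr reports non-overlapping for
## repeated patterns only when matches overlap themselves; guard with a
## manual window scan instead)
oracle_scan_windows <- function(genome, pattern, max_mismatch = 0L) {
  m <- nchar(pattern)
  codes <- strsplit(toupper(pattern), "")[[1L]]
  sets <- lapply(codes, iupac_base_set)
  rc <- revcomp(pattern)
  rc_sets <- lapply(strsplit(rc, "")[[1L]], iupac_base_set)
  rows <- list()
  for (chrom in names(genome)) {
    chars <- strsplit(genome[[chrom]], "")[[1L]]
    L <- length(chars)
    if (L < m) next
    for (p in 1:(L - m + 1L)) {
      win <- chars[p:(p + m - 1L)]
      mm_f <- sum(vapply(seq_len(m), function(k) !(win[k] %in% sets[[k]]), logical(1)))
      mm_r <- sum(vapply(seq_len(m), function(k) !(win[k] %in% rc_sets[[k]]), logical(1)))
      if (mm_f <= max_mismatch)
        rows[[length(rows) + 1L]] <- data.frame(chromosome = chrom, position = p,
                                                strand = "+", mismatches = mm_f)
      if (mm_r <= max_mismatch)
        rows[[length(rows) + 1L]] <- data.frame(chromosome = chrom, position = p,
                                                strand = "-", mismatches = mm_r)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(chromosome = character(0), position = integer(0),
                      strand = character(0), mismatches = integer(0)))
  df <- do.call(rbind, rows)
  df <- df[order(df$chromosome, df$position, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## ---- oracle: synteny status by full enumeration ----------------------

oracle_synteny_status <- function(locus, orthologs, ref_order, gap_tolerance) {
  if (is.na(locus$flank_left) || is.na(locus$flank_right)) return("ambiguous")
  place <- function(gene) {
    out <- list()
    for (o in orthologs$gene_b[orthologs$gene_a == gene])
      for (ch in names(ref_order)) {
        i <- which(ref_order[[ch]] == o)
        if (length(i)) out[[length(out) + 1L]] <- c(ch, i)
      }
    out
  }
  lefts <- place(locus$flank_left); rights <- place(locus$flank_right)
  if (length(lefts) == 0L || length(rights) == 0L) return("ambiguous")
  for (a in lefts) for (b in rights)
    if (a[1L] == b[1L] &&
        abs(as.integer(a[2L]) - as.integer(b[2L])) - 1L <= gap_tolerance)
      return("syntenic")
  "breakpoint"
}

## random toy genome pair for synteny trials
random_synteny_case <- function(n_genes = 30L) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  ## query: two chromosomes
  cut <- sample(5:(n_genes - 5L), 1L)
  query <- list(q1 = genes[1:cut], q2 = genes[(cut + 1L):n_genes])
  ## reference: random permutation blocks across 2-3 chromosomes
  perm <- sample(genes)
  k <- sample(2:3, 1L)
  bounds <- sort(sample(2:(n_genes - 1L), k - 1L))
  ref <- split(perm, cumsum(seq_len(n_genes) %in% (bounds + 1L)))
  names(ref) <- paste0("r", seq_along(ref))
  ## orthologs: identity, plus an occasional second copy mapping
  orth <- data.frame(gene_a = genes, gene_b = genes, stringsAsFactors = FALSE)
  if (runif(1) < 0.5) {
    dup <- sample(genes, 2L)
    orth <- rbind(orth, data.frame(gene_a = dup, gene_b = sample(genes, 2L)))
  }
  list(query = query, ref = ref, orth = orth)
}
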