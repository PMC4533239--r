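## Gene-order synteny classification of centromere loci ------------------

#' Build a gene order from gene annotations
#'
#' Genes are ordered by start coordinate within each chromosome.
#'
#' @param genes a [GenomicRanges::GRanges] with an `ID` column.
#' @return named list: chromosome -> character vector of gene IDs in order.
#' @export
gene_order_from_granges <- function(genes) {
  chroms <- as.character(unique(GenomicRanges::seqnames(genes)))
  out <- lapply(chroms, function(ch) {
    g <- genes[as.character(GenomicRanges::seqnames(genes)) == ch]
    g$ID[order(GenomicRanges::start(g))]
  })
  names(out) <- chroms
  ids <- unlist(out, use.names = FALSE)
  if (anyDuplicated(ids)) stop("gene IDs must be unique within a genome", call. = FALSE)
  out
}

#' Read a reference gene order from a 3-column TSV
#'
#' Columns: genome label, chromosome, comma-separated ordered gene list.
#'
#' @param path TSV file.
#' @return named list chromosome -> ordered gene IDs.
#' @export
read_gene_order_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("genome", "chrom", "genes"),
                          stringsAsFactors = FALSE)
  out <- lapply(df$genes, function(s) strsplit(s, ",", fixed = TRUE)[[1L]])
  names(out) <- df$chrom
  out
}

#' Write a gene order as a 3-column TSV
#' @param order named list chromosome -> ordered gene IDs.
#' @param path output file.
#' @param genome genome label for the first column.
#' @export
write_gene_order_tsv <- function(order, path, genome = "ref") {
  df <- data.frame(genome = genome, chrom = names(order),
                   genes = vapply(order, paste, character(1), collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Locate a centromere between its flanking genes
#'
#' @param chromosome chromosome name.
#' @param start,end centromere interval, 0-based half-open.
#' @param genes gene [GenomicRanges::GRanges] (1-based).
#' @return a `centromere_locus` list: chromosome, flank_left, flank_right
#'   (gene IDs; NA with a warning when the centromere has no gene on one
#'   side).
#' @export
locate_centromere <- function(chromosome, start, end, genes) {
  sel <- as.character(GenomicRanges::seqnames(genes)) == chromosome
  if (!any(sel)) {
    warning(sprintf("no annotations for %s; locus ambiguous", chromosome))
    return(structure(list(chromosome = chromosome, flank_left = NA_character_,
                          flank_right = NA_character_), class = "centromere_locus"))
  }
  g <- genes[sel]
  g <- g[order(GenomicRanges::start(g))]
  s0 <- GenomicRanges::start(g) - 1L
  e0 <- GenomicRanges::end(g)
  left <- which(e0 <= start)
  right <- which(s0 >= end)
  fl <- if (length(left)) g$ID[max(left)] else NA_character_
  fr <- if (length(right)) g$ID[min(right)] else NA_character_
  if (is.na(fl)) warning(sprintf("centromere at %s:%d has no gene to its left",
                                 chromosome, start))
  if (is.na(fr)) warning(sprintf("centromere at %s:%d has no gene to its right",
                                 chromosome, start))
  structure(list(chromosome = chromosome, flank_left = fl, flank_right = fr),
            class = "centromere_locus")
}

.orth_of <- function(gene, orthologs) {
  orthologs$gene_b[orthologs$gene_a == gene]
}

.ref_position <- function(gene, ref_order) {
  for (ch in names(ref_order)) {
    i <- match(gene, ref_order[[ch]])
    if (!is.na(i)) return(c(chrom = ch, index = i))
  }
  NULL
}

#' Classify a centromere locus as syntenic or a breakpoint
#'
#' The locus is syntenic when some ortholog of the left flank and some
#' ortholog of the right flank (post-WGD genes may each have up to two
#' copies; the semantics are existential over all pairings) lie on one
#' reference chromosome with at most `gap_tolerance` intervening genes,
#' orientation-agnostic. It is a breakpoint when both flanks have reference
#' orthologs but no pairing satisfies this, and ambiguous when a flank is
#' missing or has no ortholog placed in the reference order.
#'
#' @param locus a [locate_centromere()] result.
#' @param orthologs data.frame with columns gene_a (query) and gene_b
#'   (reference).
#' @param ref_order named list chromosome -> ordered reference gene IDs.
#' @param ref_centromeres optional data.frame chrom/after marking reference
#'   centromeres lying after `after` genes on their chromosome.
#' @param gap_tolerance maximum number of intervening reference genes.
#' @return a `synteny_call` list: locus fields, status
#'   (syntenic/breakpoint/ambiguous), partner_chrom, partner_left,
#'   partner_right, gap, partner_has_centromere.
#' @export
classify_synteny <- function(locus, orthologs, ref_order,
                             ref_centromeres = NULL, gap_tolerance = 5L) {
  out <- list(chromosome = locus$chromosome, flank_left = locus$flank_left,
              flank_right = locus$flank_right, status = "ambiguous",
              partner_chrom = NA_character_, partner_left = NA_character_,
              partner_right = NA_character_, gap = NA_integer_,
              partner_has_centromere = NA)
  if (is.na(locus$flank_left) || is.na(locus$flank_right))
    return(structure(out, class = "synteny_call"))

  pos_of <- function(gene) {
    placed <- list()
    for (o in .orth_of(gene, orthologs)) {
      p <- .ref_position(o, ref_order)
      if (!is.null(p)) placed[[length(placed) + 1L]] <-
          list(gene = o, chrom = p[["chrom"]], index = as.integer(p[["index"]]))
    }
    placed
  }
  lefts <- pos_of(locus$flank_left)
  rights <- pos_of(locus$flank_right)
  if (length(lefts) == 0L || length(rights) == 0L)
    return(structure(out, class = "synteny_call"))

  best <- NULL
  for (a in lefts) for (b in rights) {
    if (a$chrom != b$chrom) next
    gap <- abs(a$index - b$index) - 1L
    if (gap <= gap_tolerance && (is.null(best) || gap < best$gap))
      best <- list(a = a, b = b, gap = gap)
  }
  if (is.null(best)) {
    out$status <- "breakpoint"
    return(structure(out, class = "synteny_call"))
  }
  out$status <- "syntenic"
  out$partner_chrom <- best$a$chrom
  out$partner_left <- best$a$gene
  out$partner_right <- best$b$gene
  out$gap <- best$gap
  if (!is.null(ref_centromeres)) {
    lo <- min(best$a$index, best$b$index)
    hi <- max(best$a$index, best$b$index)
    sel <- ref_centromeres$chrom == best$a$chrom &
      ref_centromeres$after >= lo & ref_centromeres$after < hi
    out$partner_has_centromere <- any(sel)
  }
  structure(out, class = "synteny_call")
}

#' Survey all centromere loci of a genome against a reference
#'
#' @param loci list of [locate_centromere()] results.
#' @param orthologs,ref_order,ref_centromeres,gap_tolerance see
#'   [classify_synteny()].
#' @return list with `calls` (data.frame, one row per locus) and `summary`
#'   (named counts: syntenic_with_ref_cen, syntenic_without_ref_cen,
#'   breakpoint, ambiguous).
#' @export
synteny_survey <- function(loci, orthologs, ref_order, ref_centromeres = NULL,
                           gap_tolerance = 5L) {
  calls <- lapply(loci, classify_synteny, orthologs = orthologs,
                  ref_order = ref_order, ref_centromeres = ref_centromeres,
                  gap_tolerance = gap_tolerance)
  df <- do.call(rbind, lapply(calls, function(x)
    data.frame(chromosome = x$chromosome, flank_left = x$flank_left,
               flank_right = x$flank_right, status = x$status,
               partner_chrom = x$partner_chrom, partner_left = x$partner_left,
               partner_right = x$partner_right, gap = x$gap,
               partner_has_centromere = x$partner_has_centromere,
               stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  syn <- df$status == "syntenic"
  with_cen <- syn & !is.na(df$partner_has_centromere) & df$partner_has_centromere
  summary <- c(syntenic_with_ref_cen = sum(with_cen),
               syntenic_without_ref_cen = sum(syn & !with_cen),
               breakpoint = sum(df$status == "breakpoint"),
               ambiguous = sum(df$status == "ambiguous"))
  list(calls = df, summary = summary)
}
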