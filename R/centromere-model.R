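## Generative models of point-centromere windows -------------------------

#' Specify a consensus DNA element inside a centromere window
#'
#' @param name element label, e.g. `"NaCDEI"`.
#' @param start,end 1-based inclusive columns within the centromere window.
#' @param pattern IUPAC string of length `end - start + 1`.
#' @return an `element_spec` object.
#' @examples
#' element_spec("NaCDEI", 20, 26, "SGGKTAA")
#' @export
element_spec <- function(name, start, end, pattern) {
  if (end < start) stop("element end must be >= start", call. = FALSE)
  assert_iupac(pattern, sprintf("element '%s' pattern", name))
  if (nchar(pattern) != end - start + 1L)
    stop(sprintf("element '%s': pattern length %d != span %d", name,
                 nchar(pattern), end - start + 1L), call. = FALSE)
  structure(list(name = name, start = as.integer(start), end = as.integer(end),
                 pattern = toupper(pattern)),
            class = "element_spec")
}

#' The two Naumovozyma consensus DNA elements
#'
#' NaCDEI is `SGGKTAA` at window columns 20-26 and NaCDEII is `ACGDDWWT` at
#' 45-52 (S: G or C; K: G or T; D: not C; W: A or T). A conserved third
#' element (NaCDEIII) exists but is dispensable for centromere function, so it
#' is not part of the default layout.
#'
#' @return list of two [element_spec()] objects.
#' @export
nacde_elements <- function() {
  list(element_spec("NaCDEI", 20L, 26L, "SGGKTAA"),
       element_spec("NaCDEII", 45L, 52L, "ACGDDWWT"))
}

#' Generative model of an unconventional point-centromere window
#'
#' The model describes a 110-bp window as a per-column composition profile:
#' consensus elements (highly conserved, degeneracy restricted to each
#' column's IUPAC set), A/T-only and G/C-only spacer columns inside the
#' conserved core (columns 20-89 by default), compositionally mixed "guard"
#' columns at the element and core boundaries (which is what makes the planted
#' boundaries identifiable from a finite sample), and unconstrained AT-rich
#' flank columns outside the core.
#'
#' @param window_length window size in bp.
#' @param elements list of [element_spec()]; must lie within the core and not
#'   overlap. Append an NaCDEIII-style element here to model it.
#' @param core_start,core_end 1-based columns bounding the conserved core.
#' @param spacer_at_fraction fraction of non-element, non-guard core columns
#'   that are A/T-only composition columns (the rest are G/C-only).
#' @param flank_at_fraction per-base probability that a flank position is A or
#'   T.
#' @param element_conservation probability that an element column shows its
#'   dominant base in any one centromere; the remainder is spread uniformly
#'   over the other bases of the column's IUPAC set.
#' @return a `centromere_model` object with a `column_profile` vector of
#'   per-column types (`flank`, `element`, `at`, `gc`, `mixed`).
#' @export
centromere_model <- function(window_length = 110L,
                             elements = nacde_elements(),
                             core_start = 20L, core_end = 89L,
                             spacer_at_fraction = 0.7,
                             flank_at_fraction = 0.85,
                             element_conservation = 0.99) {
  window_length <- as.integer(window_length)
  core_start <- as.integer(core_start); core_end <- as.integer(core_end)
  if (window_length < core_end || core_start < 1L || core_end < core_start)
    stop("window must contain the core and core_end >= core_start", call. = FALSE)
  if (spacer_at_fraction < 0 || spacer_at_fraction > 1 ||
      flank_at_fraction < 0 || flank_at_fraction > 1)
    stop("AT fractions must lie in [0, 1]", call. = FALSE)

  covered <- integer(0)
  for (el in elements) {
    if (!inherits(el, "element_spec")) stop("elements must be element_spec objects", call. = FALSE)
    if (el$start < core_start || el$end > core_end)
      stop(sprintf("element '%s' lies outside the core [%d, %d]",
                   el$name, core_start, core_end), call. = FALSE)
    span <- el$start:el$end
    if (any(span %in% covered))
      stop(sprintf("element '%s' overlaps another element", el$name), call. = FALSE)
    covered <- c(covered, span)
  }

  profile <- rep("flank", window_length)
  profile[core_start:core_end] <- "spacer"
  for (el in elements) profile[el$start:el$end] <- "element"

  ## Guard columns keep the planted boundaries identifiable from a finite
  ## sample. Columns flanking an element (inside the core) get uniform base
  ## composition, which minimises the chance that such a column lands in the
  ## invariant/high conservation band and extends an element run; columns just
  ## outside the core get an AT-leaning mixed composition, which minimises the
  ## chance of any classification at all (A/T-only, GC-rich or conserved) that
  ## would extend the core span.
  el_guards <- integer(0)
  for (el in elements) el_guards <- c(el_guards, el$start - 1L, el$end + 1L)
  edge_guards <- c(core_start - 1L, core_end + 1L)
  el_guards <- el_guards[el_guards >= 1L & el_guards <= window_length]
  edge_guards <- edge_guards[edge_guards >= 1L & edge_guards <= window_length]
  el_guards <- el_guards[profile[el_guards] != "element"]
  profile[el_guards] <- "mixed"
  profile[edge_guards] <- "edge"

  spacer_cols <- which(profile == "spacer")
  n_gc <- round((1 - spacer_at_fraction) * length(spacer_cols))
  profile[spacer_cols] <- "at"
  if (n_gc > 0L) {
    pick <- unique(round(seq(1L, length(spacer_cols), length.out = n_gc)))
    profile[spacer_cols[pick]] <- "gc"
  }

  structure(list(window_length = window_length, elements = elements,
                 core_start = core_start, core_end = core_end,
                 spacer_at_fraction = spacer_at_fraction,
                 flank_at_fraction = flank_at_fraction,
                 element_conservation = element_conservation,
                 column_profile = profile),
            class = "centromere_model")
}

#' @export
print.centromere_model <- function(x, ...) {
  cat(sprintf("centromere window model: %d bp, core %d-%d\n",
              x$window_length, x$core_start, x$core_end))
  for (el in x$elements)
    cat(sprintf("  element %-8s %3d-%3d  %s\n", el$name, el$start, el$end, el$pattern))
  tab <- table(factor(x$column_profile,
                      levels = c("element", "at", "gc", "mixed", "edge", "flank")))
  cat("  columns:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

## dominant base of an element column: alphabetically first member of the set.
.element_dominant <- function(code) iupac_base_set(code)[1L]

#' Sample one centromere window sequence from a model
#'
#' Every sampled sequence matches all element IUPAC patterns of the model (the
#' degeneracy of a code like `S` is realised as a rare minor allele, never as
#' a base outside the set).
#'
#' @param model a [centromere_model()].
#' @param seed optional integer seed (draws from the current RNG stream when
#'   NULL).
#' @return list with `sequence` (character), and `elements`: a data.frame of
#'   name/start/end/pattern/realized for each element.
#' @export
sample_centromere <- function(model, seed = NULL) {
  stopifnot(inherits(model, "centromere_model"))
  with_seed(seed, {
    n <- model$window_length
    bases <- character(n)
    prof <- model$column_profile
    fa <- model$flank_at_fraction
    flank_p <- c(A = fa / 2, C = (1 - fa) / 2, G = (1 - fa) / 2, T = fa / 2)
    edge_p <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
    acgt <- c("A", "C", "G", "T")
    for (i in seq_len(n)) {
      bases[i] <- switch(prof[i],
        at = sample(c("A", "T"), 1L),
        gc = sample(c("G", "C"), 1L),
        mixed = sample(acgt, 1L),
        edge = sample(acgt, 1L, prob = edge_p),
        flank = sample(acgt, 1L, prob = flank_p[acgt]),
        element = NA_character_)
    }
    for (el in model$elements) {
      codes <- strsplit(el$pattern, "", fixed = TRUE)[[1L]]
      for (j in seq_along(codes)) {
        set <- iupac_base_set(codes[j])
        dom <- set[1L]
        if (length(set) == 1L || stats::runif(1) < model$element_conservation) {
          bases[el$start + j - 1L] <- dom
        } else {
          bases[el$start + j - 1L] <- sample(set[-1L], 1L)
        }
      }
    }
    seqchr <- paste(bases, collapse = "")
    eldf <- do.call(rbind, lapply(model$elements, function(el) {
      data.frame(name = el$name, start = el$start, end = el$end,
                 pattern = el$pattern,
                 realized = substr(seqchr, el$start, el$end),
                 stringsAsFactors = FALSE)
    }))
    list(sequence = seqchr, elements = eldf)
  })
}

#' Sample a set of centromere windows
#'
#' @param model a [centromere_model()].
#' @param n number of windows.
#' @param seed optional integer seed.
#' @return named character vector of sequences (`cen1`, `cen2`, ...).
#' @export
sample_centromere_set <- function(model, n = 10L, seed = NULL) {
  with_seed(seed, {
    out <- vapply(seq_len(n), function(i) sample_centromere(model)$sequence,
                  character(1))
    names(out) <- paste0("cen", seq_len(n))
    out
  })
}

#' Expected degenerate core pattern of a centromere model
#'
#' The IUPAC pattern over the core columns that every window sampled from the
#' model is guaranteed to match: element columns keep their codes, A/T-only
#' columns become `W`, G/C-only columns `S`, and mixed columns `N`. Scanning a
#' genome for this pattern operationalises the question of whether the overall
#' core consensus occurs anywhere outside the planted centromeres.
#'
#' @param model a [centromere_model()].
#' @return IUPAC string of length `core_end - core_start + 1`.
#' @export
model_core_pattern <- function(model) {
  prof <- model$column_profile
  out <- character(model$window_length)
  out[prof == "at"] <- "W"
  out[prof == "gc"] <- "S"
  out[prof %in% c("mixed", "edge", "flank")] <- "N"
  for (el in model$elements) {
    out[el$start:el$end] <- strsplit(el$pattern, "", fixed = TRUE)[[1L]]
  }
  paste(out[model$core_start:model$core_end], collapse = "")
}

## Conventional (CDEI/II/III) point centromeres --------------------------

#' Model of a conventional CDEI/II/III point centromere
#'
#' The CDEII spacer is a 70-170 bp AT-rich segment with AT content strictly
#' above `cdeII_min_at` (79% by default). The CDEI and CDEIII defaults are the
#' commonly cited consensus strings for conventional point centromeres from
#' the general literature; both are plain configuration values and can be
#' overridden.
#'
#' @param cdeI_pattern IUPAC string for CDEI.
#' @param cdeII_length_range inclusive bp range of the CDEII spacer.
#' @param cdeII_min_at strict lower bound on CDEII AT content.
#' @param cdeIII_pattern IUPAC string for CDEIII.
#' @param cdeII_at_fraction per-base A/T probability used when sampling the
#'   spacer (before the strict AT-content bound is enforced by resampling).
#' @return a `conventional_cen_model` object.
#' @export
conventional_cen_model <- function(cdeI_pattern = "RTCACRTG",
                                   cdeII_length_range = c(70L, 170L),
                                   cdeII_min_at = 0.79,
                                   cdeIII_pattern = "TGTTTTTGNTTTCCGAANNNNAAA",
                                   cdeII_at_fraction = 0.9) {
  if (cdeII_min_at < 0 || cdeII_min_at > 1) stop("cdeII_min_at must lie in [0,1]", call. = FALSE)
  rng <- as.integer(cdeII_length_range)
  if (length(rng) != 2L || rng[2L] < rng[1L] || rng[1L] <= 0L)
    stop("cdeII_length_range must be a non-empty positive range", call. = FALSE)
  assert_iupac(cdeI_pattern, "cdeI_pattern")
  assert_iupac(cdeIII_pattern, "cdeIII_pattern")
  structure(list(cdeI_pattern = toupper(cdeI_pattern),
                 cdeII_length_range = rng,
                 cdeII_min_at = cdeII_min_at,
                 cdeIII_pattern = toupper(cdeIII_pattern),
                 cdeII_at_fraction = cdeII_at_fraction),
            class = "conventional_cen_model")
}

#' Sample a CDEII spacer
#'
#' Length is uniform over the configured range; bases are i.i.d. with A/T
#' probability `cdeII_at_fraction`, resampled until the AT content is strictly
#' greater than `cdeII_min_at`.
#'
#' @param model a [conventional_cen_model()].
#' @param seed optional integer seed.
#' @return character scalar.
#' @export
sample_cdeII <- function(model, seed = NULL) {
  stopifnot(inherits(model, "conventional_cen_model"))
  with_seed(seed, {
    at <- model$cdeII_at_fraction
    p <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
    len <- sample(seq(model$cdeII_length_range[1L], model$cdeII_length_range[2L]), 1L)
    repeat {
      s <- paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
      if (at_content(s) > model$cdeII_min_at) return(s)
    }
  })
}

#' Sample a full conventional centromere sequence
#'
#' @param model a [conventional_cen_model()].
#' @param seed optional integer seed.
#' @return list with `sequence` and the realised `cdeI`, `cdeII`, `cdeIII`
#'   parts.
#' @export
sample_conventional_centromere <- function(model, seed = NULL) {
  stopifnot(inherits(model, "conventional_cen_model"))
  with_seed(seed, {
    realize <- function(pattern) {
      codes <- strsplit(pattern, "", fixed = TRUE)[[1L]]
      paste(vapply(codes, function(cd) {
        set <- iupac_base_set(cd)
        if (length(set) == 1L) set else sample(set, 1L)
      }, character(1)), collapse = "")
    }
    cdeI <- realize(model$cdeI_pattern)
    cdeII <- sample_cdeII(model)
    cdeIII <- realize(model$cdeIII_pattern)
    list(sequence = paste0(cdeI, cdeII, cdeIII),
         cdeI = cdeI, cdeII = cdeII, cdeIII = cdeIII)
  })
}

#' AT content of a sequence
#'
#' `(#A + #T) / length`; any other letter (including N) counts against the AT
#' fraction.
#'
#' @param sequence non-empty character scalar.
#' @return fraction in `[0, 1]`.
#' @examples
#' at_content("AATACGTTTA")  # 0.8
#' @export
at_content <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("sequence must be a single non-empty string", call. = FALSE)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  sum(chars %in% c("A", "T")) / length(chars)
}
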