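---
title: "Discovering unconventional point centromeres: models and methods"
author: "pointcen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering unconventional point centromeres: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pointcen)
```

## The problem

Budding yeasts of the family Saccharomycetaceae carry *point centromeres*:
short (roughly 120–200 bp), sequence-defined centromeres whose kinetochore
assembly is dictated by consensus DNA elements rather than by chromatin
state. The conventional layout is CDEI–CDEII–CDEIII, where CDEII is a
70–170 bp spacer with AT content strictly above 79%. *Naumovozyma
castellii* breaks this pattern: its centromeres are bound by the usual
kinetochore and CBF3 machinery (Cse4, Ndc10, Cep3, Ndc80) yet carry a
completely different pair of consensus elements, named NaCDEI (`SGGKTAA`;
S = G/C, K = G/T) and NaCDEII (`ACGDDWWT`; D = not C, W = A/T), embedded in
a 70-bp conserved core, and their chromosomal positions are mostly *not*
syntenic with the centromeres of related species — the signature of
centromere relocation through genome rearrangement rather than descent.

`pointcen` re-implements the computational chain behind such a discovery as
a reusable, tested pipeline:

1. **enrichment peaks** — call single dominant ChIP/input enrichment peaks
   per chromosome, tier them (primary/secondary) and test whether summits
   are intergenic;
2. **consensus model** — align candidate centromere sequences without gaps,
   build a position frequency matrix (PFM), classify columns, and emit a
   degenerate consensus with element and core spans;
3. **motif scan** — scan genomes for degenerate IUPAC patterns, report
   uniqueness relative to known centromeres, and apply the window-frame
   mutations used to test element function;
4. **synteny** — classify each centromere's flanking-gene interval as
   syntenic or a breakpoint against a reference gene order via ortholog
   adjacency;
5. **synthetic genome** — a first-class generator producing genomes,
   annotations, coverage tracks and machine-readable planted truth with the
   statistical structure the analysis assumes;
6. **pipeline** — one-call orchestration (`run_all()`) with a JSON run
   report, plus a thin command-line wrapper (`inst/scripts/pointcen`).

Raw sequencing data for the original study are not redistributable here, so
the synthetic module is the package's test bed: it emulates the study's
*conditions* (a ten-chromosome karyotype, one intergenic centromere per
chromosome, a 110-bp window with elements at columns 20–26 and 45–52 and a
conserved core at 20–89, AT-rich flanks, and per-factor extra binding
sites — one, two and six for the Cse4-, Ndc10- and Cep3-like factors) while
every algorithm operates on the standard file formats (FASTA, GFF3,
bedGraph, TSV, JSON) it would meet on real data.

## The centromere window model

`centromere_model()` describes a 110-bp window as a *per-column composition
profile*, i.e. a generative model of the aligned centromere set rather than
of a single sequence:

* **element columns** (20–26 and 45–52 by default) are highly conserved:
  each column has a dominant base shown with probability
  `element_conservation` (default 0.99) and minor alleles confined to the
  column's IUPAC set, so every sampled window matches `SGGKTAA` and
  `ACGDDWWT` by construction. High conservation is what the source
  description of these positions implies (identical in 100% or 80–90% of
  centromeres), and it is required for the element spans to be recoverable
  from ten sequences: a column sampled *uniformly* over a two-base set has
  only an ~11% chance of landing in the invariant/high conservation bands.
* **spacer columns** inside the core are fixed, position-specific
  composition classes: a fraction `spacer_at_fraction` (default 0.7) are
  A/T-only columns and the rest are G/C-only columns, placed
  deterministically. This mirrors the observed consensus, where the core is
  a mosaic of conserved, A/T-only and GC-rich positions.
* **guard columns** — the single column flanking each element inside the
  core, and the single column just outside each core boundary — are
  compositionally mixed (uniform, and AT-leaning at the core boundary).
  This is an identifiability device, and it is also what makes the planted
  truth *true*: the element boundary at column 20 is a real boundary
  precisely because column 19 is not conserved. Without mixed boundary
  columns, chance conservation in a ten-sequence sample extends element or
  core spans a few percent of the time.
* **flank columns** (1–19 and 90–110) are unconstrained AT-rich sequence:
  i.i.d. draws with per-base A/T probability `flank_at_fraction`
  (default 0.85).

With ten sequences, an AT-rich flank column is all-A/T by chance with
probability $0.85^{10} \approx 0.20$, so isolated "classified" columns in
the flanks are statistically unavoidable. The core span is therefore
defined robustly as the interval from the first to the last classified
*run* of at least `core_min_run` columns (default 5, the same minimum used
for elements); setting `core_min_run = 1` restores the naive
first-to-last-classified rule. With the default model this recovers the
planted 70-bp core; the naive rule would stretch it into the flanks almost
surely.

The conventional-centromere arm (`conventional_cen_model()`) samples
CDEI/CDEIII realisations from configurable IUPAC patterns (the defaults are
the commonly cited consensus strings for conventional point centromeres)
around a CDEII spacer of uniform length 70–170 bp whose AT content is
strictly above `cdeII_min_at = 0.79`, enforced by resampling.

```{r model}
model <- centromere_model()
model
set.seed(42)
cens <- sample_centromere_set(model, 10)
annotate_consensus(build_pfm(cens))
```

## Column classification

`classify_positions()` applies, in precedence order: **invariant** (majority
base fraction at least `invariant_min = 1.0`), **high** (majority fraction
within `[0.80, 0.90]` — with ten sequences, exactly 8 or 9 identical),
**at_only** (no G or C at all), **gc_rich** (G+C fraction at least 0.80),
else unclassified. The 80–90% band is inclusive at both ends. Note the band
is a *fraction* band: for a merged set of 20 sequences a 19/20 column
(0.95) falls between the high band and invariance; when annotating merged
sets, widen `high_max` to `(n-1)/n` if "all but one" should still count as
highly conserved.

Elements are maximal invariant/high runs of at least `element_min_len = 5`
columns — long enough that isolated conserved columns are not reported as
elements, short enough to catch the 7- and 8-column elements. The
degenerate consensus uses `include_min = 0.15`: with ten sequences a base
must occur at least twice to enter a column's IUPAC code, which suppresses
singleton noise while still recovering two-fold degenerate codes.

## Ungapped anchor alignment

Point-centromere elements have fixed spacing, so `anchor_align()` uses no
gaps: each sequence receives one offset, and the objective is the summed
per-column majority count. When the offset space is small (at most
`exact_limit = 1e6` tuples) the search is exhaustive, enumerated in
lexicographic order so ties break toward the smallest offset vector. For
realistic candidate sets (ten 400-bp windows) the search space is
astronomical; the alignment is then seeded by anchoring all sequences on
the most widely shared 8-mer (conserved elements make one such word recur
in nearly every candidate; ties break lexicographically), remaining
sequences are placed greedily against the growing profile, and
leave-one-out align-to-profile passes iterate to convergence (at most 20
passes). A sequence-pair seed was rejected: between two long AT-rich
contexts, the *best chance* agreement over all offset pairs can exceed the
true signal, while a ten-way shared word essentially cannot occur by
chance. The aligned frame is defined only up to a common shift; downstream
spans are reported in alignment columns.

## ChIP coverage simulation and peak calling

Coverage is simulated per bin (default 50 bp): input is negative binomial
with mean `background_mean = 100` and variance $m(1 + \alpha m)$ with
dispersion $\alpha = 0.05$; ChIP multiplies the background mean by a
Gaussian kernel $1 + (f - 1)\,e^{-d^2/2\sigma^2}$ around each bound site
($\sigma$ = `peak_sd` = 300 bp), with fold $f = 10$ at centromeres and
$f = 3$ at secondary sites. Secondary sites sit in intergenic intervals at
least 50 kb from any centromere and 5 kb apart, so the tier distinction is
exercised cleanly.

The caller smooths the pseudocounted ChIP/input ratio with a centred
11-bin moving average and thresholds against the genome-wide median
enrichment: peaks enter at `secondary_threshold = 1.75` and are *primary*
at `primary_threshold = 4`. These four numbers are a joint design: after
smoothing, the background enrichment noise has a relative standard
deviation of about $\sqrt{2(\alpha + 1/m)} / \sqrt{11} \approx 0.10$, so a
secondary site (smoothed summit about 2.7) sits several standard deviations
inside the (1.75, 4) band, a centromere (smoothed summit about 8.9) sits
far above it, and the global background maximum over ~40,000 bins stays
well below 1.75. A noisier simulation (dispersion 0.1) with a narrower
band (thresholds 3/2) leaves secondary summits only ~1–2 standard
deviations from the tier boundaries and misclassifies sites in a few
percent of runs, which would defeat exact recovery of the planted one, two
and six extra sites. Enrichment is a ratio, so chip/input depth differences
cancel; no further library-size scaling is applied (a documented
limitation — strong copy-number variation would still bias it). Intergenic
classification uses the summit only, matching the point-centromere logic;
a summit exactly at a gene's half-open end coordinate is intergenic.

## Motif scanning and mutations

`scan_genome()` compares every window against the pattern with *set-aware*
Hamming semantics: a position mismatches when the base falls outside the
IUPAC code's set, and an `N` in the subject matches only an `N` in the
pattern. Both strands are scanned by default, with reverse-strand hits
reported at forward coordinates; overlapping and palindromic hits are all
reported. Long patterns (the 70-bp core consensus from
`model_core_pattern()`) are scanned by per-window set comparison — the
expansion to concrete strings that the test oracles use is only feasible
for short motifs. Mutations use the window-frame naming of the
field (`21-23a` = columns 21–23 to A): `21-23a` and `24-26c` destroy the
NaCDEI match, `45-47t` destroys NaCDEII, and the inter-element controls
`32-34c` and `37-39g` destroy neither — a purely structural fact the test
suite verifies on a thousand sampled windows.

## Synteny classification

A centromere locus is its pair of immediately flanking genes. Against a
reference gene order, the locus is *syntenic* when some ortholog of the
left flank and some ortholog of the right flank lie on one reference
chromosome with at most `gap_tolerance` (default 5) intervening genes —
existential semantics over the up-to-two ortholog copies a post-WGD genome
provides, orientation-agnostic. It is a *breakpoint* when orthologs exist
but no pairing works, and *ambiguous* when a flank is missing or unplaced.
The default tolerance forgives small local rearrangements; set it to 0 for
the strict adjacency reading. `simulate_reference()` plants the
ground truth for this module by cutting the query gene order exactly at
centromeres and exchanging right arms cyclically between "broken"
chromosomes, so flanks of a broken centromere end up on different reference
chromosomes by construction; `n_syntenic` (default 1) centromeres keep
conserved gene order and a reference centromere between their flank
orthologs, reproducing the situation where exactly one centromere pair
shows complete synteny.

## What the synthetic data does and does not show

The generator reproduces the statistical structure the methods rely on:
single dominant enrichment per chromosome over overdispersed background,
conserved elements inside a classifiable core, AT-rich flanks, genome-wide
uniqueness of the core consensus, and gene-order breakpoints at
centromeres. It deliberately omits read-level artefacts (mappability, GC
bias, duplicates, fragment-length effects), diploidy, repetitive DNA and
real intergenic length distributions. Passing tests therefore demonstrate
the correctness of the algorithms under the stated model, not performance
on arbitrary real libraries; on real data the caller's thresholds and the
classifier's bands are the knobs to revisit.

Problem sizes are chosen so a full simulate-and-analyse round trip runs in
seconds to a couple of minutes on one core: ten chromosomes of 300 kb
(40,000 bins genome-wide) rather than megabase chromosomes; property-style
tests use hundreds of randomized small cases per invariant and a thousand
sampled windows for the mutation and recovery contracts. The
element-recovery rate is checked as a one-sided exact binomial test of the
designed ≥99% rate over 1000 sets, which is stable against sampling noise
at the true rate (~99.2%; the residual shortfall is the irreducible chance
that a mixed guard column lands in a conservation band).

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open internally and 1-based inclusive in GFF3
and in window-column numbering (so "positions 20–26" reads off directly).
All randomness flows from one root seed through labelled child streams
(`child_seed()`), so regenerating any object is bit-identical and adding a
chromosome does not shift the draws of the others. Summit and alignment
ties break leftmost/lexicographic; flat tracks yield no peaks; an all-zero
track warns and returns an empty result; a PFM with no classified runs has
an undefined core (with a warning) and no elements; pseudocounts keep
enrichment finite on zero-input bins.

## Known limitations

* The ungapped alignment cannot represent indels between centromeres; a
  centromere with a true insertion inside the core would misalign.
* The peak caller reports dominant enrichment, not calibrated significance;
  there are no p-values by design.
* The classifier's conservation bands are tuned to n ≈ 10–20 sequences;
  for much larger sets the fraction bands should be rethought in terms of
  counts.
* Synteny requires a given ortholog map; the package does not infer
  orthology.
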