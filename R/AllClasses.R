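#' @include fourCcall-package.R
NULL

## IUPAC nucleotide codes and the bases each matches. N is deliberately
## absent from every expansion used on the genome side: unplaced sequence
## must never create phantom restriction sites.
IUPAC_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Restriction enzyme specification
#'
#' A recognition site (IUPAC nucleotide string) together with the cut
#' position, expressed as an offset in bases from the start of the
#' recognition match. HindIII (A^AGCTT) has recognition `"AAGCTT"` and
#' `cutOffset = 1`; NlaIII (CATG^) has recognition `"CATG"` and
#' `cutOffset = 4`.
#'
#' @slot name enzyme name, free text.
#' @slot recognition IUPAC recognition site, length >= 4.
#' @slot cutOffset integer in `[0, nchar(recognition)]`.
#' @export
setClass("EnzymeSpec",
  representation(name = "character", recognition = "character",
                 cutOffset = "integer"))

setValidity("EnzymeSpec", function(object) {
  msg <- character()
  site <- toupper(object@recognition)
  if (length(site) != 1L || nchar(site) < 4L)
    msg <- c(msg, "recognition site must be a single string of length >= 4")
  else if (!all(strsplit(site, "")[[1]] %in% names(IUPAC_EXPAND)))
    msg <- c(msg, sprintf("invalid IUPAC code in recognition site '%s'", site))
  if (length(object@cutOffset) != 1L || is.na(object@cutOffset) ||
      object@cutOffset < 0L || object@cutOffset > nchar(site))
    msg <- c(msg, "cutOffset must lie in [0, nchar(recognition)]")
  if (length(msg)) msg else TRUE
})

#' 4C library design
#'
#' The experimental quantities that determine which 3C fragments are
#' observable: the primary (3C) enzyme, the secondary (4C trimming) enzyme,
#' an optional linearization enzyme, read and primer lengths, and the
#' size-selection bounds of the sequencing library.
#'
#' @slot primaryEnzyme,secondaryEnzyme [EnzymeSpec-class] objects.
#' @slot linearizationEnzyme an [EnzymeSpec-class] or `NULL` (annotation
#'   only; fragments containing its site are flagged, not excluded).
#' @slot readLength,primerLength,sizeMin,sizeMax,minMapLength integers, bases.
#' @export
setClass("LibraryDesign",
  representation(primaryEnzyme = "EnzymeSpec", secondaryEnzyme = "EnzymeSpec",
                 linearizationEnzyme = "ANY",
                 readLength = "integer", primerLength = "integer",
                 sizeMin = "integer", sizeMax = "integer",
                 minMapLength = "integer"))

setValidity("LibraryDesign", function(object) {
  msg <- character()
  if (!is.null(object@linearizationEnzyme) &&
      !is(object@linearizationEnzyme, "EnzymeSpec"))
    msg <- c(msg, "linearizationEnzyme must be an EnzymeSpec or NULL")
  if (object@sizeMin <= 0L || object@sizeMin > object@sizeMax)
    msg <- c(msg, "need 0 < sizeMin <= sizeMax")
  if (object@readLength <= 0L) msg <- c(msg, "readLength must be positive")
  if (object@primerLength < 0L) msg <- c(msg, "primerLength must be >= 0")
  if (object@minMapLength <= 0L) msg <- c(msg, "minMapLength must be positive")
  if (length(msg)) msg else TRUE
})

#' The 3C fragment database
#'
#' An ordered, chromosome-tiling set of restriction fragments of the primary
#' (3C library) enzyme, stored as a [GenomicRanges::GRanges] with metadata
#' columns `index` (0-based ordinal within its chromosome), `mappable`,
#' `end5` and `end3` (capturability of each fragment end under the library
#' design). Fragments tile each chromosome exactly: the first starts at
#' position 0, each fragment ends where the next begins, and the last ends
#' at the chromosome length. Coordinates are stored 1-based closed (GRanges
#' convention) in memory; all files written by the package use 0-based
#' half-open coordinates.
#'
#' @slot frags a `GRanges` with the metadata columns above and seqlengths set.
#' @export
setClass("FragmentMap", representation(frags = "GRanges"))

setValidity("FragmentMap", function(object) {
  gr <- object@frags
  need <- c("index", "mappable", "end5", "end3")
  if (!all(need %in% names(S4Vectors::mcols(gr))))
    return(sprintf("missing metadata column(s): %s",
                   paste(setdiff(need, names(S4Vectors::mcols(gr))), collapse = ", ")))
  sl <- GenomeInfoDb::seqlengths(gr)
  if (any(is.na(sl))) return("all seqlengths must be set")
  for (chr in GenomeInfoDb::seqlevels(gr)) {
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == chr]
    if (length(g) == 0L) next
    s <- GenomicRanges::start(g); e <- GenomicRanges::end(g)
    if (is.unsorted(s, strictly = TRUE))
      return(sprintf("fragments on %s not strictly ordered", chr))
    if (s[1L] != 1L || e[length(g)] != sl[[chr]] ||
        (length(g) > 1L && any(e[-length(g)] + 1L != s[-1L])))
      return(sprintf("fragments do not tile chromosome %s", chr))
    if (!identical(S4Vectors::mcols(g)$index, seq_along(g) - 1L))
      return(sprintf("fragment index not 0..n-1 on %s", chr))
  }
  bad <- with(as.data.frame(S4Vectors::mcols(gr)), mappable & !(end5 | end3))
  if (any(bad)) return("mappable fragment with neither end capturable")
  TRUE
})

#' Per-fragment 4C-Seq read counts
#'
#' Non-negative read counts parallel to the fragments of a
#' [FragmentMap-class], plus an `included` flag that realizes region
#' masking: the analysis set used for windows and for the shuffle pool is
#' the fragments that are both mappable and included. Masking toggles
#' `included` instead of deleting rows, so the fragment map keeps its
#' tiling invariant.
#'
#' @slot fmap the [FragmentMap-class] the counts are aligned to.
#' @slot counts integer vector, one entry per fragment.
#' @slot included logical vector, one entry per fragment.
#' @slot replicate,allele free-text labels (allele tags are opaque
#'   pass-through metadata).
#' @slot unassigned number of input reads not assigned to any fragment.
#' @export
setClass("CountTable",
  representation(fmap = "FragmentMap", counts = "integer",
                 included = "logical", replicate = "character",
                 allele = "character", unassigned = "integer"))

setValidity("CountTable", function(object) {
  n <- length(object@fmap@frags)
  msg <- character()
  if (length(object@counts) != n)
    msg <- c(msg, "counts length must equal number of fragments")
  if (length(object@included) != n)
    msg <- c(msg, "included length must equal number of fragments")
  if (any(is.na(object@counts)) || any(object@counts < 0L))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(object@unassigned) != 1L || object@unassigned < 0L)
    msg <- c(msg, "unassigned must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' Threshold-engine configuration
#'
#' @slot window sliding-window size W in mappable fragments (>= 1).
#' @slot fdr target empirical false discovery rate, in (0, 1).
#' @slot nPermutations number of count shuffles P (>= 1; 1000 recommended).
#' @slot topPercentile k: the final threshold is the smallest
#'   per-permutation cutoff within the top k percent of the cutoff
#'   distribution (5 recommended).
#' @slot mode `"percentile"` (per-permutation FDR, order-statistic
#'   threshold) or `"pooled_mean"` (comparator: permutation-averaged FDR).
#' @slot shuffleUnit `"vector"` (permute the per-fragment count vector) or
#'   `"read"` (rescatter each read independently).
#' @slot seed integer master seed; per-permutation streams are derived from
#'   (seed, chromosome, permutation index).
#' @export
setClass("ThresholdConfig",
  representation(window = "integer", fdr = "numeric",
                 nPermutations = "integer", topPercentile = "numeric",
                 mode = "character", shuffleUnit = "character",
                 seed = "integer"))

setValidity("ThresholdConfig", function(object) {
  msg <- character()
  if (object@window < 1L) msg <- c(msg, "window must be >= 1")
  if (!(object@fdr > 0 && object@fdr < 1)) msg <- c(msg, "fdr must be in (0,1)")
  if (object@nPermutations < 1L) msg <- c(msg, "nPermutations must be >= 1")
  if (!(object@topPercentile > 0 && object@topPercentile <= 100))
    msg <- c(msg, "topPercentile must be in (0,100]")
  if (!object@mode %in% c("percentile", "pooled_mean"))
    msg <- c(msg, "mode must be 'percentile' or 'pooled_mean'")
  if (!object@shuffleUnit %in% c("vector", "read"))
    msg <- c(msg, "shuffleUnit must be 'vector' or 'read'")
  if (length(msg)) msg else TRUE
})

#' Per-chromosome significance threshold
#'
#' The distribution of per-permutation cutoffs X and the final threshold T
#' (reads per window) for one chromosome, with diagnostics.
#'
#' @slot chrom chromosome name.
#' @slot threshold final threshold T, an integer >= 1. In percentile mode T
#'   is always an attained value of the X distribution.
#' @slot xDistribution integer vector of the P per-permutation cutoffs
#'   (percentile mode; length-0 in pooled-mean mode, where no per-
#'   permutation cutoff exists).
#' @slot config the [ThresholdConfig-class] used.
#' @slot diagnostics list: `nMappable`, `totalReads`, `nWindows`,
#'   `maxObservedSum`.
#' @export
setClass("ThresholdResult",
  representation(chrom = "character", threshold = "integer",
                 xDistribution = "integer", config = "ThresholdConfig",
                 diagnostics = "list"))

setValidity("ThresholdResult", function(object) {
  msg <- character()
  if (object@threshold < 1L) msg <- c(msg, "threshold must be >= 1")
  if (object@config@mode == "percentile" &&
      length(object@xDistribution) > 0L &&
      !(object@threshold %in% object@xDistribution))
    msg <- c(msg, "percentile-mode threshold must be an attained X value")
  if (length(msg)) msg else TRUE
})
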