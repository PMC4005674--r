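#' @include AllClasses.R
NULL

#' Accessors for fourCcall objects
#'
#' `fragments()` returns the fragment `GRanges`; `nFragments()` the number
#' of fragments (optionally per chromosome); `chromNames()` the chromosome
#' names; `mappableFragments()` the logical mappability vector;
#' `fragmentCounts()` the per-fragment counts; `analysisSet()` the logical
#' vector marking fragments in the analysis set (mappable and not masked
#' out); `threshold()` and `xDistribution()` the final threshold and the
#' per-permutation cutoff distribution of a [ThresholdResult-class].
#'
#' @param x a [FragmentMap-class], [CountTable-class] or
#'   [ThresholdResult-class], as appropriate.
#' @param chrom optional chromosome name to restrict to.
#' @return See the individual descriptions above.
#' @name accessors
#' @aliases fragments nFragments chromNames mappableFragments
#'   fragmentCounts analysisSet threshold xDistribution
NULL

#' @rdname accessors
#' @export
setGeneric("fragments", function(x, chrom = NULL) standardGeneric("fragments"))
#' @rdname accessors
#' @export
setGeneric("nFragments", function(x, chrom = NULL) standardGeneric("nFragments"))
#' @rdname accessors
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))
#' @rdname accessors
#' @export
setGeneric("mappableFragments", function(x, chrom = NULL)
  standardGeneric("mappableFragments"))
#' @rdname accessors
#' @export
setGeneric("fragmentCounts", function(x, chrom = NULL)
  standardGeneric("fragmentCounts"))
#' @rdname accessors
#' @export
setGeneric("analysisSet", function(x, chrom = NULL) standardGeneric("analysisSet"))
#' @rdname accessors
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))
#' @rdname accessors
#' @export
setGeneric("xDistribution", function(x) standardGeneric("xDistribution"))

.chromSubset <- function(gr, chrom) {
  if (is.null(chrom)) rep(TRUE, length(gr))
  else as.character(GenomicRanges::seqnames(gr)) == chrom
}

#' @rdname accessors
setMethod("fragments", "FragmentMap", function(x, chrom = NULL)
  x@frags[.chromSubset(x@frags, chrom)])
#' @rdname accessors
setMethod("fragments", "CountTable", function(x, chrom = NULL)
  fragments(x@fmap, chrom))
#' @rdname accessors
setMethod("nFragments", "FragmentMap", function(x, chrom = NULL)
  sum(.chromSubset(x@frags, chrom)))
#' @rdname accessors
setMethod("nFragments", "CountTable", function(x, chrom = NULL)
  nFragments(x@fmap, chrom))
#' @rdname accessors
setMethod("chromNames", "FragmentMap", function(x)
  GenomeInfoDb::seqlevels(x@frags))
#' @rdname accessors
setMethod("chromNames", "CountTable", function(x) chromNames(x@fmap))
#' @rdname accessors
setMethod("mappableFragments", "FragmentMap", function(x, chrom = NULL)
  S4Vectors::mcols(x@frags)$mappable[.chromSubset(x@frags, chrom)])
#' @rdname accessors
setMethod("mappableFragments", "CountTable", function(x, chrom = NULL)
  mappableFragments(x@fmap, chrom))
#' @rdname accessors
setMethod("fragmentCounts", "CountTable", function(x, chrom = NULL)
  x@counts[.chromSubset(x@fmap@frags, chrom)])
#' @rdname accessors
setMethod("analysisSet", "CountTable", function(x, chrom = NULL) {
  keep <- .chromSubset(x@fmap@frags, chrom)
  (x@included & S4Vectors::mcols(x@fmap@frags)$mappable)[keep]
})
#' @rdname accessors
setMethod("threshold", "ThresholdResult", function(x) x@threshold)
#' @rdname accessors
setMethod("xDistribution", "ThresholdResult", function(x) x@xDistribution)

setMethod("show", "EnzymeSpec", function(object) {
  site <- toupper(object@recognition)
  cat(sprintf("EnzymeSpec %s: %s^%s\n", object@name,
              substr(site, 1L, object@cutOffset),
              substr(site, object@cutOffset + 1L, nchar(site))))
})

setMethod("show", "LibraryDesign", function(object) {
  cat("LibraryDesign\n")
  cat("  primary enzyme:   ", object@primaryEnzyme@name, "\n")
  cat("  secondary enzyme: ", object@secondaryEnzyme@name, "\n")
  if (!is.null(object@linearizationEnzyme))
    cat("  linearization:    ", object@linearizationEnzyme@name, "\n")
  cat(sprintf("  read %d bp, primer %d bp, size selection [%d, %d] bp, min map %d bp\n",
              object@readLength, object@primerLength, object@sizeMin,
              object@sizeMax, object@minMapLength))
})

setMethod("show", "FragmentMap", function(object) {
  gr <- object@frags
  cat(sprintf("FragmentMap: %d fragments on %d chromosome(s); %d (%.1f%%) mappable\n",
              length(gr), length(GenomeInfoDb::seqlevels(gr)),
              sum(S4Vectors::mcols(gr)$mappable),
              if (length(gr)) 100 * mean(S4Vectors::mcols(gr)$mappable) else 0))
})

setMethod("show", "CountTable", function(object) {
  cat(sprintf("CountTable [%s%s]: %d fragments, %d reads assigned, %d unassigned, %d fragments in analysis set\n",
              object@replicate,
              if (nzchar(object@allele)) paste0("/", object@allele) else "",
              length(object@counts), sum(object@counts), object@unassigned,
              sum(object@included & S4Vectors::mcols(object@fmap@frags)$mappable)))
})

setMethod("show", "ThresholdConfig", function(object) {
  cat(sprintf("ThresholdConfig: W=%d, FDR<%g, P=%d, top %g%%, mode=%s, shuffle=%s, seed=%d\n",
              object@window, object@fdr, object@nPermutations,
              object@topPercentile, object@mode, object@shuffleUnit,
              object@seed))
})

setMethod("show", "ThresholdResult", function(object) {
  cat(sprintf("ThresholdResult %s: T = %d reads/window", object@chrom,
              object@threshold))
  if (length(object@xDistribution))
    cat(sprintf(" (X range %d-%d over %d permutations)",
                min(object@xDistribution), max(object@xDistribution),
                length(object@xDistribution)))
  cat("\n")
})
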