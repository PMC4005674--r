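#' Construct an enzyme specification
#'
#' @param name enzyme name (free text, used in reports).
#' @param recognition IUPAC recognition site, at least 4 bases.
#' @param cutOffset cut position in bases from the start of the recognition
#'   match, in `[0, nchar(recognition)]`.
#' @return An [EnzymeSpec-class].
#' @examples
#' hindIII <- enzymeSpec("HindIII", "AAGCTT", 1)
#' nlaIII  <- enzymeSpec("NlaIII", "CATG", 4)
#' @export
enzymeSpec <- function(name, recognition, cutOffset) {
  obj <- new("EnzymeSpec", name = as.character(name),
             recognition = toupper(as.character(recognition)),
             cutOffset = as.integer(cutOffset))
  validObject(obj)
  obj
}

#' Construct a 4C library design
#'
#' Collects the quantities that decide which fragment ends are observable:
#' a fragment end is capturable when the captured piece (primary-site
#' boundary to the nearest internal secondary-enzyme cut, `d` bases) is long
#' enough to align (`d >= minMapLength`) and the amplicon it produces falls
#' inside the size selection (`sizeMin <= d + primerLength <= sizeMax`).
#' Adapter lengths should be folded into `primerLength`.
#'
#' @param primaryEnzyme,secondaryEnzyme [EnzymeSpec-class] objects for the
#'   3C digestion and the 4C trimming digestion.
#' @param readLength sequencing read length, bases.
#' @param primerLength effective primer (plus adapter) length, bases.
#' @param sizeMin,sizeMax library size-selection bounds, bases.
#' @param linearizationEnzyme optional [EnzymeSpec-class]; fragments
#'   containing its site are annotated, not excluded, since its effect is
#'   viewpoint-specific.
#' @param minMapLength minimum capturable-piece length to be alignable.
#' @return A [LibraryDesign-class].
#' @export
libraryDesign <- function(primaryEnzyme, secondaryEnzyme, readLength,
                          primerLength, sizeMin, sizeMax,
                          linearizationEnzyme = NULL, minMapLength = 20) {
  obj <- new("LibraryDesign", primaryEnzyme = primaryEnzyme,
             secondaryEnzyme = secondaryEnzyme,
             linearizationEnzyme = linearizationEnzyme,
             readLength = as.integer(readLength),
             primerLength = as.integer(primerLength),
             sizeMin = as.integer(sizeMin), sizeMax = as.integer(sizeMax),
             minMapLength = as.integer(minMapLength))
  validObject(obj)
  obj
}

.asSequenceString <- function(sequence) {
  if (is(sequence, "DNAString") || is(sequence, "DNAStringSet"))
    sequence <- as.character(sequence)
  seq <- toupper(sequence)
  bad <- gsub("[ACGTN]", "", seq)
  if (any(nzchar(bad)))
    stop("sequence contains characters outside the A/C/G/T/N alphabet: ",
         paste(unique(strsplit(paste(bad, collapse = ""), "")[[1]]), collapse = ""))
  seq
}

.reverseComplementSite <- function(site) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(site)))
}

## Match an IUPAC site on the forward strand of seq, 0-based match starts.
## matchPattern(fixed = "subject") treats pattern degeneracy as wildcards;
## matches whose window contains N are dropped afterwards so that unplaced
## sequence never yields phantom sites.
.matchSite <- function(seq, site) {
  hits <- Biostrings::matchPattern(site, Biostrings::DNAString(seq),
                                   fixed = "subject")
  starts <- Biostrings::start(hits)
  if (length(starts)) {
    withN <- vapply(starts, function(s)
      grepl("N", substr(seq, s, s + nchar(site) - 1L), fixed = TRUE),
      logical(1))
    starts <- starts[!withN]
  }
  starts - 1L
}

#' In-silico restriction digestion of one sequence
#'
#' Returns the ordered cut positions (0-based, between-base coordinates) of
#' an enzyme on a sequence. Degenerate IUPAC codes in the recognition site
#' are honored; `N` in the sequence never matches. Palindromic sites are
#' matched on the forward strand only (equivalent to double-strand
#' matching); non-palindromic sites are additionally matched through the
#' reverse complement, with the cut mapped back to reference coordinates.
#' Overlapping matches are all reported.
#'
#' @param sequence a character string or `DNAString` over A/C/G/T/N.
#' @param enzyme an [EnzymeSpec-class].
#' @return Strictly increasing integer vector of cut positions; possibly
#'   empty.
#' @examples
#' digestSequence("GGAAGCTTCCAAGCTTGG", enzymeSpec("HindIII", "AAGCTT", 1))
#' @export
digestSequence <- function(sequence, enzyme) {
  stopifnot(is(enzyme, "EnzymeSpec"))
  validObject(enzyme)
  seq <- .asSequenceString(sequence)
  site <- enzyme@recognition
  len <- nchar(site)
  cuts <- .matchSite(seq, site) + enzyme@cutOffset
  rcSite <- .reverseComplementSite(site)
  if (!identical(rcSite, site)) {
    # minus-strand recognition: cut sits cutOffset bases from the site start
    # read 3'->5', i.e. len - cutOffset from the forward-strand match start
    rcCuts <- .matchSite(seq, rcSite) + (len - enzyme@cutOffset)
    cuts <- c(cuts, rcCuts)
  }
  sort(unique(as.integer(cuts)))
}
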