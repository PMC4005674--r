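.asGenome <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else if (is.character(genome)) {
    if (length(genome) == 1L && is.null(names(genome)) && file.exists(genome))
      return(.asGenome(Biostrings::readDNAStringSet(genome)))
    seqs <- genome
  } else stop("genome must be a DNAStringSet, a named character vector, ",
              "or a FASTA path")
  if (length(seqs) == 0L) return(character(0))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("every genome sequence must be named (chromosome name)")
  # FASTA record IDs are taken verbatim up to the first whitespace
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  vapply(seqs, .asSequenceString, character(1))
}

.newFragmentMap <- function(chrom, start0, end0, seqlens,
                            mappable = NULL, end5 = NULL, end3 = NULL) {
  n <- length(start0)
  if (is.null(mappable)) mappable <- rep(TRUE, n)
  if (is.null(end5)) end5 <- mappable
  if (is.null(end3)) end3 <- mappable
  index <- unlist(lapply(unname(table(factor(chrom, levels = unique(chrom)))),
                         function(k) seq_len(k) - 1L), use.names = FALSE)
  if (n == 0L) index <- integer()
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = names(seqlens)),
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    index = as.integer(index), mappable = as.logical(mappable),
    end5 = as.logical(end5), end3 = as.logical(end3))
  GenomeInfoDb::seqlengths(gr) <- seqlens
  obj <- new("FragmentMap", frags = gr)
  validObject(obj)
  obj
}

#' Build the 3C fragment database from a genome
#'
#' Digests every chromosome with the primary (3C library) enzyme and
#' returns the tiling fragment map: the intervals between consecutive cut
#' positions plus the leading and trailing intervals. Zero-length intervals
#' (from a cut at position 0, at the chromosome end, or coincident cuts)
#' are suppressed. Mappability flags are initialized to `TRUE`; run
#' [annotateMappability()] to set them from a [LibraryDesign-class].
#'
#' @param genome a `DNAStringSet`, a named character vector of sequences,
#'   or the path to a (multi-record) FASTA file. Record IDs are chromosome
#'   names.
#' @param primaryEnzyme an [EnzymeSpec-class].
#' @return A [FragmentMap-class].
#' @export
buildFragmentMap <- function(genome, primaryEnzyme) {
  seqs <- .asGenome(genome)
  seqs <- seqs[nchar(seqs) > 0L]
  if (length(seqs) == 0L) stop("empty genome: no chromosome of length > 0")
  pieces <- lapply(names(seqs), function(chr) {
    len <- nchar(seqs[[chr]])
    cuts <- digestSequence(seqs[[chr]], primaryEnzyme)
    b <- unique(c(0L, cuts[cuts > 0L & cuts < len], len))
    data.frame(chrom = chr, start0 = b[-length(b)], end0 = b[-1L])
  })
  df <- do.call(rbind, pieces)
  .newFragmentMap(df$chrom, df$start0, df$end0,
                  stats::setNames(nchar(seqs), names(seqs)))
}

#' Annotate fragment mappability under a 4C library design
#'
#' Examines both ends of every fragment. For an end, let `d` be the
#' distance in bases from that primary-site boundary to the nearest
#' secondary-enzyme cut strictly inside the fragment (undefined when the
#' fragment has no internal secondary site -- a "blind" fragment). The end
#' is capturable iff `d` is defined, `d >= minMapLength`, and
#' `sizeMin <= d + primerLength <= sizeMax`. A fragment is mappable iff
#' either end is capturable; blind fragments and fragments shorter than
#' `minMapLength` are unmappable. When the design names a linearization
#' enzyme, a `hasLinearizationSite` column is added (annotation only).
#'
#' @param fmap a [FragmentMap-class] built with `design@primaryEnzyme` on
#'   the same genome.
#' @param genome the genome the map was built from (same accepted forms as
#'   in [buildFragmentMap()]).
#' @param design a [LibraryDesign-class].
#' @return The annotated [FragmentMap-class].
#' @export
annotateMappability <- function(fmap, genome, design) {
  stopifnot(is(fmap, "FragmentMap"), is(design, "LibraryDesign"))
  validObject(design)
  seqs <- .asGenome(genome)
  gr <- fmap@frags
  mc <- S4Vectors::mcols(gr)
  hasLin <- if (is.null(design@linearizationEnzyme)) NULL else
    rep(FALSE, length(gr))
  for (chr in GenomeInfoDb::seqlevels(gr)) {
    sel <- which(as.character(GenomicRanges::seqnames(gr)) == chr)
    if (length(sel) == 0L) next
    if (!chr %in% names(seqs))
      stop("chromosome ", chr, " missing from the supplied genome")
    s0 <- GenomicRanges::start(gr)[sel] - 1L   # 0-based starts
    e0 <- GenomicRanges::end(gr)[sel]          # 0-based half-open ends
    cuts <- digestSequence(seqs[[chr]], design@secondaryEnzyme)
    # nearest internal cut per end: cuts c with s0 < c < e0
    iLo <- findInterval(s0, cuts) + 1L         # first cut > s0
    iHi <- findInterval(e0 - 1L, cuts)         # last cut <= e0 - 1, i.e. < e0
    hasInternal <- iLo <= iHi & iLo <= length(cuts)
    d5 <- ifelse(hasInternal, cuts[pmin(iLo, length(cuts))] - s0, NA_integer_)
    d3 <- ifelse(hasInternal, e0 - cuts[pmax(iHi, 1L)], NA_integer_)
    capturable <- function(d) {
      !is.na(d) & d >= design@minMapLength &
        d + design@primerLength >= design@sizeMin &
        d + design@primerLength <= design@sizeMax
    }
    longEnough <- (e0 - s0) >= design@minMapLength
    mc$end5[sel] <- capturable(d5) & longEnough
    mc$end3[sel] <- capturable(d3) & longEnough
    mc$mappable[sel] <- mc$end5[sel] | mc$end3[sel]
    if (!is.null(hasLin)) {
      lin <- digestSequence(seqs[[chr]], design@linearizationEnzyme)
      hasLin[sel] <- findInterval(e0 - 1L, lin) > findInterval(s0, lin)
    }
  }
  S4Vectors::mcols(gr) <- mc
  if (!is.null(hasLin)) S4Vectors::mcols(gr)$hasLinearizationSite <- hasLin
  out <- new("FragmentMap", frags = gr)
  validObject(out)
  out
}

.configHeader <- function(config) {
  if (length(config) == 0L) return(character())
  paste0("# ", names(config), "=", vapply(config, as.character, character(1)))
}

#' Read and write the fragment database
#'
#' The fragment table is tab-delimited text with columns `chrom`, `start`,
#' `end`, `index`, `mappable`, `end5`, `end3` (flags as 0/1), coordinates
#' 0-based half-open, `#` comment lines allowed. This file is the template
#' that per-fragment count tables (the "retab" format) are aligned to.
#'
#' @param fmap a [FragmentMap-class].
#' @param path file path.
#' @param config optional named list echoed into `#` header lines.
#' @return `readFragmentTable` returns a [FragmentMap-class];
#'   `writeFragmentTable` returns `path` invisibly.
#' @export
writeFragmentTable <- function(fmap, path, config = list()) {
  stopifnot(is(fmap, "FragmentMap"))
  gr <- fmap@frags
  mc <- S4Vectors::mcols(gr)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   index = mc$index, mappable = as.integer(mc$mappable),
                   end5 = as.integer(mc$end5), end3 = as.integer(mc$end3))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# fourCcall fragment database; coordinates 0-based half-open",
               .configHeader(config),
               paste(colnames(df), collapse = "\t")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

.readTabTable <- function(path, columns) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineNo <- which(keep)
  if (length(lineNo) == 0L) stop("no data lines in ", path)
  # drop a header line repeating the column names
  if (identical(strsplit(lines[lineNo[1L]], "\t")[[1L]], columns)) {
    keep[lineNo[1L]] <- FALSE
    lineNo <- lineNo[-1L]
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(columns))
  if (length(bad))
    stop(sprintf("%s line %d: expected %d tab-delimited fields, found %d",
                 path, lineNo[bad[1L]], length(columns),
                 lengths(fields)[bad[1L]]))
  df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  colnames(df) <- columns
  attr(df, "lineNo") <- lineNo
  df
}

.parseIntColumn <- function(df, col, path, nonneg = TRUE) {
  v <- suppressWarnings(as.integer(df[[col]]))
  bad <- which(is.na(v) | (nonneg & v < 0L))
  if (length(bad))
    stop(sprintf("%s line %d: column '%s' has invalid value '%s'",
                 path, attr(df, "lineNo")[bad[1L]], col, df[[col]][bad[1L]]))
  v
}

.checkFragmentOrder <- function(chrom, start, end, path, lineNo) {
  if (any(start >= end)) {
    i <- which(start >= end)[1L]
    stop(sprintf("%s line %d: fragment start >= end", path, lineNo[i]))
  }
  byChr <- split(seq_along(chrom), factor(chrom, levels = unique(chrom)))
  for (idx in byChr) {
    if (is.unsorted(start[idx], strictly = TRUE) ||
        any(end[idx][-length(idx)] != start[idx][-1L])) {
      stop(sprintf("%s: fragments on %s are out of order or do not tile",
                   path, chrom[idx[1L]]))
    }
  }
}

#' @rdname writeFragmentTable
#' @export
readFragmentTable <- function(path) {
  cols <- c("chrom", "start", "end", "index", "mappable", "end5", "end3")
  df <- .readTabTable(path, cols)
  start <- .parseIntColumn(df, "start", path)
  end <- .parseIntColumn(df, "end", path)
  .checkFragmentOrder(df$chrom, start, end, path, attr(df, "lineNo"))
  seqlens <- tapply(end, factor(df$chrom, levels = unique(df$chrom)), max)
  .newFragmentMap(df$chrom, start, end,
                  stats::setNames(as.integer(seqlens), names(seqlens)),
                  mappable = .parseIntColumn(df, "mappable", path) > 0L,
                  end5 = .parseIntColumn(df, "end5", path) > 0L,
                  end3 = .parseIntColumn(df, "end3", path) > 0L)
}
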