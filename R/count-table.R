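#' Construct a count table
#'
#' @param fmap a [FragmentMap-class].
#' @param counts integer vector of per-fragment read counts, parallel to
#'   `fragments(fmap)`.
#' @param replicate,allele free-text labels.
#' @param unassigned number of reads not assigned to any fragment.
#' @param included logical analysis-inclusion flags (masking state);
#'   defaults to all `TRUE`.
#' @return A [CountTable-class].
#' @export
countTable <- function(fmap, counts, replicate = "", allele = "",
                       unassigned = 0L, included = NULL) {
  if (is.null(included)) included <- rep(TRUE, length(fmap@frags))
  obj <- new("CountTable", fmap = fmap, counts = as.integer(counts),
             included = included, replicate = as.character(replicate),
             allele = as.character(allele), unassigned = as.integer(unassigned))
  validObject(obj)
  obj
}

.cigarRefWidth <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1L]]
    tok <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1L]]
    n <- as.integer(sub("[A-Z=]$", "", tok))
    op <- sub("^\\d+", "", tok)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read aligned reads from SAM-format text
#'
#' Parses the minimum alignment fields needed for fragment assignment:
#' RNAME, POS, FLAG (strand, unmapped bit), MAPQ, and CIGAR (to locate the
#' 5'-most aligned base of reverse-strand reads). `pos5` is 0-based: for
#' forward-strand reads `POS - 1`, for reverse-strand reads the 0-based
#' alignment end. A `BC:Z:left-right` optional tag, when present, is split
#' into the random-barcode pair.
#'
#' @param path path to a SAM text file.
#' @return A data.frame with columns `chrom`, `pos5`, `strand`, `mapq`,
#'   `bcLeft`, `bcRight` (NA when absent), one row per mapped record.
#' @export
readSamAlignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), pos5 = integer(),
                      strand = character(), mapq = integer(),
                      bcLeft = character(), bcRight = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 6L))
    stop("malformed SAM record at line ", which(lengths(fields) < 6L)[1L])
  getf <- function(i) vapply(fields, `[`, character(1), i)
  flag <- as.integer(getf(2L))
  rname <- getf(3L)
  pos <- as.integer(getf(4L))
  mapq <- as.integer(getf(5L))
  cigar <- getf(6L)
  mapped <- bitwAnd(flag, 4L) == 0L & rname != "*"
  minus <- bitwAnd(flag, 16L) != 0L
  pos5 <- ifelse(minus, pos - 1L + pmax(.cigarRefWidth(cigar) - 1L, 0L),
                 pos - 1L)
  bc <- vapply(fields, function(f) {
    hit <- grep("^BC:Z:", f[-(1:11)], value = TRUE)
    if (length(hit)) sub("^BC:Z:", "", hit[1L]) else NA_character_
  }, character(1))
  bcSplit <- strsplit(ifelse(is.na(bc), "NA-NA", bc), "-", fixed = TRUE)
  df <- data.frame(chrom = rname, pos5 = pos5,
                   strand = ifelse(minus, "-", "+"), mapq = mapq,
                   bcLeft = vapply(bcSplit, `[`, character(1), 1L),
                   bcRight = vapply(bcSplit, `[`, character(1), 2L))
  df$bcLeft[is.na(bc)] <- NA_character_
  df$bcRight[is.na(bc)] <- NA_character_
  df[mapped, , drop = FALSE]
}

## fragment ordinal (global row in fmap) containing each 0-based position,
## NA when off-chromosome or chromosome absent
.locateFragments <- function(fmap, chrom, pos5) {
  gr <- fmap@frags
  out <- rep(NA_integer_, length(chrom))
  for (chr in unique(chrom)) {
    rows <- which(as.character(GenomicRanges::seqnames(gr)) == chr)
    sel <- which(chrom == chr)
    if (length(rows) == 0L) next
    starts0 <- GenomicRanges::start(gr)[rows] - 1L
    chromLen <- GenomicRanges::end(gr)[rows[length(rows)]]
    k <- findInterval(pos5[sel], starts0)
    ok <- pos5[sel] >= 0L & pos5[sel] < chromLen & k >= 1L
    out[sel[ok]] <- rows[k[ok]]
  }
  out
}

#' Assign aligned reads to 3C fragments
#'
#' Turns alignments into a per-fragment count table on the fragment
#' database. In `containment` mode a read increments the fragment whose
#' interval contains its 5'-most aligned base. In `boundary` mode the read
#' must additionally start within `boundaryTolerance` bases of the fragment
#' boundary it would have been captured from -- the fragment start for
#' forward-strand reads, the last fragment base for reverse-strand reads --
#' otherwise it is left unassigned. Reads below `minMapq`, on chromosomes
#' absent from the map, or off the chromosome end are unassigned. Assigned
#' plus unassigned always equals the number of input reads (when
#' `collapseDuplicates = FALSE`).
#'
#' @param reads a data.frame with columns `chrom`, `pos5` (0-based),
#'   `strand` (`"+"`/`"-"`), `mapq`, and optionally `bcLeft`/`bcRight`
#'   (random-barcode pair), e.g. from [readSamAlignments()].
#' @param fmap a [FragmentMap-class].
#' @param mode `"containment"` (default) or `"boundary"`.
#' @param boundaryTolerance bases, for boundary mode; the default of 4
#'   mirrors a 4-base random barcode between primer and genomic sequence.
#' @param minMapq minimum mapping quality; the default 1 keeps uniquely
#'   aligned reads only.
#' @param collapseDuplicates when `TRUE`, reads sharing an identical
#'   (fragment, barcode pair) are collapsed to one before counting;
#'   barcode-less reads are never collapsed.
#' @param replicate,allele labels stored on the result.
#' @return A [CountTable-class].
#' @export
assignReads <- function(reads, fmap, mode = c("containment", "boundary"),
                        boundaryTolerance = 4, minMapq = 1,
                        collapseDuplicates = FALSE,
                        replicate = "", allele = "") {
  mode <- match.arg(mode)
  stopifnot(is(fmap, "FragmentMap"))
  gr <- fmap@frags
  if (length(gr) == 0L) stop("fragment map is empty")
  nIn <- nrow(reads)
  frag <- if (nIn) .locateFragments(fmap, reads$chrom, reads$pos5) else integer()
  if (nIn) frag[reads$mapq < minMapq] <- NA_integer_
  if (mode == "boundary" && nIn) {
    bnd <- ifelse(reads$strand == "-", GenomicRanges::end(gr)[frag] - 1L,
                  GenomicRanges::start(gr)[frag] - 1L)
    tooFar <- !is.na(frag) & abs(reads$pos5 - bnd) > boundaryTolerance
    frag[tooFar] <- NA_integer_
  }
  if (collapseDuplicates && nIn && all(c("bcLeft", "bcRight") %in% names(reads))) {
    hasBc <- !is.na(reads$bcLeft) & !is.na(reads$bcRight) & !is.na(frag)
    key <- paste(frag, reads$bcLeft, reads$bcRight, sep = "\r")
    drop <- hasBc & duplicated(key)
    frag <- frag[!drop]
    nIn <- length(frag)
  }
  counts <- tabulate(frag[!is.na(frag)], nbins = length(gr))
  countTable(fmap, counts, replicate = replicate, allele = allele,
             unassigned = nIn - sum(!is.na(frag)))
}

#' Read and write per-fragment count tables (retab format)
#'
#' The retab dialect is tab-delimited text with columns `chrom`, `start`,
#' `end`, `index`, `mappable` (0/1), `count`; coordinates 0-based
#' half-open; `#` comment lines allowed. Every fragment of the database
#' keeps its row, mappable or not. The writer echoes the `replicate`,
#' `allele` and `unassigned` fields into the header so that
#' `readRetab(writeRetab(x))` restores the table; masking state is not
#' serialized (masks are applied at analysis time).
#'
#' @param table a [CountTable-class].
#' @param path file path.
#' @param config optional named list echoed into `#` header lines.
#' @return `readRetab` returns a [CountTable-class]; `writeRetab` returns
#'   `path` invisibly.
#' @export
writeRetab <- function(table, path, config = list()) {
  stopifnot(is(table, "CountTable"))
  gr <- table@fmap@frags
  mc <- S4Vectors::mcols(gr)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   index = mc$index, mappable = as.integer(mc$mappable),
                   count = table@counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# fourCcall retab; coordinates 0-based half-open",
               paste0("# replicate=", table@replicate),
               paste0("# allele=", table@allele),
               paste0("# unassigned=", table@unassigned),
               .configHeader(config),
               paste(colnames(df), collapse = "\t")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

.headerField <- function(lines, key) {
  hit <- grep(paste0("^# ", key, "="), lines, value = TRUE)
  if (length(hit)) sub(paste0("^# ", key, "="), "", hit[1L]) else ""
}

#' @rdname writeRetab
#' @export
readRetab <- function(path) {
  cols <- c("chrom", "start", "end", "index", "mappable", "count")
  lines <- readLines(path)
  df <- .readTabTable(path, cols)
  start <- .parseIntColumn(df, "start", path)
  end <- .parseIntColumn(df, "end", path)
  counts <- .parseIntColumn(df, "count", path)
  .checkFragmentOrder(df$chrom, start, end, path, attr(df, "lineNo"))
  mappable <- .parseIntColumn(df, "mappable", path) > 0L
  seqlens <- tapply(end, factor(df$chrom, levels = unique(df$chrom)), max)
  fmap <- .newFragmentMap(df$chrom, start, end,
                          stats::setNames(as.integer(seqlens), names(seqlens)),
                          mappable = mappable)
  unassigned <- suppressWarnings(as.integer(.headerField(lines, "unassigned")))
  countTable(fmap, counts, replicate = .headerField(lines, "replicate"),
             allele = .headerField(lines, "allele"),
             unassigned = if (is.na(unassigned)) 0L else unassigned)
}

.asMaskGRanges <- function(masks) {
  if (is(masks, "GRanges")) return(masks)
  if (is.character(masks)) return(parseRegion(masks))
  if (is.data.frame(masks)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(masks)),
              all(masks$start < masks$end))
    return(GenomicRanges::GRanges(masks$chrom,
                                  IRanges::IRanges(masks$start + 1L, masks$end)))
  }
  stop("masks must be a GRanges, a data.frame(chrom, start, end), ",
       "or a 'chr:start-end' string")
}

#' Parse a `chr:start-end` region string
#'
#' Coordinates in the string are 0-based half-open, matching every file the
#' package writes.
#'
#' @param region a string like `"chr5:100000-250000"`.
#' @return A length-1 `GRanges`.
#' @export
parseRegion <- function(region) {
  m <- regmatches(region, regexec("^(.+):(\\d+)-(\\d+)$", region))[[1L]]
  if (length(m) != 4L) stop("cannot parse region '", region,
                            "'; expected chr:start-end")
  start0 <- as.numeric(m[3L]); end0 <- as.numeric(m[4L])
  if (start0 >= end0) stop("region start must be < end")
  GenomicRanges::GRanges(m[2L], IRanges::IRanges(start0 + 1, end0))
}

#' Read mask/region intervals from a BED file
#'
#' Only the first three BED columns are used.
#'
#' @param path BED file path.
#' @return A `GRanges`.
#' @export
readBedRegions <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::granges(gr)
}

#' Mask regions out of (or restrict analysis to) a count table
#'
#' With `keepInside = FALSE` (mask-out), every fragment overlapping any
#' mask region -- by as little as one base -- is removed from the analysis
#' set: it contributes neither to observed windows nor to the shuffle pool.
#' With `keepInside = TRUE` (region restriction), only overlapping
#' fragments are retained, which is how a localized background is computed
#' (e.g. restricting to a few megabases around a locus of interest).
#' Removal is whole-fragment and is recorded on the `included` flag;
#' counts and the fragment map are untouched.
#'
#' @param table a [CountTable-class].
#' @param masks a `GRanges`, a data.frame with `chrom`/`start`/`end`
#'   (0-based half-open), or a `"chr:start-end"` string.
#' @param keepInside see Description.
#' @return The masked [CountTable-class].
#' @export
applyMask <- function(table, masks, keepInside = FALSE) {
  stopifnot(is(table, "CountTable"))
  maskGR <- .asMaskGRanges(masks)
  hit <- IRanges::overlapsAny(table@fmap@frags, maskGR)
  table@included <- table@included & (if (keepInside) hit else !hit)
  table
}

#' Per-fragment random-barcode duplication statistic
#'
#' 4C library protocols that place random barcodes on both read ends allow
#' PCR duplicates to be recognized: reads on one fragment sharing an
#' identical (left, right) barcode pair are unlikely to be independent
#' ligation events. For every fragment with at least one barcoded read this
#' reports the fraction of its reads whose pair is shared with another read
#' on the same fragment (0 when all pairs are distinct, 1 when all reads
#' share pairs).
#'
#' @param reads a data.frame as in [assignReads()], with `bcLeft`/`bcRight`.
#' @param fmap a [FragmentMap-class].
#' @param minMapq minimum mapping quality, as in [assignReads()].
#' @return A data.frame with one row per fragment holding barcoded reads:
#'   `chrom`, `start`, `end`, `index`, `nReads`, `dupFraction`. The number
#'   of reads excluded for missing barcodes is in attribute
#'   `"nExcluded"` (also reported via a message).
#' @export
barcodeDuplicationStats <- function(reads, fmap, minMapq = 1) {
  stopifnot(all(c("bcLeft", "bcRight") %in% names(reads)))
  hasBc <- !is.na(reads$bcLeft) & !is.na(reads$bcRight)
  nExcluded <- sum(!hasBc)
  if (nExcluded) message(nExcluded, " read(s) lacking a barcode pair excluded")
  reads <- reads[hasBc & reads$mapq >= minMapq, , drop = FALSE]
  frag <- .locateFragments(fmap, reads$chrom, reads$pos5)
  keep <- !is.na(frag)
  frag <- frag[keep]
  pair <- paste(reads$bcLeft[keep], reads$bcRight[keep], sep = "\r")
  out <- do.call(rbind, lapply(split(pair, frag), function(p) {
    tab <- table(p)
    data.frame(nReads = length(p), dupFraction = sum(tab[tab >= 2L]) / length(p))
  }))
  rows <- as.integer(names(split(pair, frag)))
  gr <- fmap@frags[rows]
  res <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    index = S4Vectors::mcols(gr)$index,
                    nReads = out$nReads, dupFraction = out$dupFraction)
  attr(res, "nExcluded") <- nExcluded
  res
}
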