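#' Priority category names
#'
#' Categories order Broad (1) < Intermediate (2) < Narrow (3); smaller is
#' broader and takes precedence when categories are combined.
#'
#' @param category integer vector with values in 1:3.
#' @return Character vector of category names.
#' @export
categoryName <- function(category) {
  c("Broad", "Intermediate", "Narrow")[as.integer(category)]
}

#' Prioritize one significant window
#'
#' Classifies how a significant window's read mass is spread over its
#' fragments by perturbing the most abundant fragment (ties broken to the
#' leftmost) and re-testing against the threshold. Broad (1): the window
#' stays significant with that fragment's reads removed entirely.
#' Intermediate (2): it stays significant when that fragment's count is
#' replaced by the mean of its in-window flanking fragments (one or two;
#' the mean is real-valued, and 0 when the window has a single fragment).
#' Narrow (3): significant only with all reads included. A window of size
#' one is therefore always Narrow. Broad windows mirror the fiber-like
#' spread of reads around a genuine contact and are the most likely to be
#' reproduced across replicates.
#'
#' @param counts the window's per-fragment counts (length W).
#' @param threshold the significance threshold T the window passed.
#' @return Integer category: 1 (Broad), 2 (Intermediate) or 3 (Narrow).
#' @examples
#' categorizeWindow(c(3, 4, 20, 3, 2), 10)   # Broad
#' categorizeWindow(c(0, 9, 30, 11, 0), 25)  # Intermediate
#' @export
categorizeWindow <- function(counts, threshold) {
  S <- sum(counts)
  if (S < threshold)
    stop("window is not significant (sum ", S, " < threshold ", threshold, ")")
  i <- which.max(counts)            # leftmost maximum
  m <- counts[i]
  if (S - m >= threshold) return(1L)
  nb <- counts[c(i - 1L, i + 1L)[c(i > 1L, i < length(counts))]]
  replacement <- if (length(nb)) mean(nb) else 0
  if (S - m + replacement >= threshold) return(2L)
  3L
}

#' Combine member-window categories into an interaction category
#'
#' An interaction takes the broadest designation among its member windows
#' (the minimum category value).
#'
#' @param categories integer vector of member-window categories.
#' @return Integer category.
#' @export
categorizeInteraction <- function(categories) {
  stopifnot(length(categories) >= 1L)
  as.integer(min(categories))
}

#' Merge significant windows into interactions
#'
#' Significant windows whose fragment ranges overlap or abut are merged;
#' each interaction's fragment range is the union of its member windows'
#' ranges, after which fragments without reads are trimmed from the 5' and
#' 3' ends (interior zero-count fragments are kept). Reported interactions
#' are maximal: no two could be merged further. Positions here are indices
#' into the analysis-set fragment sequence of one chromosome.
#'
#' @param sig 1-based indices of significant windows (window `i` covers
#'   analysis positions `i .. i + W - 1`), as from [callWindows()].
#' @param counts the analysis-set counts the windows were computed from.
#' @param W window size.
#' @param threshold the threshold T the windows passed.
#' @return A data.frame with one row per interaction: `firstPos`,
#'   `lastPos` (retained analysis-position range), `totalReads` (sum over
#'   retained fragments), `nWindows`, `category`.
#' @export
mergeSignificantWindows <- function(sig, counts, W, threshold) {
  if (is(threshold, "ThresholdResult")) threshold <- threshold@threshold
  W <- as.integer(W)
  if (length(sig) == 0L)
    return(data.frame(firstPos = integer(), lastPos = integer(),
                      totalReads = numeric(), nWindows = integer(),
                      category = integer()))
  sig <- sort(unique(as.integer(sig)))
  # ranges [i, i+W-1] overlap or abut iff the next start is <= prev end + 1
  grp <- cumsum(c(1L, as.integer(diff(sig) > W)))
  out <- lapply(split(sig, grp), function(idx) {
    first <- idx[1L]
    last <- idx[length(idx)] + W - 1L
    while (first <= last && counts[first] == 0) first <- first + 1L
    while (last >= first && counts[last] == 0) last <- last - 1L
    stopifnot(first <= last)  # a significant run holds >= T >= 1 reads
    cats <- vapply(idx, function(i)
      categorizeWindow(counts[i:(i + W - 1L)], threshold), integer(1))
    data.frame(firstPos = first, lastPos = last,
               totalReads = sum(counts[first:last]),
               nWindows = length(idx),
               category = categorizeInteraction(cats))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call interactions on a count table
#'
#' End-to-end caller: per chromosome, computes the permutation threshold,
#' sums sliding windows over the analysis set, calls significant windows,
#' merges them into trimmed interactions, and prioritizes them.
#'
#' @param table a [CountTable-class].
#' @param config a [ThresholdConfig-class].
#' @param masks optional masks, as in [applyMask()] (mask-out semantics).
#' @param chroms chromosomes to analyze (default all).
#' @return A `GRanges` of interactions (0-based half-open spans are used
#'   when written to file; in memory the GRanges convention applies) with
#'   metadata columns `category`, `categoryName`, `totalReads`,
#'   `nWindows`, `threshold`, `fragFirst`, `fragLast` (0-based chromosome
#'   fragment indices of the retained range ends). The per-chromosome
#'   [ThresholdResult-class] objects are in
#'   `S4Vectors::metadata(x)$thresholds`.
#' @export
callInteractions <- function(table, config, masks = NULL, chroms = NULL) {
  stopifnot(is(table, "CountTable"))
  if (!is.null(masks)) table <- applyMask(table, masks, keepInside = FALSE)
  if (is.null(chroms)) chroms <- chromNames(table)
  gr <- table@fmap@frags
  pieces <- list()
  thresholds <- list()
  for (chr in chroms) {
    rows <- which(as.character(GenomicRanges::seqnames(gr)) == chr)
    use <- analysisSet(table, chr)
    if (!any(use)) next
    tr <- computeThreshold(table, chr, config)
    thresholds[[chr]] <- tr
    counts <- fragmentCounts(table, chr)[use]
    sums <- suppressWarnings(windowSums(counts, config@window))
    ints <- mergeSignificantWindows(callWindows(sums, tr), counts,
                                    config@window, tr)
    if (nrow(ints) == 0L) next
    useRows <- rows[use]              # analysis position -> global frag row
    firstRow <- useRows[ints$firstPos]
    lastRow <- useRows[ints$lastPos]
    pieces[[chr]] <- GenomicRanges::GRanges(
      seqnames = chr,
      ranges = IRanges::IRanges(start = GenomicRanges::start(gr)[firstRow],
                                end = GenomicRanges::end(gr)[lastRow]),
      category = ints$category, categoryName = categoryName(ints$category),
      totalReads = ints$totalReads, nWindows = ints$nWindows,
      threshold = tr@threshold,
      fragFirst = S4Vectors::mcols(gr)$index[firstRow],
      fragLast = S4Vectors::mcols(gr)$index[lastRow],
      seqlengths = GenomeInfoDb::seqlengths(gr)[chr])
  }
  out <- if (length(pieces))
    suppressWarnings(do.call(c, unname(pieces)))
  else GenomicRanges::GRanges(category = integer(), categoryName = character(),
                              totalReads = numeric(), nWindows = integer(),
                              threshold = integer(), fragFirst = integer(),
                              fragLast = integer())
  S4Vectors::metadata(out)$thresholds <- thresholds
  out
}

#' Expand interactions to their member fragments
#'
#' Cross-references interactions with the fragment database to express
#' each interaction as its member analysis-set fragments, each tagged with
#' the interaction's category -- the congruent coordinate system used for
#' replicate set analysis.
#'
#' @param interactions a `GRanges` from [callInteractions()] or
#'   [readInteractionsBed()].
#' @param table the [CountTable-class] (or a [FragmentMap-class]) the
#'   interactions were called on; with a table, only analysis-set
#'   fragments are members, with a bare map, all mappable fragments.
#' @return A data.frame: `chrom`, `start`, `end` (0-based half-open),
#'   `index`, `category`.
#' @export
fragmentCalls <- function(interactions, table) {
  if (is(table, "CountTable")) {
    fmap <- table@fmap
    use <- table@included & S4Vectors::mcols(fmap@frags)$mappable
  } else if (is(table, "FragmentMap")) {
    fmap <- table
    use <- S4Vectors::mcols(fmap@frags)$mappable
  } else stop("table must be a CountTable or FragmentMap")
  gr <- fmap@frags
  hits <- IRanges::findOverlaps(gr, interactions)
  keep <- use[S4Vectors::queryHits(hits)]
  qi <- S4Vectors::queryHits(hits)[keep]
  si <- S4Vectors::subjectHits(hits)[keep]
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr))[qi],
                   start = GenomicRanges::start(gr)[qi] - 1L,
                   end = GenomicRanges::end(gr)[qi],
                   index = S4Vectors::mcols(gr)$index[qi],
                   category = S4Vectors::mcols(interactions)$category[si])
  # a fragment can fall in one interaction only, but keep the broadest if not
  df <- df[order(df$chrom, df$start, df$category), , drop = FALSE]
  df <- df[!duplicated(df[c("chrom", "start", "end")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Intersect replicate call sets with category retention
#'
#' Keeps exactly the fragments called in every replicate (matched by
#' identical coordinates on the shared fragment map). Each retained
#' fragment is assigned the broadest (minimum-valued) category observed
#' across replicates. Per-replicate unique fragments and pairwise overlap
#' counts are reported alongside.
#'
#' @param callSets a list of two or more fragment call sets from
#'   [fragmentCalls()] (data.frames with `chrom`, `start`, `end`,
#'   `category`).
#' @return A list: `intersection` (data.frame `chrom`, `start`, `end`,
#'   `category`, plus `rep<i>` columns with each replicate's category),
#'   `uniqueCounts` (fragments seen in exactly one replicate, per
#'   replicate), `pairwiseOverlap` (matrix of shared-fragment counts).
#' @export
intersectReplicates <- function(callSets) {
  if (length(callSets) < 2L) stop("need at least 2 replicate call sets")
  if (is.null(names(callSets)))
    names(callSets) <- paste0("rep", seq_along(callSets))
  keys <- lapply(callSets, function(df)
    paste(df$chrom, df$start, df$end, sep = ":"))
  common <- Reduce(intersect, keys)
  catOf <- function(i) {
    df <- callSets[[i]]
    stats::setNames(df$category, keys[[i]])[common]
  }
  perRep <- vapply(seq_along(callSets), catOf,
                   numeric(length(common)))
  if (length(common) == 1L) perRep <- matrix(perRep, nrow = 1L)
  base <- callSets[[1L]][match(common, keys[[1L]]),
                         c("chrom", "start", "end"), drop = FALSE]
  intersection <- cbind(base,
                        category = if (length(common))
                          as.integer(apply(perRep, 1L, min)) else integer())
  colnames(perRep) <- names(callSets)
  intersection <- cbind(intersection, as.data.frame(perRep))
  intersection <- intersection[order(intersection$chrom, intersection$start), ,
                               drop = FALSE]
  rownames(intersection) <- NULL
  allKeys <- unlist(keys, use.names = FALSE)
  seenOnce <- names(which(table(allKeys) == 1L))
  uniqueCounts <- vapply(keys, function(k) sum(k %in% seenOnce), integer(1))
  n <- length(callSets)
  pairwise <- matrix(0L, n, n, dimnames = list(names(callSets), names(callSets)))
  for (i in seq_len(n)) for (j in seq_len(n))
    pairwise[i, j] <- length(intersect(keys[[i]], keys[[j]]))
  list(intersection = intersection, uniqueCounts = uniqueCounts,
       pairwiseOverlap = pairwise)
}
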