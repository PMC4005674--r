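#' Construct a threshold-engine configuration
#'
#' Defaults follow the recommended practice for 4C-Seq significance
#' calling: at least 1000 permutations, the top fifth percentile of the
#' cutoff distribution, and a target FDR below 0.01.
#'
#' @param window sliding-window size W, in mappable fragments.
#' @param fdr target empirical FDR (proportion in (0,1)).
#' @param nPermutations number of shuffles P.
#' @param topPercentile k; the final threshold is the smallest
#'   per-permutation cutoff among the top k percent.
#' @param mode `"percentile"` or the comparator `"pooled_mean"` (FDR
#'   averaged over permutations, as in earlier averaged-FDR callers).
#' @param shuffleUnit `"vector"` or `"read"`; see [shuffleCounts()].
#' @param seed master seed for the permutation streams.
#' @return A [ThresholdConfig-class].
#' @export
thresholdConfig <- function(window = 5, fdr = 0.01, nPermutations = 1000,
                            topPercentile = 5,
                            mode = c("percentile", "pooled_mean"),
                            shuffleUnit = c("vector", "read"), seed = 1) {
  obj <- new("ThresholdConfig", window = as.integer(window), fdr = fdr,
             nPermutations = as.integer(nPermutations),
             topPercentile = topPercentile, mode = match.arg(mode),
             shuffleUnit = match.arg(shuffleUnit), seed = as.integer(seed))
  validObject(obj)
  obj
}

#' Deterministic per-permutation seed
#'
#' Derives the RNG seed for permutation `p` of chromosome `chrom` from the
#' master seed, so per-chromosome results are independent of execution
#' order and reproducible piecewise. The derivation (a multiplicative hash
#' modulo the Mersenne prime 2^31 - 1) is part of the package's
#' reproducibility contract: any independent re-implementation of the
#' permutation loop seeded through this function sees the same shuffles.
#'
#' @param seed integer master seed.
#' @param chrom chromosome name.
#' @param p permutation index (1-based).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
permutationSeed <- function(seed, chrom, p) {
  M <- 2147483647
  h <- as.numeric(seed) %% M
  for (ch in utf8ToInt(as.character(chrom))) h <- (h * 131 + ch) %% M
  h <- (h * 131 + as.numeric(p)) %% M
  as.integer(h %% (M - 1)) + 1L
}

#' Sliding-window sums over mappable-fragment counts
#'
#' Windows of W consecutive fragments of the analysis set (mappable,
#' unmasked), sliding by one fragment. Window `i` (1-based) covers analysis
#' positions `i .. i + W - 1`; callers map analysis positions back to
#' fragment rows. When W exceeds the number of fragments the result is
#' empty, with a warning.
#'
#' @param counts integer counts of the analysis-set fragments, in order.
#' @param W window size (>= 1).
#' @return Numeric vector of `max(0, length(counts) - W + 1)` window sums.
#' @examples
#' windowSums(c(1, 2, 3, 4), 2)  # 3 5 7
#' @export
windowSums <- function(counts, W) {
  W <- as.integer(W)
  stopifnot(W >= 1L)
  n <- length(counts)
  if (W > n) {
    warning(sprintf("window size %d exceeds %d available fragments", W, n))
    return(numeric(0))
  }
  cs <- cumsum(as.numeric(c(0, counts)))
  cs[(W + 1L):(n + 1L)] - cs[1L:(n - W + 1L)]
}

#' Shuffle per-fragment counts
#'
#' The null model for threshold calculation: reads are redistributed at
#' random among the analysis-set fragments. With `unit = "vector"` (the
#' default) the count vector is uniformly permuted, preserving the exact
#' multiset of per-fragment counts -- the conservative choice for
#' overdispersed 4C counts. With `unit = "read"` every read is placed
#' independently and uniformly on a fragment (sum preserved, multiset
#' not). Uses the current RNG state; callers seed it (see
#' [permutationSeed()]).
#'
#' @param counts integer counts of the analysis-set fragments.
#' @param unit `"vector"` or `"read"`.
#' @return Shuffled integer vector of the same length and total.
#' @export
shuffleCounts <- function(counts, unit = c("vector", "read")) {
  unit <- match.arg(unit)
  n <- length(counts)
  if (n == 0L) return(integer(0))
  if (unit == "vector") {
    counts[sample.int(n)]
  } else {
    as.integer(stats::rmultinom(1L, sum(counts), rep(1, n)))
  }
}

## tail[c] = #{x >= c} for c = 1..cmax, x non-negative integers
.tailCounts <- function(x, cmax) {
  if (length(x) == 0L) return(rep(0L, cmax))
  h <- tabulate(pmin(x, cmax) + 1L, nbins = cmax + 1L)  # h[i] = #{x == i-1}
  rev(cumsum(rev(h)))[-1L]                              # drop c = 0
}

.fdrCutoffFromTails <- function(shufTail, obsTail, alpha) {
  # FDRhat(c) = shufTail[c] / obsTail[c]; 0 when obsTail[c] == 0
  fdr <- ifelse(obsTail == 0L, 0, shufTail / obsTail)
  c(which(fdr < alpha), length(fdr) + 1L)[1L]
}

#' Per-permutation empirical-FDR cutoff X
#'
#' The minimum reads-per-window cutoff at which the shuffled data's
#' discoveries, relative to the observed data's, fall below the target
#' FDR: `X = min{ c >= 1 : #{shuffled >= c} / #{observed >= c} < alpha }`,
#' with the convention that the ratio is 0 when no observed window reaches
#' `c`. X always exists (beyond the shuffled maximum the numerator is 0)
#' and is at most `max(shuffled) + 1`.
#'
#' @param observed,shuffled window-sum vectors over the same fragment
#'   universe and window size.
#' @param alpha target FDR.
#' @return Integer cutoff X >= 1. Empty inputs give 1 with a warning.
#' @examples
#' fdrCutoff(c(50, 3, 2, 1), c(5, 4, 3, 2), 0.25)  # 6
#' @export
fdrCutoff <- function(observed, shuffled, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(observed) == 0L && length(shuffled) == 0L) {
    warning("empty window vectors; cutoff is vacuously 1")
    return(1L)
  }
  cmax <- as.integer(max(observed, shuffled, 0)) + 1L
  as.integer(.fdrCutoffFromTails(.tailCounts(as.integer(round(shuffled)), cmax),
                                 .tailCounts(as.integer(round(observed)), cmax),
                                 alpha))
}

#' Per-chromosome significance threshold by permutation
#'
#' The core of the caller. For one chromosome: (1) sum the observed counts
#' over sliding windows of W analysis-set fragments; (2) shuffle the
#' counts among those fragments and recompute the window sums; (3) from
#' the shuffled and observed sums compute the cutoff X attaining the
#' target FDR; (4) repeat P times to obtain the X distribution; (5) in
#' `percentile` mode the final threshold T is the smallest X within the
#' top k percent -- the order statistic of rank
#' `P - floor(P * k / 100) + 1` (clamped to `[1, P]`), so T is always an
#' attained X. In the `pooled_mean` comparator mode T is the smallest
#' cutoff at which the permutation-averaged FDR falls below the target;
#' this reproduces earlier averaged-FDR callers, whose averages an extreme
#' shuffle can dominate. Masks are applied before thresholding; the
#' shuffle pool and the observed windows use exactly the same fragments.
#' Identical input, config and seed give bit-identical results.
#'
#' @param table a [CountTable-class].
#' @param chrom chromosome to analyze.
#' @param config a [ThresholdConfig-class].
#' @param masks optional masks, as in [applyMask()] (mask-out semantics);
#'   applied on top of any masking already on the table.
#' @return A [ThresholdResult-class].
#' @export
computeThreshold <- function(table, chrom, config, masks = NULL) {
  stopifnot(is(table, "CountTable"), is(config, "ThresholdConfig"))
  validObject(config)
  if (!chrom %in% chromNames(table)) stop("chromosome ", chrom,
                                          " not in the fragment map")
  if (!is.null(masks)) table <- applyMask(table, masks, keepInside = FALSE)
  use <- analysisSet(table, chrom)
  counts <- fragmentCounts(table, chrom)[use]
  if (length(counts) == 0L)
    stop("no mappable fragments left on chromosome ", chrom, " after masking")
  W <- config@window
  P <- config@nPermutations
  observed <- suppressWarnings(windowSums(counts, W))
  obsInt <- as.integer(round(observed))
  cmaxObs <- if (length(obsInt)) max(obsInt) else 0L
  # one pass per permutation; tails over candidate cutoffs are cheap because
  # window sums are small integers. No shuffled window sum can exceed the
  # sum of the W largest counts (vector unit) or the chromosome total
  # (read unit), which bounds the candidate-cutoff range.
  total <- sum(counts)
  shufBound <- if (config@shuffleUnit == "vector")
    sum(sort(counts, decreasing = TRUE)[seq_len(min(W, length(counts)))])
  else total
  cmax <- as.integer(max(cmaxObs, shufBound, 1L)) + 1L
  obsTail <- .tailCounts(obsInt, cmax)
  xs <- integer(P)
  pooledShufTail <- numeric(cmax)
  for (p in seq_len(P)) {
    set.seed(permutationSeed(config@seed, chrom, p))
    shufSums <- suppressWarnings(
      windowSums(shuffleCounts(counts, config@shuffleUnit), W))
    shufTail <- .tailCounts(as.integer(round(shufSums)), cmax)
    if (config@mode == "percentile") {
      xs[p] <- if (length(observed) == 0L && length(shufSums) == 0L) 1L else
        as.integer(.fdrCutoffFromTails(shufTail, obsTail, config@fdr))
    } else {
      pooledShufTail <- pooledShufTail + shufTail
    }
  }
  if (config@mode == "percentile") {
    sorted <- sort(xs)
    r <- min(max(P - floor(P * config@topPercentile / 100) + 1L, 1L), P)
    T <- sorted[r]
    xdist <- xs
  } else {
    T <- if (length(observed) == 0L) 1L else
      as.integer(.fdrCutoffFromTails(pooledShufTail / P, obsTail, config@fdr))
    xdist <- integer(0)
  }
  new("ThresholdResult", chrom = chrom, threshold = as.integer(T),
      xDistribution = xdist, config = config,
      diagnostics = list(nMappable = length(counts), totalReads = total,
                         nWindows = length(observed),
                         maxObservedSum = cmaxObs))
}

#' Call significant windows
#'
#' A window is significant iff its read sum reaches the threshold
#' (inclusive: the threshold is defined as the minimum number of reads
#' required).
#'
#' @param sums window-sum vector (observed).
#' @param threshold integer threshold T >= 1, or a
#'   [ThresholdResult-class].
#' @return Integer indices (1-based) of significant windows.
#' @export
callWindows <- function(sums, threshold) {
  if (is(threshold, "ThresholdResult")) threshold <- threshold@threshold
  stopifnot(threshold >= 1)
  which(sums >= threshold)
}
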