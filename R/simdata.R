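#' Simulate a tiling fragment map
#'
#' Generates one synthetic chromosome tiled by fragments whose lengths are
#' geometric with the given mean (minimum 1 base), with a configurable
#' fraction flagged unmappable at random -- the structure, though not the
#' sequence, of a restriction digest.
#'
#' @param nFragments number of fragments (>= 1).
#' @param meanFragmentLength mean fragment length, bases.
#' @param unmappableFraction fraction of fragments flagged unmappable.
#' @param seed integer seed.
#' @param chrom chromosome name.
#' @return A [FragmentMap-class].
#' @export
simulateFragmentMap <- function(nFragments, meanFragmentLength = 2500,
                                unmappableFraction = 0.1, seed = 1,
                                chrom = "chrS") {
  stopifnot(nFragments >= 1, meanFragmentLength >= 1,
            unmappableFraction >= 0, unmappableFraction <= 1)
  set.seed(as.integer(seed))
  lens <- 1L + stats::rgeom(nFragments, 1 / meanFragmentLength)
  end0 <- cumsum(as.numeric(lens))
  start0 <- c(0, end0[-nFragments])
  mappable <- stats::runif(nFragments) >= unmappableFraction
  .newFragmentMap(rep(chrom, nFragments), as.integer(start0),
                  as.integer(end0),
                  stats::setNames(as.integer(end0[nFragments]), chrom),
                  mappable = mappable)
}

#' Simulate an exchangeable overdispersed background
#'
#' Mappable fragments receive independent negative-binomial counts
#' (mean `mu`, dispersion `dispersion`); unmappable fragments receive 0. The
#' counts are exchangeable across mappable fragments by construction,
#' which is exactly the null hypothesis of the shuffle-based threshold --
#' so thresholds calibrated on this background should rarely call
#' anything. The negative binomial emulates the overdispersion of real 4C
#' backgrounds; a Poisson background would understate window-sum variance
#' and make thresholds unrealistically tight.
#'
#' @param fmap a [FragmentMap-class].
#' @param mu background mean reads per mappable fragment.
#' @param dispersion negative-binomial dispersion in the sense used
#'   throughout count-based genomics: the variance is
#'   `mu + dispersion * mu^2` (`rnbinom` is called with
#'   `size = 1/dispersion`). Larger values give heavier tails; 0.3 is a
#'   realistic level of 4C background overdispersion.
#' @param seed integer seed.
#' @param replicate,allele labels stored on the table.
#' @return A [CountTable-class].
#' @export
simulateCounts <- function(fmap, mu = 2, dispersion = 0.3, seed = 1,
                           replicate = "sim", allele = "") {
  stopifnot(is(fmap, "FragmentMap"), mu >= 0, dispersion > 0)
  set.seed(as.integer(seed))
  n <- length(fmap@frags)
  mappable <- S4Vectors::mcols(fmap@frags)$mappable
  counts <- integer(n)
  counts[mappable] <- stats::rnbinom(sum(mappable), mu = mu,
                                     size = 1 / dispersion)
  countTable(fmap, counts, replicate = replicate, allele = allele)
}

#' Add power-law distance decay around a viewpoint
#'
#' Chromatin is a polymer: contact probability falls off with linear
#' distance from the viewpoint, so real 4C backgrounds are elevated near
#' it. Each mappable fragment at ordinal distance `d` fragments from the
#' viewpoint gains an independent Poisson draw with mean
#' `s * (1 + d)^-gamma`. Adding independent draws (rather than scaling
#' counts deterministically) keeps the table a counting process, so
#' shuffle-based calibration stays meaningful.
#'
#' @param table a [CountTable-class].
#' @param viewpoint 1-based fragment row (on the table's single ordering)
#'   of the viewpoint; must be mappable.
#' @param s decay scale: mean added at the viewpoint itself.
#' @param gamma decay exponent (>= 0; 0 adds a uniform mean shift).
#' @param seed integer seed.
#' @return The augmented [CountTable-class].
#' @export
addDistanceDecay <- function(table, viewpoint, s, gamma, seed = 1) {
  stopifnot(is(table, "CountTable"), s >= 0, gamma >= 0)
  n <- length(table@counts)
  viewpoint <- as.integer(viewpoint)
  stopifnot(viewpoint >= 1L, viewpoint <= n)
  mappable <- S4Vectors::mcols(table@fmap@frags)$mappable
  if (!mappable[viewpoint]) stop("viewpoint fragment must be mappable")
  if (s == 0) return(table)
  set.seed(as.integer(seed))
  d <- abs(seq_len(n) - viewpoint)
  extra <- integer(n)
  extra[mappable] <- stats::rpois(sum(mappable),
                                  s * (1 + d[mappable])^(-gamma))
  table@counts <- table@counts + extra
  validObject(table)
  table
}

#' Plant an interaction into a count table
#'
#' Distributes exactly `nReads` reads over mappable fragments around a
#' center, using a discretized symmetric Gaussian kernel of width `spread`
#' fragments: `spread = 0` puts every read on the center fragment (a
#' single-fragment spike, the shape of a spurious call), larger spreads
#' emulate the fiber-like read distribution of a genuine contact, whose
#' mass centers on the point of highest contact probability and falls off
#' into the neighboring fragments.
#'
#' @param table a [CountTable-class].
#' @param center 1-based fragment row of the peak center; must be mappable.
#' @param nReads total reads to add (conserved exactly).
#' @param spread kernel standard deviation, in mappable-fragment units.
#' @param seed integer seed.
#' @return The augmented [CountTable-class].
#' @export
plantInteraction <- function(table, center, nReads, spread, seed = 1) {
  stopifnot(is(table, "CountTable"), nReads >= 0, spread >= 0)
  n <- length(table@counts)
  center <- as.integer(center)
  stopifnot(center >= 1L, center <= n)
  mappable <- S4Vectors::mcols(table@fmap@frags)$mappable
  if (!mappable[center]) stop("center fragment must be mappable")
  if (nReads == 0) return(table)
  added <- integer(n)
  if (spread == 0) {
    added[center] <- as.integer(nReads)
  } else {
    set.seed(as.integer(seed))
    # kernel over mappable fragments, by mappable-ordinal distance from center
    mapRows <- which(mappable)
    ctrOrd <- match(center, mapRows)
    dOrd <- abs(seq_along(mapRows) - ctrOrd)
    keep <- dOrd <= ceiling(3 * spread)
    w <- exp(-(dOrd[keep]^2) / (2 * spread^2))
    alloc <- as.integer(stats::rmultinom(1L, as.integer(nReads), w))
    added[mapRows[keep]] <- alloc
  }
  table@counts <- table@counts + added
  validObject(table)
  table
}

#' Simulate a complete 4C-like count table
#'
#' Convenience wrapper: fragment map, exchangeable negative-binomial
#' background, optional viewpoint distance decay, and planted
#' interactions. Sub-seeds for the independent stages are derived from
#' `seed` via [permutationSeed()].
#'
#' @param nFragments,meanFragmentLength,unmappableFraction see
#'   [simulateFragmentMap()].
#' @param mu,dispersion background model, see [simulateCounts()].
#' @param viewpoint optional 1-based fragment row for decay (picked as the
#'   nearest mappable row if the given one is not mappable).
#' @param decayScale,decayGamma decay parameters, see [addDistanceDecay()].
#' @param peaks optional list of `list(center, nReads, spread)` planted
#'   interactions (centers snapped to the nearest mappable row).
#' @param seed integer master seed.
#' @param chrom chromosome name.
#' @return A list with elements `fmap` ([FragmentMap-class]) and `table`
#'   ([CountTable-class]).
#' @export
simulate4C <- function(nFragments = 2000, meanFragmentLength = 2500,
                       unmappableFraction = 0.1, mu = 2, dispersion = 0.3,
                       viewpoint = NULL, decayScale = 50, decayGamma = 1.2,
                       peaks = list(), seed = 1, chrom = "chrS") {
  fmap <- simulateFragmentMap(nFragments, meanFragmentLength,
                              unmappableFraction,
                              seed = permutationSeed(seed, chrom, 1L),
                              chrom = chrom)
  table <- simulateCounts(fmap, mu = mu, dispersion = dispersion,
                          seed = permutationSeed(seed, chrom, 2L))
  snap <- function(row) {
    mapRows <- which(S4Vectors::mcols(fmap@frags)$mappable)
    mapRows[which.min(abs(mapRows - row))]
  }
  if (!is.null(viewpoint)) {
    table <- addDistanceDecay(table, snap(viewpoint), decayScale, decayGamma,
                              seed = permutationSeed(seed, chrom, 3L))
  }
  for (k in seq_along(peaks)) {
    p <- peaks[[k]]
    table <- plantInteraction(table, snap(p$center), p$nReads, p$spread,
                              seed = permutationSeed(seed, chrom, 3L + k))
  }
  list(fmap = fmap, table = table)
}
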