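## Independent oracles and fixture builders shared across the suite.
## Oracles deliberately use different mechanisms than the implementation
## (regex scanning, straight-line loops) so agreement is informative.

# fragment map from explicit fragment lengths (0-based tiling)
makeMap <- function(lens, mappable = NULL, chrom = "chrT") {
  end0 <- cumsum(as.integer(lens))
  start0 <- c(0L, end0[-length(end0)])
  fourCcall:::.newFragmentMap(rep(chrom, length(lens)), start0, end0,
                              stats::setNames(end0[length(end0)], chrom),
                              mappable = mappable)
}

uniformMap <- function(n, fragLen = 1000L, chrom = "chrT")
  makeMap(rep(fragLen, n), chrom = chrom)

IUPAC_REGEX <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                 K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                 H = "[ACT]", V = "[ACG]", N = "[ACGT]")

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

revcompSite <- function(site)
  paste(rev(IUPAC_COMPLEMENT[strsplit(site, "")[[1]]]), collapse = "")

# regex-based digestion oracle; overlapping matches via lookahead
naiveDigest <- function(seq, site, cutOffset) {
  toRegex <- function(s)
    paste(IUPAC_REGEX[strsplit(s, "")[[1]]], collapse = "")
  scan1 <- function(s) {
    m <- gregexpr(paste0("(?=", toRegex(s), ")"), seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
  }
  cuts <- scan1(site) + cutOffset
  rc <- revcompSite(site)
  if (!identical(rc, site))
    cuts <- c(cuts, scan1(rc) + (nchar(site) - cutOffset))
  sort(unique(as.integer(cuts)))
}

randomSeq <- function(len) paste(sample(c("A", "C", "G", "T", "N"), len,
                                        replace = TRUE,
                                        prob = c(.24, .24, .24, .24, .04)),
                                 collapse = "")

# brute-force enumeration of the empirical-FDR cutoff
bruteFdrCutoff <- function(obs, shuf, alpha) {
  cmax <- max(obs, shuf, 0) + 1
  for (cc in seq_len(cmax)) {
    nobs <- sum(obs >= cc)
    fdr <- if (nobs == 0) 0 else sum(shuf >= cc) / nobs
    if (fdr < alpha) return(cc)
  }
  cmax
}

# literal straight-line transcription of the threshold procedure:
# window sums -> shuffle -> per-permutation cutoff -> sort -> top-k rank
literalThreshold <- function(counts, W, alpha, P, k, seed, chrom) {
  nw <- length(counts) - W + 1
  obs <- vapply(seq_len(nw), function(i) sum(counts[i:(i + W - 1)]), numeric(1))
  xs <- integer(P)
  for (p in seq_len(P)) {
    set.seed(permutationSeed(seed, chrom, p))
    sh <- counts[sample.int(length(counts))]
    shs <- vapply(seq_len(nw), function(i) sum(sh[i:(i + W - 1)]), numeric(1))
    xs[p] <- bruteFdrCutoff(obs, shs, alpha)
  }
  sx <- sort(xs)
  sx[min(max(P - floor(P * k / 100) + 1, 1), P)]
}

## --- simulation scenarios used by recovery/trend tests -------------------

# decay background with viewpoint at row ~1000 of 2000 fragments and one
# planted peak at row ~500; viewpoint +/-50 fragments masked
recoverySim <- function(s, nReads, spread, unit) {
  fmap <- simulateFragmentMap(2000, seed = 1000 + s)
  tab <- simulateCounts(fmap, mu = 2, dispersion = 0.3, seed = 2000 + s)
  mapRows <- which(mappableFragments(fmap))
  snap <- function(row) mapRows[which.min(abs(mapRows - row))]
  tab <- addDistanceDecay(tab, snap(1000), 50, 1.2, seed = 3000 + s)
  tab <- plantInteraction(tab, snap(500), nReads, spread, seed = 4000 + s)
  fr <- fragments(fmap)
  mask <- data.frame(chrom = "chrS",
                     start = GenomicRanges::start(fr)[950] - 1,
                     end = GenomicRanges::end(fr)[1050])
  cfg <- thresholdConfig(window = 5, fdr = 0.01, nPermutations = 200,
                         topPercentile = 5, shuffleUnit = unit,
                         seed = 6000 + s)
  ints <- callInteractions(tab, cfg, masks = mask)
  pos <- GenomicRanges::start(fr)[snap(500)]
  w <- which(GenomicRanges::start(ints) <= pos &
             GenomicRanges::end(ints) >= pos)
  list(category = if (length(w)) S4Vectors::mcols(ints)$category[w[1]]
                  else NA_integer_,
       nInteractions = length(ints),
       threshold = threshold(S4Vectors::metadata(ints)$thresholds$chrS))
}

# fixed simulated chromosome with tiered planted peaks for window-size
# trend checks: strong broad peaks persist at every window size, weak
# single-fragment spikes drop out as W grows
trendSim <- function(s, windows = c(5, 10, 31)) {
  fmap <- simulateFragmentMap(2600, seed = 100 + s)
  tab <- simulateCounts(fmap, mu = 2, dispersion = 0.3, seed = 200 + s)
  mapRows <- which(mappableFragments(fmap))
  snap <- function(row) mapRows[which.min(abs(mapRows - row))]
  tab <- addDistanceDecay(tab, snap(1050), 50, 1.2, seed = 300 + s)
  specs <- c(lapply(seq(150, 850, by = 140), function(ct) c(ct, 230, 4)),
             lapply(seq(1180, 1510, by = 110), function(ct) c(ct, 70, 2)),
             lapply(seq(1620, 1950, by = 110), function(ct) c(ct, 22, 0)),
             lapply(seq(2080, 2300, by = 110), function(ct) c(ct, 29, 0)))
  for (k in seq_along(specs)) {
    p <- specs[[k]]
    tab <- plantInteraction(tab, snap(p[1]), p[2], p[3], seed = 400 + 40 * s + k)
  }
  fr <- fragments(fmap)
  mask <- data.frame(chrom = "chrS",
                     start = GenomicRanges::start(fr)[1000] - 1,
                     end = GenomicRanges::end(fr)[1100])
  sapply(windows, function(W) {
    cfg <- thresholdConfig(window = W, fdr = 0.01, nPermutations = 100,
                           topPercentile = 5, shuffleUnit = "read",
                           seed = 500 + s)
    ints <- callInteractions(tab, cfg, masks = mask)
    c(n = length(ints),
      narrowFrac = if (length(ints))
        mean(S4Vectors::mcols(ints)$category == 3) else 0)
  })
}

# heavy-tailed fixture for the threshold-mode variance comparison: broad
# moderate plateau (large observed tail at the FDR crossing) over a very
# overdispersed background whose extremes dominate averaged FDRs
heavyTailFixture <- function() {
  n <- 1500
  fmap <- uniformMap(n, chrom = "chrH")
  set.seed(42)
  counts <- stats::rnbinom(n, mu = 2, size = 0.1)
  counts[500:799] <- counts[500:799] + stats::rpois(300, 20)
  countTable(fmap, counts)
}
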