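test_that("window prioritization follows the perturbation rules", {
  expect_identical(categorizeWindow(c(3, 4, 20, 3, 2), 10), 1L)   # Broad
  expect_identical(categorizeWindow(c(0, 9, 30, 11, 0), 25), 2L)  # Intermediate
  expect_identical(categorizeWindow(c(1, 1, 40, 1, 1), 40), 3L)   # Narrow
  # a single-fragment window can never spare its only fragment
  expect_identical(categorizeWindow(17, 5), 3L)
  # ties: leftmost maximum is perturbed; Broad test is tie-invariant
  expect_identical(categorizeWindow(c(10, 10, 0), 10), 1L)
  expect_error(categorizeWindow(c(1, 1, 1), 10), "not significant")
})

test_that("category conditions are nested: Broad implies the weaker tests", {
  set.seed(41)
  for (i in 1:500) {
    W <- sample(1:8, 1)
    counts <- rnbinom(W, mu = 8, size = 0.8)
    S <- sum(counts)
    if (S == 0) next
    thr <- sample(seq_len(max(S, 1)), 1)
    j <- which.max(counts); m <- counts[j]
    nb <- counts[c(j - 1, j + 1)[c(j > 1, j < W)]]
    repl <- if (length(nb)) mean(nb) else 0
    broadOK <- S - m >= thr
    interOK <- S - m + repl >= thr
    if (broadOK) expect_true(interOK)
    if (interOK) expect_gte(S, thr)
    cat3 <- categorizeWindow(counts, min(thr, S))
    expect_identical(cat3, if (S - m >= min(thr, S)) 1L
                           else if (S - m + repl >= min(thr, S)) 2L else 3L)
  }
})

test_that("interactions take the broadest member designation", {
  expect_identical(categorizeInteraction(c(3L, 1L)), 1L)
  expect_identical(categorizeInteraction(c(2L, 3L)), 2L)
  expect_identical(categorizeInteraction(3L), 3L)
})

test_that("merging unions overlapping windows and trims zero-count ends", {
  # one significant window over positions 11-15 with counts 0,3,9,2,0
  counts <- c(rep(0, 10), 0, 3, 9, 2, 0, rep(0, 5))
  ints <- mergeSignificantWindows(11L, counts, 5, 10)
  expect_identical(nrow(ints), 1L)
  expect_identical(ints$firstPos, 12L)
  expect_identical(ints$lastPos, 14L)
  expect_identical(ints$totalReads, 14)
  # adjacent significant windows merge into one interaction
  counts2 <- c(1, 5, 9, 6, 2, 1, 1, 1, 1, 1)
  two <- mergeSignificantWindows(c(1L, 2L), counts2, 3, 15)
  expect_identical(nrow(two), 1L)
  expect_identical(two$nWindows, 2L)
  # windows separated by more than a window length stay apart
  counts3 <- c(9, 9, 0, 0, 0, 0, 0, 0, 9, 9)
  apart <- mergeSignificantWindows(c(1L, 9L), counts3, 2, 18)
  expect_identical(nrow(apart), 2L)
  expect_identical(apart$firstPos, c(1L, 9L))
  expect_identical(apart$lastPos, c(2L, 10L))
  # maximality: no two reported interactions could be merged
  set.seed(13)
  for (i in 1:50) {
    counts <- rnbinom(60, mu = 4, size = 0.5)
    sums <- windowSums(counts, 4)
    thr <- max(1, sort(sums, decreasing = TRUE)[5])
    sig <- callWindows(sums, thr)
    if (length(sig) == 0) next
    ints <- mergeSignificantWindows(sig, counts, 4, thr)
    if (nrow(ints) > 1) {
      gap <- ints$firstPos[-1] - ints$lastPos[-nrow(ints)]
      expect_true(all(gap > 1))
    }
    expect_true(all(counts[ints$firstPos] > 0))
    expect_true(all(counts[ints$lastPos] > 0))
    expect_true(all(ints$totalReads >= thr))
  }
})

test_that("every interaction called at window size one is Narrow", {
  for (s in 1:50) {
    fmap <- simulateFragmentMap(300, seed = 70 + s,
                                unmappableFraction = 0.05)
    tab <- simulateCounts(fmap, mu = 2, dispersion = 0.3, seed = 170 + s)
    mapRows <- which(mappableFragments(fmap))
    centers <- mapRows[c(50, 150, 250)]
    for (k in seq_along(centers))
      tab <- plantInteraction(tab, centers[k], 60 + 10 * k, 0,
                              seed = 270 + 10 * s + k)
    cfg <- thresholdConfig(window = 1, fdr = 0.01, nPermutations = 100,
                           topPercentile = 5, shuffleUnit = "read",
                           seed = 370 + s)
    ints <- callInteractions(tab, cfg)
    expect_gt(length(ints), 0)
    expect_true(all(S4Vectors::mcols(ints)$category == 3L))
  }
})

test_that("replicate intersection keeps common fragments with the broadest tag", {
  callset <- function(cats) data.frame(
    chrom = "chrA", start = seq(0, by = 1000, length.out = length(cats)),
    end = seq(1000, by = 1000, length.out = length(cats)), category = cats)
  a <- callset(c(3L, 2L, 3L))
  b <- callset(c(1L, 2L, 3L))[1:2, ]     # third fragment absent
  c3 <- callset(c(3L, 3L, 2L))
  xs <- intersectReplicates(list(r1 = a, r2 = b, r3 = c3))
  expect_identical(nrow(xs$intersection), 2L)
  expect_identical(xs$intersection$category, c(1L, 2L))  # Broad retained
  expect_identical(unname(xs$uniqueCounts), c(0L, 0L, 0L))
  expect_identical(xs$pairwiseOverlap["r1", "r2"], 2L)
  # the fragment absent from one replicate is excluded
  expect_false(2000 %in% xs$intersection$start)
  # identical inputs intersect to themselves
  same <- intersectReplicates(list(a, a))
  expect_identical(nrow(same$intersection), 3L)
  expect_identical(same$intersection$category, a$category)
  expect_error(intersectReplicates(list(a)), "at least 2")
})

test_that("fragment call sets expand interactions onto analysis-set fragments", {
  sim <- simulate4C(nFragments = 400, seed = 31,
                    peaks = list(list(center = 200, nReads = 250, spread = 3)))
  cfg <- thresholdConfig(window = 5, nPermutations = 80, seed = 6)
  ints <- callInteractions(sim$table, cfg)
  expect_gt(length(ints), 0)
  fc <- fragmentCalls(ints, sim$table)
  expect_true(all(fc$category %in% 1:3))
  # members are mappable fragments inside the interaction spans
  fr <- fragments(sim$fmap)
  member <- IRanges::overlapsAny(fr, ints)
  expect_identical(nrow(fc), sum(member & mappableFragments(sim$fmap)))
})
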