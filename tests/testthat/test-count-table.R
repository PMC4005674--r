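toyMap <- makeMap(c(3L, 8L, 7L), chrom = "chrA")   # [0,3) [3,11) [11,18)

test_that("reads are assigned to the fragment containing their 5' base", {
  reads <- data.frame(chrom = c("chrA", "chrA", "chrA", "chrZ", "chrA"),
                      pos5 = c(5L, 0L, 17L, 4L, 2L),
                      strand = "+", mapq = c(30L, 30L, 30L, 30L, 0L))
  tab <- assignReads(reads, toyMap)
  expect_identical(fragmentCounts(tab), c(1L, 1L, 1L))   # mapq 0 dropped
  expect_identical(tab@unassigned, 2L)                   # chrZ + low mapq
  expect_identical(sum(fragmentCounts(tab)) + tab@unassigned, nrow(reads))
})

test_that("boundary mode keeps reads near the strand-appropriate boundary", {
  mk <- function(pos5, strand) data.frame(chrom = "chrA", pos5 = pos5,
                                          strand = strand, mapq = 30L)
  near <- assignReads(mk(14L, "+"), toyMap, mode = "boundary",
                      boundaryTolerance = 4)
  expect_identical(fragmentCounts(near), c(0L, 0L, 1L))
  far <- assignReads(mk(16L, "+"), toyMap, mode = "boundary",
                     boundaryTolerance = 4)
  expect_identical(far@unassigned, 1L)
  # exhaustive positions on the toy map against the distance rule
  for (pos in 0:17) for (strand in c("+", "-")) {
    tab <- assignReads(mk(pos, strand), toyMap, mode = "boundary",
                       boundaryTolerance = 2)
    fr <- fragments(toyMap)
    k <- findInterval(pos, GenomicRanges::start(fr) - 1L)
    bnd <- if (strand == "+") GenomicRanges::start(fr)[k] - 1L
           else GenomicRanges::end(fr)[k] - 1L
    expect_identical(sum(fragmentCounts(tab)) == 1L, abs(pos - bnd) <= 2,
                     info = paste(pos, strand))
  }
})

test_that("read conservation holds on random inputs", {
  set.seed(21)
  fmap <- simulateFragmentMap(50, meanFragmentLength = 200, seed = 5)
  for (i in 1:10) {
    reads <- data.frame(
      chrom = sample(c("chrS", "chrX"), 200, replace = TRUE, prob = c(.9, .1)),
      pos5 = sample(0:12000, 200, replace = TRUE),
      strand = sample(c("+", "-"), 200, replace = TRUE),
      mapq = sample(0:60, 200, replace = TRUE))
    tab <- assignReads(reads, fmap,
                       mode = sample(c("containment", "boundary"), 1))
    expect_identical(sum(fragmentCounts(tab)) + tab@unassigned, 200L)
  }
})

test_that("SAM text records yield strand-aware 5' positions", {
  sam <- c("@HD\tVN:1.6", "@SQ\tSN:chrA\tLN:18",
           paste("r1", 0, "chrA", 4, 42, "5M", "*", 0, 0, "ACGTA", "*",
                 sep = "\t"),
           paste("r2", 16, "chrA", 4, 42, "3M2D2M", "*", 0, 0, "ACGTA", "*",
                 "BC:Z:ACGT-TTAC", sep = "\t"),
           paste("r3", 4, "*", 0, 0, "*", "*", 0, 0, "ACGTA", "*", sep = "\t"))
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, path)
  reads <- readSamAlignments(path)
  expect_identical(nrow(reads), 2L)                 # unmapped dropped
  expect_identical(reads$pos5, c(3L, 9L))           # reverse: 3 + (7 - 1)
  expect_identical(reads$strand, c("+", "-"))
  expect_identical(reads$bcLeft, c(NA, "ACGT"))
  expect_identical(reads$bcRight, c(NA, "TTAC"))
})

test_that("retab files round-trip and reject malformed input", {
  fmap <- makeMap(c(3L, 8L, 7L), mappable = c(TRUE, TRUE, FALSE),
                  chrom = "chrA")
  tab <- countTable(fmap, c(4L, 0L, 9L), replicate = "rep1", allele = "B6",
                    unassigned = 3L)
  path <- withr::local_tempfile(fileext = ".retab")
  writeRetab(tab, path)
  back <- readRetab(path)
  expect_identical(fragmentCounts(back), fragmentCounts(tab))
  expect_identical(mappableFragments(back), mappableFragments(tab))
  expect_identical(back@replicate, "rep1")
  expect_identical(back@allele, "B6")
  expect_identical(back@unassigned, 3L)
  # second round trip is byte-identical
  path2 <- withr::local_tempfile(fileext = ".retab")
  writeRetab(back, path2)
  expect_identical(readLines(path), readLines(path2))

  lines <- readLines(path)
  neg <- sub("\t9$", "\t-1", lines)
  writeLines(neg, path2)
  expect_error(readRetab(path2), "line")
  disorder <- lines[c(1:5, 7, 6, 8)]
  writeLines(disorder, path2)
  expect_error(readRetab(path2), "order|tile")
})

test_that("masking removes whole overlapping fragments and is idempotent", {
  fmap <- uniformMap(20, chrom = "chrA")
  tab <- countTable(fmap, rep(2L, 20))
  # one-base overlap removes the whole fragment
  grazed <- applyMask(tab, data.frame(chrom = "chrA", start = 4999, end = 5001))
  expect_identical(which(!grazed@included), 5:6)
  twice <- applyMask(grazed, data.frame(chrom = "chrA", start = 4999, end = 5001))
  expect_identical(twice@included, grazed@included)
  # whole-chromosome mask empties the analysis set
  all <- applyMask(tab, data.frame(chrom = "chrA", start = 0, end = 20000))
  expect_false(any(analysisSet(all)))
  expect_error(computeThreshold(all, "chrA", thresholdConfig(seed = 1)),
               "chrA")
  # region restriction keeps only overlapping fragments
  inside <- applyMask(tab, "chrA:3000-8000", keepInside = TRUE)
  expect_identical(which(inside@included), 4:8)
})

test_that("masking out a region equals restricting to its complement", {
  fmap <- uniformMap(30, chrom = "chrA")
  set.seed(9)
  tab <- countTable(fmap, rpois(30, 3))
  # fragment-aligned region and complement
  region <- data.frame(chrom = "chrA", start = 10000, end = 18000)
  complement <- data.frame(chrom = c("chrA", "chrA"),
                           start = c(0, 18000), end = c(10000, 30000))
  a <- applyMask(tab, region, keepInside = FALSE)
  b <- applyMask(tab, complement, keepInside = TRUE)
  expect_identical(a@included, b@included)
  expect_identical(analysisSet(a), analysisSet(b))
})

test_that("barcode duplication fractions count reads sharing a pair", {
  fmap <- makeMap(c(10L, 10L, 10L), chrom = "chrA")
  reads <- data.frame(chrom = "chrA",
                      pos5 = c(1L, 2L, 3L, 11L, 12L, 13L, 14L, 21L),
                      strand = "+", mapq = 30L,
                      bcLeft = c("A", "B", "C", "A", "A", "C", "D", NA),
                      bcRight = c("X", "Y", "Z", "B", "B", "D", "E", "Q"))
  expect_message(stats <- barcodeDuplicationStats(reads, fmap), "excluded")
  expect_identical(attr(stats, "nExcluded"), 1L)
  expect_identical(stats$dupFraction[stats$index == 0L], 0)      # all distinct
  expect_identical(stats$dupFraction[stats$index == 1L], 0.5)    # {AB,AB,CD,DE}
  reads4 <- data.frame(chrom = "chrA", pos5 = c(1L, 2L, 3L, 4L), strand = "+",
                       mapq = 30L, bcLeft = "A", bcRight = "B")
  expect_identical(barcodeDuplicationStats(reads4, fmap)$dupFraction, 1)
  mixed <- data.frame(chrom = "chrA", pos5 = c(1L, 2L, 3L), strand = "+",
                      mapq = 30L, bcLeft = c("A", "A", "C"),
                      bcRight = c("B", "B", "D"))
  expect_equal(barcodeDuplicationStats(mixed, fmap)$dupFraction, 2 / 3)
})

test_that("duplicate collapsing keeps one read per fragment and barcode pair", {
  fmap <- makeMap(c(10L, 10L), chrom = "chrA")
  reads <- data.frame(chrom = "chrA", pos5 = c(1L, 2L, 3L, 11L),
                      strand = "+", mapq = 30L,
                      bcLeft = c("A", "A", "C", "A"),
                      bcRight = c("B", "B", "D", "B"))
  plain <- assignReads(reads, fmap)
  expect_identical(fragmentCounts(plain), c(3L, 1L))
  collapsed <- assignReads(reads, fmap, collapseDuplicates = TRUE)
  expect_identical(fragmentCounts(collapsed), c(2L, 1L))
})
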