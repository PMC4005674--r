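hindIII <- enzymeSpec("HindIII", "AAGCTT", 1)
nlaIII <- enzymeSpec("NlaIII", "CATG", 4)

test_that("digestion returns cut positions at recognition start + offset", {
  expect_identical(digestSequence("GGAAGCTTCCAAGCTTGG", hindIII), c(3L, 11L))
  expect_identical(digestSequence("AACATGTT", nlaIII), 6L)
  expect_identical(digestSequence("AAAAAAAA", hindIII), integer(0))
  # degenerate IUPAC codes are honored (AflIII: A^CRYGT)
  aflIII <- enzymeSpec("AflIII", "ACRYGT", 1)
  expect_identical(digestSequence("TTACGCGTTTACATGTTT", aflIII), c(3L, 11L))
  # N in the sequence never creates a site
  expect_identical(digestSequence("GGAAGCTNCC", hindIII), integer(0))
  expect_identical(digestSequence("AANATGTT", nlaIII), integer(0))
  # non-palindromic sites are matched through the reverse complement too
  fokI <- enzymeSpec("FokI-like", "GGATG", 0)
  expect_identical(digestSequence("TTGGATGTT", fokI), 2L)   # forward
  expect_identical(digestSequence("TTCATCCTT", fokI), 7L)   # reverse
  expect_error(enzymeSpec("bad", "AXGCTT", 1), "IUPAC")
  expect_error(digestSequence("ACGTQ", hindIII), "alphabet")
})

test_that("digestion agrees with a regex-based IUPAC matcher on random sequences", {
  set.seed(101)
  enzymes <- list(hindIII, nlaIII,
                  enzymeSpec("AflIII", "ACRYGT", 1),
                  enzymeSpec("DpnII", "GATC", 0),
                  enzymeSpec("FokI-like", "GGATG", 5))
  for (i in 1:1000) {
    seq <- randomSeq(1000)
    enz <- enzymes[[(i %% length(enzymes)) + 1L]]
    expect_identical(digestSequence(seq, enz),
                     naiveDigest(seq, enz@recognition, enz@cutOffset),
                     info = paste("sequence", i, enz@name))
  }
})

test_that("fragment maps tile the genome between cuts", {
  fmap <- buildFragmentMap(c(chrA = "GGAAGCTTCCAAGCTTGG"), hindIII)
  fr <- fragments(fmap)
  expect_identical(GenomicRanges::start(fr) - 1L, c(0L, 3L, 11L))
  expect_identical(GenomicRanges::end(fr), c(3L, 11L, 18L))
  expect_identical(S4Vectors::mcols(fr)$index, 0:2)
  # no cuts: one fragment spanning the chromosome
  one <- buildFragmentMap(c(chrB = "ACGTACGTAC"), hindIII)
  expect_identical(nFragments(one), 1L)
  expect_identical(GenomicRanges::width(fragments(one)), 10L)
  # cut at position 0: leading empty interval suppressed
  zero <- buildFragmentMap(c(chrC = "AAGCTTGG"), enzymeSpec("x", "AAGCTT", 0))
  expect_identical(GenomicRanges::start(fragments(zero)) - 1L, 0L)
  expect_identical(nFragments(zero), 1L)
  expect_error(buildFragmentMap(character(0), hindIII), "empty genome")
  # tiling invariant on a larger random genome
  set.seed(7)
  genome <- c(chr1 = randomSeq(5000), chr2 = randomSeq(3000))
  big <- buildFragmentMap(genome, nlaIII)
  for (chr in chromNames(big)) {
    fr <- fragments(big, chr)
    expect_identical(sum(GenomicRanges::width(fr)), nchar(genome[[chr]]))
    expect_true(all(GenomicRanges::end(fr)[-length(fr)] + 1L ==
                    GenomicRanges::start(fr)[-1L]))
  }
})

test_that("end capturability follows the amplicon-length rule", {
  # single 1000-bp fragment, one secondary cut at 300
  seq <- paste0(strrep("A", 296), "CATG", strrep("A", 700))
  expect_identical(digestSequence(seq, nlaIII), 300L)
  fmap <- buildFragmentMap(c(chrA = seq), hindIII)
  design <- libraryDesign(hindIII, nlaIII, readLength = 100,
                          primerLength = 50, sizeMin = 200, sizeMax = 650,
                          minMapLength = 20)
  ann <- annotateMappability(fmap, c(chrA = seq), design)
  mc <- S4Vectors::mcols(fragments(ann))
  expect_true(mc$end5)          # d = 300, 350 in [200, 650]
  expect_false(mc$end3)         # d = 700, 750 > 650
  expect_true(mc$mappable)
  # blind fragment (no secondary site) is unmappable
  blind <- annotateMappability(buildFragmentMap(c(chrA = strrep("A", 1000)),
                                                hindIII),
                               c(chrA = strrep("A", 1000)), design)
  expect_false(S4Vectors::mcols(fragments(blind))$mappable)
  # both ends below size selection: unmappable
  tight <- libraryDesign(hindIII, nlaIII, readLength = 100,
                         primerLength = 0, sizeMin = 900, sizeMax = 950)
  low <- annotateMappability(fmap, c(chrA = seq), tight)
  expect_false(S4Vectors::mcols(fragments(low))$mappable)
})

test_that("widening the size selection never loses mappable fragments", {
  set.seed(11)
  genome <- c(chr1 = randomSeq(20000))
  fmap <- buildFragmentMap(genome, hindIII)
  for (i in 1:20) {
    lo <- sample(30:400, 1); hi <- lo + sample(50:600, 1)
    narrow <- libraryDesign(hindIII, nlaIII, readLength = 75,
                            primerLength = sample(0:60, 1),
                            sizeMin = lo, sizeMax = hi)
    wide <- libraryDesign(hindIII, nlaIII, readLength = 75,
                          primerLength = narrow@primerLength,
                          sizeMin = max(1, lo - 25), sizeMax = hi + 200)
    mNarrow <- S4Vectors::mcols(
      fragments(annotateMappability(fmap, genome, narrow)))$mappable
    mWide <- S4Vectors::mcols(
      fragments(annotateMappability(fmap, genome, wide)))$mappable
    expect_true(all(mWide[mNarrow]))
  }
})

test_that("fragment tables round-trip through the tab-delimited format", {
  set.seed(3)
  genome <- c(chr1 = randomSeq(8000), chr2 = randomSeq(4000))
  design <- libraryDesign(hindIII, nlaIII, readLength = 75, primerLength = 40,
                          sizeMin = 60, sizeMax = 800)
  fmap <- annotateMappability(buildFragmentMap(genome, hindIII), genome, design)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeFragmentTable(fmap, path, config = list(seed = 1))
  back <- readFragmentTable(path)
  expect_identical(GenomicRanges::start(fragments(back)),
                   GenomicRanges::start(fragments(fmap)))
  expect_identical(S4Vectors::mcols(fragments(back))$mappable,
                   S4Vectors::mcols(fragments(fmap))$mappable)
  expect_identical(S4Vectors::mcols(fragments(back))$end5,
                   S4Vectors::mcols(fragments(fmap))$end5)
})
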