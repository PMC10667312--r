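test_that("segment maps load from BED-like TSV, tile checks enforced", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tid\tcentromere\tmarker\tarm\tgenes",
               "chr\t0\t100\tA\t0\t.\tleft\tg1;g2",
               "chr\t100\t250\tCEN\t1\tLEU2\tcentromeric\t.",
               "chr\t250\t400\tB\t0\t.\tright\tg3"), tsv)
  m <- loadSegmentMap(tsv)
  expect_s4_class(m, "SegmentMap")
  expect_equal(nSegments(m), 3L)
  expect_equal(totalLength(m), 400L)
  expect_equal(centromereId(m), "CEN")
  expect_equal(markerId(m), "CEN")
  expect_equal(segGenes(m)$A, c("g1", "g2"))

  # overlap, gap, duplicate ids, missing centromere are hard errors
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tid\tcentromere",
               "chr\t0\t100\tA\t1", "chr\t90\t200\tB\t0"), bad)
  expect_error(loadSegmentMap(bad), "overlap")
  writeLines(c("chrom\tstart\tend\tid\tcentromere",
               "chr\t0\t100\tA\t1", "chr\t120\t200\tB\t0"), bad)
  expect_error(loadSegmentMap(bad), "gap")
  writeLines(c("chrom\tstart\tend\tid\tcentromere",
               "chr\t0\t100\tA\t1", "chr\t100\t200\tA\t0"), bad)
  expect_error(loadSegmentMap(bad), "duplicate")
  writeLines(c("chrom\tstart\tend\tid\tcentromere",
               "chr\t0\t100\tA\t0", "chr\t100\t200\tB\t0"), bad)
  expect_error(loadSegmentMap(bad), "centromere")
})

test_that("write/load round trip is the identity on valid maps", {
  m <- syntheticSegmentMap(n = 12L, totalLength = 100000L)
  tsv <- tempfile(fileext = ".tsv")
  writeSegmentMap(m, tsv)
  m2 <- loadSegmentMap(tsv)
  expect_equal(segIds(m2), segIds(m))
  expect_equal(unname(segLengths(m2)), unname(segLengths(m)))
  expect_equal(centromereId(m2), centromereId(m))
  expect_equal(markerId(m2), markerId(m))
  expect_equal(segGenes(m2), segGenes(m))
})

test_that("the default generator map has the designed global properties", {
  m <- syntheticSegmentMap()
  expect_equal(nSegments(m), 40L)
  expect_equal(totalLength(m), 1028952L)
  expect_equal(sum(unname(segLengths(m))), 1028952L)
  cr <- causalRegionIds(m)
  expect_equal(unname(segLengths(m)[cr]), 20000L)
  expect_equal(unname(segArm(m)[cr]), "right")
  # deterministic design: two calls give the same map
  expect_equal(segLengths(syntheticSegmentMap()), segLengths(m))
})

test_that("retained fraction follows the presence definition", {
  m <- SegmentMap(c(10000L, 5000L, 85000L), ids = c("A", "CEN", "B"),
                  centromere = 2, marker = 2)
  expect_equal(retainedFraction(referenceStructure(m), m), 1.0)
  expect_equal(retainedFraction(word("CEN", "circular"), m), 0.05)
  # duplicates never raise the fraction above one
  expect_equal(retainedFraction(word(c("A", "A", "CEN", "B")), m), 1.0)
  expect_equal(retainedFraction(word(c("A", "CEN")), m,
                                weighting = "segments"), 2 / 3)
  expect_error(retainedFraction(word("ZZ"), m), "unknown")
})

test_that("preservation profile counts strains retaining each segment", {
  m <- map6()
  mk <- function(w, topo = "linear")
    new("StrainRecord", strainId = "s", structure = word(w, topo),
        events = list(), retainedFraction = 1, recoveryRatePct = 0,
        colonySizesMm = numeric(0), trisomyFlag = FALSE,
        conditionLabel = "YPD")
  pop <- list(mk(LETTERS[1:6]), mk(c("A", "C", "D")), mk(c("C", "D"),
                                                         "circular"))
  pr <- preservationProfile(pop, m)
  expect_equal(unname(pr), c(2, 1, 3, 3, 1, 1) / 3)
  expect_error(preservationProfile(list(), m), "empty")
  # unSCRaMbLEd population: all frequencies 1
  expect_true(all(preservationProfile(list(mk(LETTERS[1:6])), m) == 1))
})

test_that("deletion-biased site weights carve a visible hotspot", {
  m <- map6()
  wts <- c(E = 8, F = 8)   # elevated right-arm propensity
  p <- SimParams(eventTypeProbs = c(deletion = 1, inversion = 0,
                                    duplication = 0),
                 meanEvents = 2.5, circularizationProb = 0,
                 siteWeights = wts)
  pop <- simulatePopulation(m, p, 120, seed = 42)
  pr <- preservationProfile(pop, m)
  expect_lt(mean(pr[c("E", "F")]), mean(pr[c("A", "B")]))
})
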