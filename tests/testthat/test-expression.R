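mkFitStrain <- function(id, recovery, w = NULL, m = syntheticSegmentMap()) {
  st <- if (is.null(w)) referenceStructure(m) else word(w, "circular")
  new("StrainRecord", strainId = id, structure = st, events = list(),
      retainedFraction = retainedFraction(st, m),
      recoveryRatePct = recovery, colonySizesMm = numeric(0),
      trisomyFlag = FALSE, conditionLabel = "YPD")
}

test_that("noise-free dosage is exact: 2x duplicated, 1x buffered", {
  m <- syntheticSegmentMap()
  parent <- mkFitStrain("disome", 10)
  se <- simulateExpression(list(parent), m,
                           params = expressionParams(noise = FALSE),
                           seed = 1)
  fc <- dosageSummary(se)
  rd <- SummarizedExperiment::rowData(se)
  dup <- SummarizedExperiment::assay(se, "copies")[, "disome"] == 2L
  esrFree <- rd$esrSet == "none"
  expect_true(all(abs(fc$log2fc[dup & !rd$buffered & esrFree, 1] - 1)
                  < 1e-12))
  expect_true(all(abs(fc$log2fc[dup & rd$buffered & esrFree, 1]) < 1e-12))
  # extremes of the buffered-fraction estimator
  expect_equal(dosageSummary(se)$bufferedFraction[["disome"]],
               mean(rd$buffered[dup]), tolerance = 1e-12)
  expect_error(expressionParams(bufferedFraction = 1.5), "bufferedFraction")
})

test_that("replicate-pooled buffered fraction recovers the planted 0.10", {
  m <- syntheticSegmentMap()
  reps <- lapply(1:6, function(i) mkFitStrain(sprintf("rep%d", i), 10))
  se <- simulateExpression(reps, m, seed = 42)
  est <- dosageSummary(se)$bufferedFractionPooled
  expect_lt(abs(est - 0.10), 0.05)
})

test_that("hypergeometric enrichment matches combinatorial enumeration", {
  # toy universe of 20 genes, set of 5, 6 up-calls of which 4 in the set
  pManual <- hyperTailManual(4, 5, 20, 6)
  pHyper <- phyper(3, 5, 15, 6, lower.tail = FALSE)
  expect_equal(pHyper, pManual, tolerance = 1e-12)
  # and on a second configuration
  expect_equal(phyper(1, 8, 17, 9, lower.tail = FALSE),
               hyperTailManual(2, 8, 25, 9), tolerance = 1e-12)
})

test_that("ESR scoring flags the signature and its reversal", {
  m <- syntheticSegmentMap()
  gs <- makeEsrGeneSets()
  burdened <- mkFitStrain("disome", 5)       # burden 0.95
  relieved <- mkFitStrain("happy", 90)       # burden 0.10
  se <- simulateExpression(list(burdened, relieved), m, gs, seed = 7)
  scB <- esrScore(se, "disome", gs)
  expect_gte(scB$iesrUpFraction, 0.70)
  expect_gte(scB$resrDownFraction, 0.80)
  expect_lt(scB$qIesr, 1e-6)
  scR <- esrScore(se, "happy", gs)
  expect_lt(scR$iesrUpFraction, 0.5)
  expect_lt(scR$resrDownFraction, 0.5)

  # at zero burden the calls fall to the background false-positive rate and
  # the enrichment is not significant
  se0 <- simulateExpression(list(mkFitStrain("zero", 100)), m, gs, seed = 8)
  sc0 <- esrScore(se0, "zero", gs)
  expect_lt(sc0$iesrUpFraction, 0.05)
  expect_lt(sc0$resrDownFraction, 0.05)
  expect_gt(sc0$qIesr, 0.001)

  rep_ <- esrReversalReport(se, gs, disome = "disome")
  expect_false(rep_$reversed[rep_$strain == "disome"])
  expect_true(rep_$reversed[rep_$strain == "happy"])
  expect_error(esrScore(se, "disome", list(iESR = "nope1", rESR = "nope2")),
               "absent")
})

test_that("partial recovery gives an intermediate, graded ESR response", {
  m <- syntheticSegmentMap()
  gs <- makeEsrGeneSets()
  se <- simulateExpression(list(mkFitStrain("disome", 5),
                                mkFitStrain("half", 50)), m, gs, seed = 3)
  rep_ <- esrReversalReport(se, gs, disome = "disome")
  half <- rep_[rep_$strain == "half", ]
  full <- rep_[rep_$strain == "disome", ]
  # the response tracks burden: half recovery sits strictly between the
  # burdened parent and background
  expect_gt(half$iesrUpFraction, 0.03)
  expect_lt(half$iesrUpFraction, full$iesrUpFraction)
  expect_gt(half$resrDownFraction, 0.03)
  expect_lt(half$resrDownFraction, full$resrDownFraction)
})
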