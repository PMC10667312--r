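test_that("simulator contracts: identity limit, reproducibility, viability", {
  m <- map6()
  p0 <- SimParams(meanEvents = 0, circularizationProb = 0)
  st <- simulateStrain(m, p0, seed = 1)
  expect_equal(structureWord(st@structure),
               structureWord(referenceStructure(m)))
  expect_equal(length(st@events), 0L)

  a <- simulateStrain(m, SimParams(), seed = 99)
  b <- simulateStrain(m, SimParams(), seed = 99)
  expect_identical(structureWord(a@structure), structureWord(b@structure))
  expect_equal(length(a@events), length(b@events))

  pop <- simulatePopulation(m, SimParams(), 50, seed = 5)
  expect_equal(length(pop), 50L)
  expect_true(all(vapply(strains(pop), function(s)
    selectionFilter(s@structure, m), logical(1))))
  expect_error(SimParams(meanEvents = 0.5), "meanEvents")
})

test_that("mean retention decreases with the event budget (deletion-only)", {
  m <- map6()
  meanRet <- vapply(c(1.5, 3, 6), function(mu) {
    p <- SimParams(eventTypeProbs = c(deletion = 1, inversion = 0,
                                      duplication = 0),
                   meanEvents = mu, circularizationProb = 0)
    pop <- simulatePopulation(m, p, 200, seed = 7)
    mean(vapply(strains(pop), function(s) s@retainedFraction, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanRet) < 0))
})

test_that("fitness model follows the linear form with region bonus", {
  m <- syntheticSegmentMap()
  cr <- causalRegionIds(m)
  p <- SimParams(causalRegion = cr, noiseSd = 0)
  full <- simulateStrain(m, SimParams(meanEvents = 0,
                                      circularizationProb = 0), seed = 1)
  full <- assignFitness(full, p, seed = 1)
  expect_equal(full@recoveryRatePct, p@beta0)

  # same strain minus the causal segment: beta0 + mass + region
  st <- full
  keep <- st@structure@segIds != cr
  st@structure <- new("ChromosomeStructure", topology = "linear",
                      segIds = st@structure@segIds[keep],
                      signs = st@structure@signs[keep])
  st@retainedFraction <- retainedFraction(st@structure, m)
  st <- assignFitness(st, p, seed = 1)
  expect_equal(st@recoveryRatePct,
               p@beta0 + p@betaMass * (1 - st@retainedFraction) +
                 p@betaRegion,
               tolerance = 1e-10)
})

test_that("retention and fitness are negatively correlated by design", {
  m <- syntheticSegmentMap()
  neg <- vapply(1:8, function(r) {
    pop <- simulatePopulation(m, SimParams(), 219, seed = 400 + r)
    ret <- vapply(strains(pop), function(s) s@retainedFraction, numeric(1))
    rec <- vapply(strains(pop), function(s) s@recoveryRatePct, numeric(1))
    cor(ret, rec) < 0
  }, logical(1))
  expect_gte(mean(neg), 0.95)
})

test_that("growth curves start at the inoculum and close the DT loop", {
  gc <- simulateGrowthCurve(120)
  expect_equal(gc$od600[1L], 0.01)
  expect_equal(diff(gc$time_min), rep(20, nrow(gc) - 1L))
  expect_equal(max(gc$time_min), 48 * 60)
  expect_lt(abs(doublingTime(gc)$dtMin - 120), 1)
  # carrying capacity reached before 48 h for DT <= 180 min
  expect_gt(max(simulateGrowthCurve(180)$od600), 0.99 * 2)
  expect_error(simulateGrowthCurve(-10), "positive")
})

test_that("population-level knobs: trisomy count and circular fraction", {
  m <- syntheticSegmentMap()
  pop <- simulatePopulation(m, SimParams(trisomyFraction = 3 / 219), 219,
                            seed = 2)
  expect_equal(sum(vapply(strains(pop), function(s) s@trisomyFlag,
                          logical(1))), 3L)
  topo <- vapply(strains(pop), function(s) s@structure@topology,
                 character(1))
  expect_lt(abs(mean(topo == "circular") - 0.89), 0.05)
})
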