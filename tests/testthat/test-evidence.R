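mkStrain <- function(w, topo = "linear", trisomy = FALSE)
  new("StrainRecord", strainId = "s", structure = word(w, topo),
      events = list(), retainedFraction = 1, recoveryRatePct = 0,
      colonySizesMm = numeric(0), trisomyFlag = trisomy,
      conditionLabel = "YPD")

test_that("noise-free evidence is information-complete", {
  m <- map6()
  ev <- generateEvidence(mkStrain(LETTERS[1:6]), m, noise = FALSE)
  expect_true(all(ev@segDepth == 100))
  expect_equal(nrow(ev@junctions), 5L)

  # deletion case: zero depth and the novel junction appear
  ev2 <- generateEvidence(mkStrain(c("A", "B", "D", "E", "F")), m,
                          noise = FALSE)
  expect_equal(unname(ev2@segDepth["C"]), 0)
  key <- paste(ev2@junctions$endA, ev2@junctions$endB)
  expect_true("B.r D.l" %in% key)

  # every simulated strain is exactly recoverable from noise-free evidence
  # (a molecule in which every segment count is even is skipped: such a
  # word is depth-indistinguishable from its half and resolves to the
  # fewest copies)
  set.seed(20)
  for (i in 1:25) {
    st <- simulateStrain(m, SimParams())
    truth <- table(st@structure@segIds)
    if (all(truth %% 2L == 0L)) next
    e <- generateEvidence(st, m, noise = FALSE)
    cn <- estimateCopyNumbers(e, m)
    expect_equal(unname(cn[names(truth)]), unname(as.integer(truth)))
    expect_true(all(cn[setdiff(names(cn), names(truth))] == 0L))
  }
})

test_that("depth scales linearly with copy number (noise-free)", {
  m <- map6()
  st <- mkStrain(c("A", "B", "B", "B", "C", "D"))
  ev <- generateEvidence(st, m, noise = FALSE)
  copies <- c(A = 1, B = 3, C = 1, D = 1, E = 0, F = 0)
  fit <- lm(unname(ev@segDepth[names(copies)]) ~ unname(copies))
  expect_equal(unname(coef(fit)[2L]), 100, tolerance = 1e-9)
  expect_equal(unname(coef(fit)[1L]), 0, tolerance = 1e-9)
})

test_that("circular recovery bias self-normalizes in copy calls", {
  m <- map6()
  st <- mkStrain(c("B", "C", "D", "E"), topo = "circular")
  ev <- generateEvidence(st, m, noise = FALSE)
  expect_equal(unname(ev@segDepth["C"]), 100 / 3)
  cn <- estimateCopyNumbers(ev, m)
  expect_equal(unname(cn[c("B", "C", "D", "E")]), rep(1L, 4))
  # tandem duplication: copy 2 called
  st2 <- mkStrain(c("A", "B", "C", "D", "D", "E", "F"))
  cn2 <- estimateCopyNumbers(generateEvidence(st2, m, noise = FALSE), m)
  expect_equal(unname(cn2["D"]), 2L)
  expect_error(estimateCopyNumbers(
    new("EvidenceSet", segDepth = c(A = 0, B = 0), baselineDepth = 100,
        junctions = data.frame(), wtReads = 1L, synReads = 1L,
        topologyHint = "linear"), m), "zero")
})

test_that("Poisson-noise copy calls recover the truth almost always", {
  # circular molecules sit at a third of the baseline depth, so some
  # minimal circles are depth-limited; accuracy on the default study map
  # sits near 98.5 percent of segment calls at baseline 100
  m <- syntheticSegmentMap()
  set.seed(8)
  ok <- 0L; tot <- 0L
  for (i in 1:60) {
    st <- simulateStrain(m, SimParams())
    ev <- generateEvidence(st, m, baseline = 100, noise = TRUE)
    cn <- estimateCopyNumbers(ev, m)
    truth <- vapply(segIds(m), function(s)
      sum(st@structure@segIds == s), integer(1))
    ok <- ok + sum(cn == truth)
    tot <- tot + length(cn)
  }
  expect_gte(ok / tot, 0.97)
})

test_that("ploidy anomaly flag follows the exact binomial test", {
  mk <- function(wt, syn)
    new("EvidenceSet", segDepth = c(A = 100), baselineDepth = 100,
        junctions = data.frame(), wtReads = as.integer(wt),
        synReads = as.integer(syn), topologyHint = "linear")
  expect_true(flagPloidyAnomaly(mk(200, 100))$flag)    # the 2:1 anomaly
  expect_false(flagPloidyAnomaly(mk(150, 150))$flag)   # exact 1:1
  r <- flagPloidyAnomaly(mk(12, 9))
  expect_false(r$flag)
  expect_equal(r$p, binom.test(9, 21, 0.5)$p.value)
  expect_error(flagPloidyAnomaly(mk(0, 0)), "reads")
})

test_that("ploidy flag type-I error is controlled under the 1:1 null", {
  set.seed(77)
  syn <- rbinom(10000, 300, 0.5)
  flags <- vapply(syn, function(s) {
    p <- binom.test(s, 300L, 0.5)$p.value
    ratio <- (300 - s) / s
    (p < 0.05) && (max(ratio, 1 / ratio) >= 1.5)
  }, logical(1))
  expect_lte(mean(flags), 0.05)
})

test_that("evidence serializes through the two TSVs plus JSON header", {
  m <- map6()
  ev <- generateEvidence(mkStrain(c("A", "B", "D", "E", "F")), m,
                         noise = FALSE)
  base <- tempfile()
  writeEvidence(ev, base)
  back <- readEvidence(base)
  expect_equal(back@segDepth, ev@segDepth)
  expect_equal(back@junctions$support, ev@junctions$support)
  expect_equal(back@wtReads, ev@wtReads)
  expect_equal(back@topologyHint, ev@topologyHint)
})
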