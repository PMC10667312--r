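mkEv <- function(w, topo = "linear") {
  m <- map6()
  st <- new("StrainRecord", strainId = "s", structure = word(w, topo),
            events = list(), retainedFraction = 1, recoveryRatePct = 0,
            colonySizesMm = numeric(0), trisomyFlag = FALSE,
            conditionLabel = "YPD")
  generateEvidence(st, m, noise = FALSE)
}

test_that("adjacency graphs type junctions and surface conflicts", {
  m <- map6()
  g <- buildGraph(mkEv(c("A", "B", "C", "D", "F")), m)
  expect_s4_class(g, "AdjacencyGraph")
  expect_equal(unname(g@copies["E"]), 0L)
  expect_equal(nrow(g@conflicts), 0L)

  # a junction touching a zero-copy segment is reported, not dropped
  ev <- mkEv(c("A", "B", "C", "D", "F"))
  ev@segDepth["B"] <- 0
  g2 <- buildGraph(ev, m)
  expect_gt(nrow(g2@conflicts), 0L)
  expect_match(g2@conflicts$reason[1L], "zero-copy")
})

test_that("structure inference solves the canonical textbook cases", {
  m <- map6()
  # deletion: unique traversal
  cands <- inferStructures(buildGraph(mkEv(c("A", "B", "C", "D", "F")), m),
                           m)
  expect_length(cands, 1L)
  expect_equal(structureWord(cands[[1L]]), c("A", "B", "C", "D", "F"))
  # reference evidence reproduces the reference
  cands <- inferStructures(buildGraph(mkEv(LETTERS[1:6]), m), m)
  expect_length(cands, 1L)
  expect_true(sameStructure(cands[[1L]], referenceStructure(m), m))
  # inversion case
  cands <- inferStructures(buildGraph(mkEv(c("A", "-C", "-B", "D", "E",
                                             "F")), m), m)
  expect_true(any(vapply(cands, sameStructure, logical(1),
                         word(c("A", "-C", "-B", "D", "E", "F")), m)))
  # tandem duplication ranked first by parsimony
  cands <- inferStructures(buildGraph(mkEv(c("A", "B", "B", "C", "D", "E",
                                             "F")), m), m)
  expect_true(sameStructure(cands[[1L]],
                            word(c("A", "B", "B", "C", "D", "E", "F")), m))
})

test_that("noise-free evidence always contains the true structure", {
  m <- map6()
  ref <- referenceStructure(m)
  found <- 0L; eligible <- 0L
  for (i in 1:60) {
    set.seed(3000 + i)
    st <- simulateStrain(m, SimParams())
    if (all(table(st@structure@segIds) %% 2L == 0L)) next  # see vignette
    eligible <- eligible + 1L
    cands <- inferStructures(buildGraph(generateEvidence(st, m,
                                                         noise = FALSE),
                                        m), m)
    if (any(vapply(cands, sameStructure, logical(1), st@structure, m)))
      found <- found + 1L
  }
  expect_gte(eligible, 50L)
  expect_equal(found, eligible)
})

test_that("minimal event distance solves the simple cases exactly", {
  m <- map6()
  ref <- referenceStructure(m)
  expect_equal(minEventDistance(ref, ref, m)@k, 0L)
  d1 <- minEventDistance(ref, word(c("A", "B", "D", "E", "F")), m)
  expect_equal(d1@k, 1L)
  expect_true(d1@isMinimal)
  expect_equal(eventKinds(d1@events), "deletion")
  d2 <- minEventDistance(ref, word(c("A", "-C", "-B", "D", "E", "F")), m)
  expect_equal(d2@k, 1L)
  expect_equal(eventKinds(d2@events), "inversion")
  # replay invariant
  expect_true(sameStructure(replayEvents(ref, d2@events),
                            word(c("A", "-C", "-B", "D", "E", "F")), m))
})

test_that("decompositions replay correctly for random scrambles", {
  m <- map6()
  ref <- referenceStructure(m)
  for (i in 1:40) {
    set.seed(500 + i)
    st <- simulateStrain(m, SimParams())
    d <- minEventDistance(ref, st@structure, m)
    expect_true(sameStructure(replayEvents(ref, d@events), st@structure, m))
    expect_lte(d@k, length(st@events))  # parsimony never exceeds history
  }
})

test_that("population classification pools event types as defined", {
  mkDec <- function(kinds) new("EventDecomposition",
                               events = lapply(kinds, function(k)
                                 ScrambleEvent(k, 2, 3)),
                               k = length(kinds), isMinimal = TRUE)
  cl <- classifyPopulation(list(mkDec(c("deletion", "deletion")),
                                mkDec(c("inversion"))))
  expect_equal(unname(cl$typeFractions["deletion"]), 2 / 3)
  expect_equal(cl$meanEvents, 1.5)
  expect_equal(cl$circularFraction, 0)

  cl0 <- classifyPopulation(list(mkDec(character(0)), mkDec(character(0))))
  expect_true(all(cl0$typeFractions == 0))
  expect_equal(cl0$meanEvents, 0)

  clC <- classifyPopulation(list(mkDec(c("circularization", "deletion")),
                                 mkDec("inversion")))
  expect_equal(clC$circularFraction, 0.5)
  expect_equal(unname(clC$typeFractions["deletion"]), 0.5)
})

test_that("round trip recovers per-strain counts for clean decompositions", {
  m <- map6()
  ref <- referenceStructure(m)
  checked <- 0L
  for (i in 1:40) {
    set.seed(9200 + i)
    st <- simulateStrain(m, SimParams(meanEvents = 2))
    cands <- inferStructures(buildGraph(generateEvidence(st, m,
                                                         noise = FALSE),
                                        m), m)
    if (length(cands) != 1L) next
    d <- minEventDistance(ref, cands[[1L]], m)
    if (!d@isMinimal) next
    checked <- checked + 1L
    expect_lte(d@k, length(st@events))
    expect_true(sameStructure(replayEvents(ref, d@events), st@structure, m))
  }
  expect_gt(checked, 10L)
})
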