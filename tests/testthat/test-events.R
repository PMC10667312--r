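ref6 <- function() referenceStructure(map6())

test_that("events act on spans as defined", {
  r <- ref6()
  expect_equal(structureWord(applyEvent(r, ScrambleEvent("deletion", 3, 4))),
               c("A", "B", "D", "E", "F"))
  inv <- ScrambleEvent("inversion", 2, 4)
  expect_equal(structureWord(applyEvent(r, inv)),
               c("A", "-C", "-B", "D", "E", "F"))
  # inversion is an involution
  expect_equal(structureWord(applyEvent(applyEvent(r, inv), inv)),
               structureWord(r))
  expect_equal(structureWord(applyEvent(r, ScrambleEvent("duplication",
                                                         4, 5))),
               c("A", "B", "C", "D", "D", "E", "F"))
  circ <- applyEvent(r, ScrambleEvent("circularization", 2, 6))
  expect_equal(topology(circ), "circular")
  expect_equal(structureWord(circ), c("B", "C", "D", "E"))
})

test_that("junction validity and the circular lock-in are enforced", {
  r <- ref6()
  # ends are telomeres, not loxPsym sites, on a linear molecule
  expect_error(applyEvent(r, ScrambleEvent("deletion", 1, 3)), "range")
  expect_error(applyEvent(r, ScrambleEvent("deletion", 3, 7)), "range")
  circ <- applyEvent(r, ScrambleEvent("circularization", 2, 6))
  expect_error(applyEvent(circ, ScrambleEvent("circularization", 2, 3)),
               "circular")
  # wrapping spans are legal on circles: (B,C,D,E) delete wrap span E..B
  out <- applyEvent(circ, ScrambleEvent("deletion", 4, 2))
  expect_equal(sort(unique(out@segIds)), c("C", "D"))
  expect_error(applyEvent(circ, ScrambleEvent("deletion", 1, 1)))
})

test_that("multiset conservation holds for each event kind", {
  set.seed(11)
  m <- map6()
  r <- referenceStructure(m)
  for (i in 1:40) {
    st <- r
    # random prefix of events to reach varied states
    for (k in seq_len(sample(0:3, 1))) {
      res <- ScrambleDisome:::.sampleEvent(st, SimParams(), m)
      if (is.null(res)) break
      st <- res$structure
    }
    res <- ScrambleDisome:::.sampleEvent(st, SimParams(), m)
    if (is.null(res)) next
    before <- table(st@segIds)
    after <- table(res$structure@segIds)
    kind <- res$event@kind
    if (kind == "inversion") {
      expect_equal(after, before)
    } else if (kind == "deletion") {
      expect_true(all(after[names(after)] <= before[names(after)]))
    } else if (kind == "duplication") {
      extra <- as.integer(sum(after)) - as.integer(sum(before))
      expect_gte(extra, 1L)
      expect_true(all(before[names(before)] <= after[names(before)]))
    }
  }
})

test_that("recorded events replay to the recorded structure exactly", {
  m <- map6()
  r <- referenceStructure(m)
  for (seed in 1:30) {
    set.seed(seed)
    st <- simulateStrain(m, SimParams())
    rp <- replayEvents(r, st@events)
    expect_identical(rp@segIds, st@structure@segIds)
    expect_identical(rp@signs, st@structure@signs)
    expect_identical(rp@topology, st@structure@topology)
  }
})

test_that("circular structures never revert to linear", {
  m <- map6()
  set.seed(3)
  for (i in 1:20) {
    st <- simulateStrain(m, SimParams(circularizationProb = 1))
    expect_equal(topology(st@structure), "circular")
    # push many more events: topology must stay circular
    s <- st@structure
    for (k in 1:10) {
      res <- ScrambleDisome:::.sampleEvent(s, SimParams(), m)
      if (is.null(res)) break
      s <- res$structure
      expect_equal(topology(s), "circular")
    }
  }
})
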