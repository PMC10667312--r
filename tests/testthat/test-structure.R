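test_that("canonical form identifies rotations and mirrors of circles", {
  a <- word(c("A", "B", "C"), "circular")
  expect_true(sameStructure(a, word(c("B", "C", "A"), "circular")))
  expect_true(sameStructure(a, word(c("-C", "-B", "-A"), "circular")))
  expect_false(sameStructure(a, word(c("A", "C", "B"), "circular")))
  # derived example: (B,-A) canonicalizes to (A,-B)
  expect_equal(structureWord(canonicalForm(word(c("B", "-A"), "circular"))),
               c("A", "-B"))
  # linear words only mirror
  expect_equal(structureWord(canonicalForm(word(c("A", "B")))), c("A", "B"))
  expect_equal(structureWord(canonicalForm(word(c("-B", "-A")))),
               c("A", "B"))
  expect_error(ChromosomeStructure(character(0)), "nonempty")
})

test_that("canonical form is idempotent and invariant on all short words", {
  ids <- c("A", "B", "C")
  set.seed(1)
  for (len in 2:4) {
    for (rep in 1:25) {
      w <- paste0(sample(c("", "-"), len, replace = TRUE),
                  sample(ids, len, replace = TRUE))
      for (topo in c("linear", "circular")) {
        x <- word(w, topo)
        cf <- canonicalForm(x)
        expect_equal(structureWord(canonicalForm(cf)), structureWord(cf))
        # every rotation (circular) and the mirror map to the same form
        mir <- ScrambleDisome:::.mirror(x)
        expect_equal(structureWord(canonicalForm(mir)), structureWord(cf))
        if (topo == "circular") {
          for (k in seq_len(len - 1L)) {
            rot <- ScrambleDisome:::.rotate(x, k)
            expect_equal(structureWord(canonicalForm(rot)),
                         structureWord(cf))
          }
        }
      }
    }
  }
})

test_that("structure words serialize through text and JSON forms", {
  x <- word(c("A", "-C", "-B", "D"), "circular")
  line <- formatStructure(x)
  expect_match(line, "^topology:circular\t")
  y <- parseStructure(line)
  expect_equal(structureWord(y), structureWord(x))
  expect_equal(topology(y), "circular")

  z <- structureFromJson(structureToJson(x))
  expect_equal(structureWord(z), structureWord(x))

  path <- tempfile()
  writeStructures(list(s1 = x, s2 = word("A")), path)
  back <- readStructures(path)
  expect_equal(names(back), c("s1", "s2"))
  expect_equal(structureWord(back$s1), structureWord(x))
})
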