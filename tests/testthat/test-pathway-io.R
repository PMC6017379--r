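test_that("substrate-product rule derives edges and reversible closure holds", {
  p <- Pathway("P", "O", list(
    rxn("u1", inputs = "C0", outputs = "C1"),
    rxn("u2", inputs = "C1", outputs = "C2")
  ), deriveEdges = TRUE)
  expect_equal(unname(pathwayEdges(p)), matrix(c("u1", "u2"), 1))

  single <- Pathway("P", "O", list(rxn("u1")), deriveEdges = TRUE)
  expect_equal(nReactions(single), 1L)
  expect_equal(nrow(pathwayEdges(single)), 0L)

  rev2 <- Pathway("P", "O", list(
    rxn("u1", inputs = "C0", outputs = "C1", reversible = TRUE),
    rxn("u2", inputs = "C1", outputs = "C2", reversible = TRUE)
  ), deriveEdges = TRUE)
  e <- pathwayEdges(rev2)
  expect_setequal(paste(e[, 1], e[, 2]), c("u1 u2", "u2 u1"))
})

test_that("self-loops are dropped and duplicate reaction ids rejected", {
  p <- Pathway("P", "O", list(rxn("u1", inputs = "C1", outputs = "C1")),
               deriveEdges = TRUE)
  expect_equal(nrow(pathwayEdges(p)), 0L)
  expect_error(
    Pathway("P", "O", list(rxn("a"), rxn("a"))),
    "duplicate reaction id"
  )
})

test_that("native dialects round-trip randomly generated pathways", {
  set.seed(71)
  for (i in 1:10) {
    p <- randomPathway(sample(2:9, 1), pid = sprintf("pw%d", i))
    for (dialect in c("native-json", "native-tsv")) {
      f <- tempfile(fileext = if (dialect == "native-json") ".json" else ".tsv")
      writePathway(p, f, dialect)
      q <- readPathway(f, dialect)
      expect_identical(reactions(q), reactions(p))
      expect_identical(pathwayEdges(q), pathwayEdges(p))
      expect_identical(pathwayId(q), pathwayId(p))
      expect_identical(organismId(q), organismId(p))
      unlink(f)
    }
  }
})

test_that("unicode compound ids survive a JSON round trip", {
  p <- Pathway("P", "O", list(rxn("u1", inputs = "α-glc",
                                  outputs = "β-glc")))
  f <- tempfile(fileext = ".json")
  writePathway(p, f)
  expect_identical(reactions(readPathway(f))$inputs[[1]], "α-glc")
  unlink(f)
})

test_that("edge derivation is idempotent and closure is preserved on re-read", {
  set.seed(72)
  for (i in 1:8) {
    p <- randomPathway(sample(3:8, 1))
    q <- Pathway(pathwayId(p), organismId(p), reactions(p),
                 edges = pathwayEdges(p), deriveEdges = TRUE)
    expect_identical(pathwayEdges(q), pathwayEdges(p))
  }
  # all-reversible pathways have symmetric edge sets
  for (i in 1:5) {
    n <- sample(3:7, 1)
    rx <- lapply(seq_len(n), function(j) {
      rxn(sprintf("r%d", j), inputs = sprintf("c%d", sample(n, 1)),
          outputs = sprintf("c%d", sample(n, 1)), reversible = TRUE)
    })
    p <- Pathway("P", "O", rx, deriveEdges = TRUE)
    e <- pathwayEdges(p)
    if (nrow(e) > 0) {
      expect_setequal(paste(e[, 1], e[, 2]), paste(e[, 2], e[, 1]))
    }
  }
})

test_that("malformed pathway files raise parse errors naming the location", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("#pathway_id\tP", "#organism_id\tO", "#reactions",
               "r1\t1.1.1.1\tC1"), f)
  expect_error(readPathway(f, "native-tsv"), "line 4")
  writeLines("{not json", f)
  expect_error(readPathway(f, "native-json"), "malformed")
  unlink(f)
})

test_that("compound table reads symmetrically with identity policy", {
  f <- tempfile(fileext = ".tsv")
  writeLines("C1\tC2\t0.6", f)
  tab <- readCompoundTable(f)
  expect_equal(compoundSimilarity(tab, "C2", "C1"), 0.6)
  expect_equal(compoundSimilarity(tab, "C1", "C2"), 0.6)
  # empty file -> identity only
  writeLines(character(0), f)
  tab0 <- readCompoundTable(f)
  expect_equal(compoundSimilarity(tab0, "C1", "C1"), 1)
  expect_equal(compoundSimilarity(tab0, "C1", "C2"), 0)
  # identity pair with non-1 score is overridden with a warning
  writeLines("C1\tC1\t0.4", f)
  expect_warning(tabi <- readCompoundTable(f), "overridden")
  expect_equal(compoundSimilarity(tabi, "C1", "C1"), 1)
  # out-of-range score is an error
  writeLines("C1\tC2\t1.4", f)
  expect_error(readCompoundTable(f), "outside")
  unlink(f)
})

test_that("the KGML subset reader builds reactions, ECs and derived edges", {
  f <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<pathway name="path:tst00010" org="tst">',
    '  <entry id="1" name="ec:1.2.3.4" type="enzyme" reaction="rn:R001"/>',
    '  <entry id="2" name="ec:2.3.4.5 ec:2.3.4.6" type="enzyme" reaction="rn:R002"/>',
    '  <reaction id="10" name="rn:R001" type="irreversible">',
    '    <substrate id="20" name="cpd:C00001"/>',
    '    <product id="21" name="cpd:C00002"/>',
    '  </reaction>',
    '  <reaction id="11" name="rn:R002" type="reversible">',
    '    <substrate id="21" name="cpd:C00002"/>',
    '    <product id="22" name="cpd:C00003"/>',
    '  </reaction>',
    '</pathway>'), f)
  p <- readPathway(f, "kgml")
  expect_equal(organismId(p), "tst")
  expect_equal(reactionIds(p), c("R001", "R002"))
  expect_equal(reactions(p)$ec[[2]], c("2.3.4.5", "2.3.4.6"))
  expect_true(reactions(p)$reversible[2])
  expect_equal(unname(pathwayEdges(p)), matrix(c("R001", "R002"), 1))
  unlink(f)
})

test_that("PHYLIP distance matrices round-trip", {
  d <- matrix(c(0, .25, .4, .25, 0, .1, .4, .1, 0), 3,
              dimnames = list(c("orgA", "orgB", "orgC"),
                              c("orgA", "orgB", "orgC")))
  f <- tempfile(fileext = ".phy")
  writePhylipDist(d, f)
  expect_equal(readPhylipDist(f), d, tolerance = 1e-6)
  unlink(f)
})
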