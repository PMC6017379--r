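test_that("greedy matching follows the heaviest-edge trace", {
  w <- matrix(c(0.9, 0.7, 0.8, 0.6), 2,
              dimnames = list(c("r1", "r2"), c("c1", "c2")))
  m <- greedyMatching(w)
  expect_equal(m$row, c("r1", "r2"))
  expect_equal(m$col, c("c1", "c2"))
  # a tie on 0.9 is broken lexicographically: (r1,c2) claims it first
  w2 <- matrix(c(0.5, 0.9, 0.9, 0.1), 2,
               dimnames = list(c("r1", "r2"), c("c1", "c2")))
  m2 <- greedyMatching(w2)
  expect_setequal(paste(m2$row, m2$col), c("r1 c2", "r2 c1"))
  # nothing admissible
  expect_equal(nrow(greedyMatching(w * 0.1, minWeight = 0.5)), 0L)
  expect_equal(nrow(greedyMatching(matrix(0, 2, 2,
    dimnames = list(c("r1", "r2"), c("c1", "c2"))))), 0L)
})

test_that("greedy matching agrees with an independent trace and is one-to-one", {
  set.seed(11)
  for (i in 1:30) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    w <- matrix(round(stats::runif(n * m), 2), n,
                dimnames = list(sprintf("r%d", sample(n)),
                                sprintf("c%d", sample(m))))
    got <- greedyMatching(w)
    ref <- refGreedyTrace(w)
    expect_equal(got[order(got$row), ], ref, ignore_attr = TRUE)
    expect_false(anyDuplicated(got$row) > 0)
    expect_false(anyDuplicated(got$col) > 0)
  }
})

test_that("greedy matching is invariant under row and column permutation", {
  set.seed(12)
  for (i in 1:15) {
    n <- sample(3:6, 1)
    w <- matrix(sample(round(stats::runif(4), 2), n * n, replace = TRUE), n,
                dimnames = list(sprintf("r%d", 1:n), sprintf("c%d", 1:n)))
    m0 <- greedyMatching(w)
    wp <- w[sample(n), sample(n), drop = FALSE]
    mp <- greedyMatching(wp)
    expect_equal(mp[order(mp$row), ], m0[order(m0$row), ],
                 ignore_attr = TRUE)
  }
})

test_that("exact matching mode is an optimal assignment", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(2:4, 1); m <- sample(2:4, 1)
    w <- matrix(round(stats::runif(n * m), 3), n,
                dimnames = list(sprintf("r%d", 1:n), sprintf("c%d", 1:m)))
    got <- pathphylo:::exactMatching(w)
    expect_equal(sum(got$weight), bruteAssignmentValue(w), tolerance = 1e-9)
    expect_false(anyDuplicated(got$row) > 0)
    expect_false(anyDuplicated(got$col) > 0)
  }
})

test_that("pairwise union of a pathway with itself has no gaps", {
  p <- chainPathway(4)
  u <- buildPairwiseUnion(p, p)
  mem <- compositeNodes(u)
  expect_equal(mem[, 1], mem[, 2], ignore_attr = TRUE)
  expect_false(anyNA(mem))
  expect_equal(diag(homologicalMatrix(u)), rep(1, 4), ignore_attr = TRUE)
})

test_that("union cardinality follows the anchor and gaps fill the deficit", {
  g3 <- chainPathway(3, org = "A")
  g2 <- chainPathway(2, pid = "P", org = "B")
  u <- buildPairwiseUnion(g3, g2)
  expect_equal(nrow(compositeNodes(u)), 3L)
  expect_equal(sum(is.na(compositeNodes(u)[, "B"])), 1L)
  # everything dissimilar: all gaps
  far <- Pathway("P", "B", list(
    rxn("x1", ec = "9.9.9.9", inputs = "z1", outputs = "z2"),
    rxn("x2", ec = "9.9.8.8", inputs = "z2", outputs = "z3")
  ), deriveEdges = TRUE)
  u2 <- buildPairwiseUnion(chainPathway(3, org = "A"), far, minWeight = 0.2)
  expect_true(all(is.na(compositeNodes(u2)[, "B"])))
})

test_that("homological similarity combines cross and within terms", {
  expect_equal(homologicalSimilarity(1, 1, 1, 1), 1)
  expect_equal(homologicalSimilarity(1, 1, 0, 0), 0.5)
  expect_equal(homologicalSimilarity(0, 0, 0, 0), 0)
  # unscaled form reaches 2
  expect_equal(homologicalSimilarity(1, 1, 1, 1, rescale = FALSE), 2)
  # direct arithmetic oracle on random terms
  set.seed(14)
  for (i in 1:50) {
    s <- stats::runif(4)
    expect_equal(homologicalSimilarity(s[1], s[2], s[3], s[4]),
                 (s[3] + s[4] + s[1] + s[2]) / 4)
  }
})

test_that("a fully gapped partner contributes zero homological similarity", {
  g3 <- chainPathway(3, org = "A")
  far <- Pathway("P", "B", list(
    rxn("x1", ec = "9.9.9.9", inputs = "z1", outputs = "z2"),
    rxn("x2", ec = "9.8.7.6", inputs = "z2", outputs = "z3"),
    rxn("x3", ec = "8.7.6.5", inputs = "z3", outputs = "z4")
  ), deriveEdges = TRUE)
  u <- buildPairwiseUnion(g3, far, minWeight = 0.5)
  expect_true(all(is.na(compositeNodes(u)[, "B"])))
  expect_true(all(homologicalMatrix(u) == 0))
})

test_that("merging unions sums member slots and similarity matrices", {
  pA <- chainPathway(3, org = "A")
  pB <- chainPathway(3, org = "B")
  pC <- chainPathway(3, org = "C")
  u1 <- buildPairwiseUnion(pA, pB)
  u2 <- buildPairwiseUnion(pA, pC)
  # identity merge for k = 2
  m1 <- mergeUnions(list(u1))
  expect_identical(homologicalMatrix(m1), homologicalMatrix(u1))
  expect_identical(compositeNodes(m1), compositeNodes(u1))
  # k = 3 with identical pathways: members identical, H doubled
  m <- mergeUnions(list(u1, u2))
  expect_equal(ncol(compositeNodes(m)), 3L)
  expect_equal(compositeNodes(m)[, "B"], compositeNodes(m)[, "C"],
               ignore_attr = TRUE)
  expect_equal(homologicalMatrix(m), 2 * homologicalMatrix(u1))
  expect_error(mergeUnions(list(u1, buildPairwiseUnion(pB, pC))),
               "same anchor")
})

test_that("merged union H matrices are symmetric non-negative with summed diagonals", {
  set.seed(15)
  for (i in 1:8) {
    paths <- lapply(1:3, function(j) {
      set.seed(15 * i + j)
      randomPathway(5, org = sprintf("org%d", j))
    })
    os <- organismSet(paths)
    u <- buildUnionGraph(os, "P")
    H <- homologicalMatrix(u)
    expect_equal(H, t(H))
    expect_true(all(H >= 0))
    expect_true(all(H <= 2 + 1e-12))  # sum of 2 pairwise matrices in [0,1]
    # one-to-one: no reaction appears in two composite nodes
    mem <- compositeNodes(u)
    for (cc in colnames(mem)) {
      v <- mem[, cc]
      expect_false(anyDuplicated(v[!is.na(v)]) > 0)
    }
  }
})

test_that("the anchor pathway is the largest, ties broken by organism id", {
  big <- chainPathway(4, org = "zz")
  small <- chainPathway(3, pid = "P", org = "aa")
  os <- organismSet(list(big, small))
  expect_equal(buildUnionGraph(os, "P")@anchorOrganism, "zz")
  tieA <- chainPathway(3, org = "bb")
  os2 <- organismSet(list(tieA, small))
  expect_equal(buildUnionGraph(os2, "P")@anchorOrganism, "aa")
})
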