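test_that("LCCS of a self-mapped path is the whole path", {
  p <- chainPathway(3)
  mod <- list(nodes = reactionIds(p), edges = pathwayEdges(p))
  mapping <- stats::setNames(reactionIds(p), reactionIds(p))
  r <- lccs(mod, p, mapping)
  expect_equal(r$nNodes, 3L)
  expect_equal(r$nEdges, 2L)
})

test_that("LCCS respects the mapping and picks the largest component", {
  # module a1->a2->a3 mapped onto b1->b2 with b3 isolated
  modP <- Pathway("P", "A", list(
    rxn("a1", inputs = "x0", outputs = "x1"),
    rxn("a2", inputs = "x1", outputs = "x2"),
    rxn("a3", inputs = "x2", outputs = "x3")
  ), deriveEdges = TRUE)
  mod <- list(nodes = reactionIds(modP), edges = pathwayEdges(modP))
  target <- Pathway("P", "B", list(
    rxn("b1", inputs = "y0", outputs = "y1"),
    rxn("b2", inputs = "y1", outputs = "y2"),
    rxn("b3", inputs = "z0", outputs = "z1")
  ), deriveEdges = TRUE)
  r <- lccs(mod, target, c(a1 = "b1", a2 = "b2", a3 = "b3"))
  expect_setequal(r$nodes, c("a1", "a2"))
  expect_equal(r$nEdges, 1L)
  # no conserved edges: single node, zero edges
  r0 <- lccs(mod, target, c(a1 = "b2", a2 = "b1", a3 = "b3"))
  expect_equal(r0$nNodes, 1L)
  expect_equal(r0$nEdges, 0L)
  # empty mapping: empty result
  rE <- lccs(mod, target, stats::setNames(character(0), character(0)))
  expect_equal(rE$nNodes, 0L)
})

test_that("LCCS equals the exhaustive enumeration oracle on random graphs", {
  set.seed(41)
  for (i in 1:60) {
    nA <- sample(3:8, 1)
    nB <- sample(3:8, 1)
    pa <- randomPathway(nA, org = "A")
    pb <- randomPathway(nB, org = "B")
    m <- min(nA, nB)
    sel <- sample(reactionIds(pa), m)
    mapping <- stats::setNames(sample(reactionIds(pb), m), sel)
    mod <- list(nodes = reactionIds(pa), edges = pathwayEdges(pa))
    got <- lccs(mod, pb, mapping)
    want <- bruteLccs(mod, pb, mapping)
    expect_equal(got$nNodes, want$nNodes)
    expect_equal(got$nEdges, want$nEdges)
  }
})

test_that("pathway similarity is 1 for identical pathways and 0 without conservation", {
  p <- chainPathway(4, org = "A")
  q <- chainPathway(4, pid = "P", org = "B")
  os <- organismSet(list(p, q))
  u <- buildUnionGraph(os, "P")
  cl <- new("ClusterResult", exemplars = 1L, assignment = rep(1L, 4),
            iterations = 0L, converged = TRUE)
  mm <- extractModules(cl, u, os)
  expect_equal(pathwaySimScore(p, q, mm, u), 1)
  # completely unrelated partner
  far <- Pathway("P", "B", list(
    rxn("x1", ec = "9.9.9.9", inputs = "z1", outputs = "z2"),
    rxn("x2", ec = "8.8.8.8", inputs = "z2", outputs = "z3"),
    rxn("x3", ec = "7.7.7.7", inputs = "z3", outputs = "z4"),
    rxn("x4", ec = "6.6.6.6", inputs = "z4", outputs = "z5")
  ), deriveEdges = TRUE)
  os2 <- organismSet(list(p, far))
  u2 <- buildUnionGraph(os2, "P", minWeight = 0.3)
  mm2 <- extractModules(cl, u2, os2)
  expect_equal(pathwaySimScore(p, far, mm2, u2), 0)
})

test_that("pathway similarity matches the worked prefix-mapping count", {
  # 4-node path (3 edges) vs its 3-node prefix (2 edges):
  # min(2,2) / max(3,2) = 2/3
  gi <- chainPathway(4, org = "A")
  gj <- chainPathway(3, pid = "P", org = "B")
  os <- organismSet(list(gi, gj))
  u <- buildUnionGraph(os, "P")
  cl <- new("ClusterResult", exemplars = 1L, assignment = rep(1L, 4),
            iterations = 0L, converged = TRUE)
  mm <- extractModules(cl, u, os)
  expect_equal(pathwaySimScore(gi, gj, mm, u), 2 / 3)
  expect_equal(pathwaySimScore(gj, gi, mm, u), 2 / 3)
})

test_that("edgeless pathway pairs score 1 when mapped and 0 otherwise", {
  a <- Pathway("P", "A", list(rxn("u1")))
  b <- Pathway("P", "B", list(rxn("v1")))
  os <- organismSet(list(a, b))
  u <- buildUnionGraph(os, "P")
  cl <- new("ClusterResult", exemplars = 1L, assignment = 1L,
            iterations = 0L, converged = TRUE)
  mm <- extractModules(cl, u, os)
  expect_equal(pathwaySimScore(a, b, mm, u), 1)
  bFar <- Pathway("P", "B", list(rxn("v1", ec = "9.9.9.9", inputs = "q1",
                                     outputs = "q2")))
  os2 <- organismSet(list(a, bFar))
  u2 <- buildUnionGraph(os2, "P", minWeight = 0.3)
  mm2 <- extractModules(cl, u2, os2)
  expect_equal(pathwaySimScore(a, bFar, mm2, u2), 0)
})

test_that("deleting a conserved edge never increases pathway similarity", {
  set.seed(43)
  for (i in 1:6) {
    gi <- randomPathway(6, org = "A")
    gj <- Pathway("P", "B", reactions(gi), edges = pathwayEdges(gi))
    os <- organismSet(list(gi, gj))
    u <- buildUnionGraph(os, "P")
    cl <- affinityPropagation(homologicalMatrix(u), seed = i)
    mm <- extractModules(cl, u, os)
    s0 <- pathwaySimScore(gi, gj, mm, u)
    e <- pathwayEdges(gj)
    if (nrow(e) == 0) next
    rxj <- reactions(gj)
    rev <- stats::setNames(rxj$reversible, rxj$id)
    # drop a non-reversible-pair edge so the closure does not restore it
    drop <- which(!(rev[e[, 1]] & rev[e[, 2]]))[1]
    if (is.na(drop)) next
    gj2 <- Pathway("P", "B", rxj, edges = e[-drop, , drop = FALSE])
    os2 <- organismSet(list(gi, gj2))
    u2 <- buildUnionGraph(os2, "P")
    cl2 <- affinityPropagation(homologicalMatrix(u2), seed = i)
    mm2 <- extractModules(cl2, u2, os2)
    expect_lte(pathwaySimScore(gi, gj2, mm2, u2), s0 + 1e-12)
  }
})

test_that("organism score is the mean of per-pathway scores", {
  expect_equal(organismScore(c(1, 0.5, 0)), 0.5)
  expect_equal(organismScore(1), 1)
  expect_equal(organismScore(0.7), 0.7)
  expect_error(organismScore(numeric(0)), "p = 0")
})

test_that("the distance matrix is the complement with zero self-distance", {
  b <- matrix(0.4, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(b) <- 1
  d <- distanceMatrix(b)
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)
  expect_true(all(d[row(d) != col(d)] == 0.6))
  expect_equal(distanceMatrix(diag(3) * 0 + 1),
               matrix(0, 3, 3), ignore_attr = TRUE)
  bad <- b
  bad[1, 2] <- 0.9
  expect_error(distanceMatrix(bad), "symmetric")
})

test_that("organism similarity is symmetric with unit diagonal on synthetic sets", {
  g <- generateOrganismSet(generatorConfig(k = 4, p = 2, templateSize = 8,
                                           seed = 19))
  sim <- organismSimilarity(g$organisms, seed = 19)
  b <- sim$bsim
  expect_equal(b, t(b))
  expect_equal(diag(b), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(b >= 0 & b <= 1))
})
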