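test_that("affinity propagation resolves two perfect similarity blocks", {
  H <- matrix(0, 6, 6)
  H[1:3, 1:3] <- 1
  H[4:6, 4:6] <- 1
  cl <- affinityPropagation(H, seed = 1)
  asn <- clusterAssignment(cl)
  # brute-force block detection oracle: the two blocks are the only
  # zero-cut partition into fully similar groups
  expect_equal(length(unique(asn)), 2L)
  expect_equal(length(unique(asn[1:3])), 1L)
  expect_equal(length(unique(asn[4:6])), 1L)
  expect_false(asn[1] == asn[4])
  expect_true(cl@converged)
})

test_that("affinity propagation degenerate cases", {
  # 1x1 matrix: single self-exemplar cluster
  one <- affinityPropagation(matrix(3, 1, 1))
  expect_equal(exemplars(one), 1L)
  expect_equal(clusterAssignment(one), 1L)
  # no off-diagonal similarity and a high preference: all singletons
  singles <- affinityPropagation(diag(5), preference = 1, seed = 2)
  expect_equal(length(exemplars(singles)), 5L)
  expect_equal(clusterAssignment(singles), 1:5)
  expect_error(affinityPropagation(matrix(0, 2, 3)), "square")
})

test_that("affinity propagation is deterministic for a fixed seed", {
  set.seed(21)
  H <- matrix(stats::runif(49), 7, 7)
  H <- (H + t(H)) / 2
  a <- affinityPropagation(H, seed = 9)
  b <- affinityPropagation(H, seed = 9)
  expect_identical(clusterAssignment(a), clusterAssignment(b))
  expect_identical(exemplars(a), exemplars(b))
})

test_that("module extraction induces sub-graphs per organism and skips gaps", {
  # two pathways whose chains map one-to-one: a1->a2 and b1->b2
  pA <- chainPathway(2, org = "A")
  pB <- chainPathway(2, pid = "P", org = "B")
  os <- organismSet(list(pA, pB))
  u <- buildUnionGraph(os, "P")
  # force one cluster containing both composite nodes
  cl <- new("ClusterResult", exemplars = 1L, assignment = c(1L, 1L),
            iterations = 0L, converged = TRUE)
  mm <- extractModules(cl, u, os)
  mods <- moduleClusters(mm)[[1]]
  expect_equal(sort(mods$A$nodes), c("r01", "r02"))
  expect_equal(sort(mods$B$nodes), c("r01", "r02"))
  expect_equal(unname(mods$A$edges), matrix(c("r01", "r02"), 1))
  expect_equal(unname(mods$B$edges), matrix(c("r01", "r02"), 1))
})

test_that("gapped and singleton clusters yield empty or edgeless modules", {
  pA <- chainPathway(3, org = "A")
  far <- Pathway("P", "B", list(
    rxn("x1", ec = "9.9.9.9", inputs = "z1", outputs = "z2"),
    rxn("x2", ec = "8.8.8.8", inputs = "z2", outputs = "z3")
  ), deriveEdges = TRUE)
  os <- organismSet(list(pA, far))
  u <- buildUnionGraph(os, "P", minWeight = 0.3)
  expect_true(all(is.na(compositeNodes(u)[, "B"])))
  cl <- new("ClusterResult", exemplars = 1L, assignment = rep(1L, 3),
            iterations = 0L, converged = TRUE)
  mm <- extractModules(cl, u, os)
  expect_equal(length(moduleClusters(mm)[[1]]$B$nodes), 0L)
  # singleton cluster: one node, zero edges
  cl2 <- new("ClusterResult", exemplars = c(1L, 2L),
             assignment = c(1L, 2L, 2L), iterations = 0L, converged = TRUE)
  mm2 <- extractModules(cl2, u, os)
  expect_equal(length(moduleClusters(mm2)[[1]]$A$nodes), 1L)
  expect_equal(nrow(moduleClusters(mm2)[[1]]$A$edges), 0L)
})

test_that("modules partition the matched reactions and are induced sub-graphs", {
  set.seed(22)
  for (i in 1:5) {
    paths <- lapply(1:3, function(j) randomPathway(6, org = sprintf("o%d", j)))
    os <- organismSet(paths)
    u <- buildUnionGraph(os, "P")
    cl <- affinityPropagation(homologicalMatrix(u), seed = i)
    mm <- extractModules(cl, u, os)
    mem <- compositeNodes(u)
    for (org in organisms(os)) {
      all_nodes <- unlist(lapply(moduleClusters(mm),
                                 function(x) x[[org]]$nodes))
      expect_false(anyDuplicated(all_nodes) > 0)
      matched <- mem[, org][!is.na(mem[, org])]
      expect_setequal(all_nodes, matched)
      # induced property: module edges are exactly the pathway edges with
      # both endpoints inside the module
      p <- getPathway(os, org, "P")
      pe <- paste(pathwayEdges(p)[, 1], pathwayEdges(p)[, 2])
      for (clu in moduleClusters(mm)) {
        mod <- clu[[org]]
        want <- pe[pe %in% as.vector(outer(mod$nodes, mod$nodes, paste))]
        expect_setequal(paste(mod$edges[, 1], mod$edges[, 2]), want)
      }
    }
  }
})

test_that("identical pathways yield isomorphic modules across organisms", {
  base <- chainPathway(5)
  os <- cloneOrganismSet(list(base), 3)
  u <- buildUnionGraph(os, "P")
  cl <- affinityPropagation(homologicalMatrix(u), seed = 3)
  mm <- extractModules(cl, u, os)
  for (clu in moduleClusters(mm)) {
    ref <- clu[[1]]
    for (mod in clu[-1]) {
      expect_setequal(mod$nodes, ref$nodes)
      expect_setequal(paste(mod$edges[, 1], mod$edges[, 2]),
                      paste(ref$edges[, 1], ref$edges[, 2]))
    }
  }
})
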