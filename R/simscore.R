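# Phase III scoring: largest common connected sub-graph of the largest
# mapped modules, pathway similarity, organism similarity (BSim) and the
# distance matrix.

# Weakly connected component labels for `nodes` under directed `edges`
# (two-column matrix), by union-find with path halving.
weakComponents <- function(nodes, edges) {
  parent <- seq_along(nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  from <- match(edges[, 1], nodes)
  to <- match(edges[, 2], nodes)
  for (e in seq_along(from)) {
    a <- find(from[e]); b <- find(to[e])
    if (a != b) parent[a] <- b
  }
  vapply(seq_along(nodes), find, integer(1))
}

#' Largest common connected sub-graph under a fixed node mapping
#'
#' Builds the conserved-edge graph: its nodes are the module reactions with a
#' mapped partner in the target pathway; an edge joins two of them iff the
#' edge is present in the module AND its image (under the mapping) is present
#' in the target pathway. Returns the largest weakly connected component
#' (ties broken by more edges, then by lexicographically smallest node ID).
#' With no conserved edges the LCCS is a single mapped node; with no mapped
#' nodes it is empty.
#'
#' @param module a functional module: list with `nodes` (character) and
#'   `edges` (two-column character matrix), as produced by [extractModules].
#' @param target a [Pathway-class] (the other pathway).
#' @param mapping named character vector: module reaction ID -> target
#'   reaction ID (one-to-one; gap-mapped nodes simply absent).
#' @return list with `nodes` (module side), `targetNodes` (their images),
#'   `edges` (conserved edges, module side), `nNodes`, `nEdges`.
#' @export
lccs <- function(module, target, mapping) {
  emptyE <- matrix(character(0), ncol = 2,
                   dimnames = list(NULL, c("from", "to")))
  mapped <- intersect(module$nodes, names(mapping))
  mapped <- mapped[!is.na(mapping[mapped])]
  if (length(mapped) == 0) {
    return(list(nodes = character(0), targetNodes = character(0),
                edges = emptyE, nNodes = 0L, nEdges = 0L))
  }
  stopIfNot(!anyDuplicated(mapping[mapped]),
            "mapping must be one-to-one on the module's nodes")
  me <- module$edges
  cons <- emptyE
  if (nrow(me) > 0) {
    me <- me[me[, 1] %in% mapped & me[, 2] %in% mapped, , drop = FALSE]
    if (nrow(me) > 0) {
      te <- pathwayEdges(target)
      teKeys <- edgeKey(te[, 1], te[, 2])
      conserved <- edgeKey(mapping[me[, 1]], mapping[me[, 2]]) %in% teKeys
      cons <- me[conserved, , drop = FALSE]
    }
  }
  comp <- if (nrow(cons) == 0) {
    as.list(mapped)
  } else {
    split(mapped, weakComponents(mapped, cons))
  }
  consKeyFrom <- cons[, 1]
  edgeCount <- vapply(comp, function(nodes) {
    sum(consKeyFrom %in% nodes)
  }, integer(1))
  sizes <- vapply(comp, length, integer(1))
  minIds <- vapply(comp, function(nodes) min(nodes), character(1))
  best <- cOrder(-sizes, -edgeCount, minIds)[1]
  nodes <- sort(comp[[best]])
  keepE <- cons[cons[, 1] %in% nodes, , drop = FALSE]
  list(nodes = nodes, targetNodes = unname(mapping[nodes]), edges = keepE,
       nNodes = length(nodes), nEdges = nrow(keepE))
}

#' Pathway similarity from the largest mapped modules
#'
#' For pathways `gi` and `gj` sharing a union graph, selects each pathway's
#' largest functional module over the clusters, computes the LCCS of each
#' largest module against the other pathway under the union-graph mapping,
#' and scores `min(|E_lccs_i|, |E_lccs_j|) / max(|E_i|, |E_j|)`. If both
#' pathways are edge-less the score is 1 when at least one reaction mapping
#' exists between them and 0 otherwise.
#'
#' @param gi,gj [Pathway-class] objects of two organisms for the same pathway.
#' @param mm the [ModuleMapping-class] for this pathway.
#' @param u the [UnionGraph-class] the modules were extracted from.
#' @param jointMmax select, instead of each pathway's largest module
#'   independently, the single cluster maximising `min(|M_i|, |M_j|)`.
#' @return a similarity in `[0,1]`.
#' @export
pathwaySimScore <- function(gi, gj, mm, u, jointMmax = FALSE) {
  orgI <- organismId(gi); orgJ <- organismId(gj)
  if (orgI == orgJ) return(1)
  mapIJ <- unionMapping(u, orgI, orgJ)
  mapJI <- stats::setNames(names(mapIJ), mapIJ)
  nEi <- nrow(pathwayEdges(gi)); nEj <- nrow(pathwayEdges(gj))
  if (max(nEi, nEj) == 0) {
    return(if (length(mapIJ) > 0) 1 else 0)
  }
  if (jointMmax) {
    cid <- largestJointCluster(mm, orgI, orgJ)
    if (is.null(cid)) return(0)
    modI <- moduleClusters(mm)[[cid]][[orgI]]
    modJ <- moduleClusters(mm)[[cid]][[orgJ]]
  } else {
    modI <- largestModule(mm, orgI)
    modJ <- largestModule(mm, orgJ)
  }
  if (is.null(modI) || is.null(modJ)) return(0)
  eI <- lccs(modI, gj, mapIJ)$nEdges
  eJ <- lccs(modJ, gi, mapJI)$nEdges
  min(eI, eJ) / max(nEi, nEj)
}

#' Organism similarity matrix (BSim) for an organism set
#'
#' Runs the three alignment phases for every common pathway (union graph,
#' affinity propagation clustering, module extraction), scores each organism
#' pair per pathway with [pathwaySimScore], and averages over the pathways.
#' The diagonal is 1.
#'
#' @param os an [OrganismSet-class] (k >= 2 organisms, >= 1 common pathway).
#' @param table optional [CompoundSimilarityTable-class].
#' @param weights a [scoringWeights] object.
#' @param minWeight,matching,rescale,hMean see [buildUnionGraph].
#' @param preference,damping,maxIter,convIter see [affinityPropagation].
#' @param jointMmax see [pathwaySimScore].
#' @param seed integer seed (clustering jitter).
#' @return list with `bsim` (k x k similarity matrix), `perPathway` (pathway
#'   x pair score matrix), `unions` and `modules` (per-pathway lists).
#' @export
organismSimilarity <- function(os, table = NULL, weights = scoringWeights(),
                               minWeight = 0, matching = "greedy",
                               rescale = TRUE, hMean = FALSE,
                               preference = "median", damping = 0.9,
                               maxIter = 1000, convIter = 50,
                               jointMmax = FALSE, seed = 1) {
  pids <- commonPathwayIds(os)
  stopIfNot(length(pids) >= 1, "organisms share no common pathways")
  orgs <- organisms(os)
  k <- length(orgs)
  bsim <- matrix(1, k, k, dimnames = list(orgs, orgs))
  perPathway <- matrix(NA_real_, length(pids), k * (k - 1) / 2)
  rownames(perPathway) <- pids
  unions <- list(); modules <- list()
  pairNames <- character(0)
  for (t in seq_along(pids)) {
    pid <- pids[t]
    u <- buildUnionGraph(os, pid, table = table, weights = weights,
                         minWeight = minWeight, matching = matching,
                         rescale = rescale, hMean = hMean)
    cl <- affinityPropagation(homologicalMatrix(u), preference = preference,
                              damping = damping, maxIter = maxIter,
                              convIter = convIter, seed = seed + t)
    mm <- extractModules(cl, u, os)
    unions[[pid]] <- u
    modules[[pid]] <- mm
    col <- 0
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        col <- col + 1
        s <- pathwaySimScore(getPathway(os, orgs[i], pid),
                             getPathway(os, orgs[j], pid), mm, u,
                             jointMmax = jointMmax)
        perPathway[t, col] <- s
        if (t == length(pids)) pairNames[col] <- paste(orgs[i], orgs[j], sep = "|")
      }
    }
  }
  colnames(perPathway) <- pairNames
  col <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      col <- col + 1
      bsim[i, j] <- bsim[j, i] <- organismScore(perPathway[, col])
    }
  }
  list(bsim = bsim, perPathway = perPathway, unions = unions,
       modules = modules)
}

#' Organism similarity from per-pathway scores
#'
#' The arithmetic mean of the per-pathway similarity scores of one organism
#' pair.
#'
#' @param simScores numeric vector of per-pathway scores (p >= 1).
#' @return the mean score.
#' @export
organismScore <- function(simScores) {
  stopIfNot(length(simScores) >= 1, "no common pathways (p = 0)")
  mean(simScores)
}

#' Distance matrix from a similarity matrix
#'
#' `D[i,j] = 1 - BSim[i,j]`; requires a symmetric matrix with unit diagonal
#' and entries in `[0,1]`.
#'
#' @param bsim k x k organism similarity matrix.
#' @return the k x k distance matrix (zero diagonal).
#' @export
distanceMatrix <- function(bsim) {
  stopIfNot(is.matrix(bsim) && nrow(bsim) == ncol(bsim),
            "bsim must be a square matrix")
  stopIfNot(max(abs(bsim - t(bsim))) <= 1e-9, "bsim must be symmetric")
  stopIfNot(max(abs(diag(bsim) - 1)) <= 1e-9, "bsim diagonal must be 1")
  stopIfNot(all(bsim >= -1e-12 & bsim <= 1 + 1e-12),
            "bsim entries must lie in [0,1]")
  d <- 1 - bsim
  diag(d) <- 0
  d
}
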