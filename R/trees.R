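# Distance-based tree building, cousin-pair tree comparison and pathway
# perturbation for robustness analysis.

#' Build a phylogenetic tree from a distance matrix
#'
#' `method = "nj"` runs Saitou-Nei neighbor joining; negative branch lengths
#' are set to zero with the deficit transferred to the adjacent (descendant)
#' branches, and the tree is rooted at its midpoint. `method = "upgma"` runs
#' average-linkage clustering and returns the rooted ultrametric tree. A
#' two-organism matrix yields a cherry with branch lengths `d/2`; an all-zero
#' matrix yields a star with zero branch lengths.
#'
#' @param d symmetric non-negative distance matrix with organism dimnames.
#' @param method `"nj"` or `"upgma"`.
#' @return a rooted `ape::phylo` tree.
#' @export
buildTree <- function(d, method = c("nj", "upgma")) {
  method <- match.arg(method)
  stopIfNot(is.matrix(d) && nrow(d) == ncol(d), "d must be a square matrix")
  stopIfNot(max(abs(d - t(d))) <= 1e-9, "distance matrix must be symmetric")
  stopIfNot(all(d >= -1e-12), "distances must be non-negative")
  stopIfNot(max(abs(diag(d))) <= 1e-12, "self-distances must be zero")
  labs <- rownames(d) %||% paste0("t", seq_len(nrow(d)))
  dimnames(d) <- list(labs, labs)
  k <- nrow(d)
  stopIfNot(k >= 2, "need >= 2 organisms")
  if (k == 2) {
    return(ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);", labs[1],
                                         d[1, 2] / 2, labs[2], d[1, 2] / 2)))
  }
  if (max(d) <= 1e-12) {
    # degenerate: all organisms indistinguishable -> star with zero lengths
    return(ape::read.tree(text = paste0(
      "(", paste(sprintf("%s:0", labs), collapse = ","), ");")))
  }
  if (method == "nj") {
    tr <- ape::nj(stats::as.dist(d))
    tr <- clampNegativeEdges(tr)
    tr <- phangorn::midpoint(tr)
    tr$edge.length <- pmax(tr$edge.length, 0)
    tr
  } else {
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    ape::as.phylo(hc)
  }
}

# Set negative branch lengths to zero and transfer the (negative) length to
# the branches descending from the edge's child node, preserving root-to-tip
# path lengths through that node where possible.
clampNegativeEdges <- function(tr) {
  for (pass in 1:5) {
    neg <- which(tr$edge.length < 0)
    if (length(neg) == 0) break
    for (e in neg) {
      len <- tr$edge.length[e]
      child <- tr$edge[e, 2]
      tr$edge.length[e] <- 0
      down <- which(tr$edge[, 1] == child)
      if (length(down) > 0) {
        tr$edge.length[down] <- tr$edge.length[down] + len
      }
    }
  }
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

# Edge-count depth of every node from the root.
nodeDepths <- function(tr) {
  n <- ape::Ntip(tr) + tr$Nnode
  depth <- rep(NA_real_, n)
  root <- ape::Ntip(tr) + 1L
  depth[root] <- 0
  edges <- ape::reorder.phylo(tr, "cladewise")$edge
  for (e in seq_len(nrow(edges))) {
    depth[edges[e, 2]] <- depth[edges[e, 1]] + 1
  }
  depth
}

#' Cousin pairs of a rooted tree
#'
#' For each unordered pair of leaves, the cousin degree is
#' `(d1 + d2) / 2 - 1`, where `d1` and `d2` count the generations separating
#' each leaf from the pair's last common ancestor. Siblings (both children of
#' the LCA) have degree 0, an uncle/niece pair 0.5, first cousins 1, and so
#' on; a generation difference contributes 0.5.
#'
#' @param tree a rooted `ape::phylo` tree with unique tip labels.
#' @param maxDegree keep only pairs with degree `<= maxDegree`.
#' @return data.frame with columns `a`, `b` (leaf labels, `a < b`) and
#'   `degree`.
#' @export
cousinPairs <- function(tree, maxDegree = Inf) {
  stopIfNot(inherits(tree, "phylo"), "tree must be an ape phylo object")
  stopIfNot(ape::is.rooted(tree), "tree must be rooted")
  stopIfNot(!anyDuplicated(tree$tip.label), "tip labels must be unique")
  ntip <- ape::Ntip(tree)
  if (ntip < 2) {
    return(data.frame(a = character(0), b = character(0), degree = numeric(0)))
  }
  depth <- nodeDepths(tree)
  lca <- ape::mrca(tree)
  pairs <- which(upper.tri(lca), arr.ind = TRUE)
  d1 <- depth[pairs[, 1]] - depth[lca[pairs]]
  d2 <- depth[pairs[, 2]] - depth[lca[pairs]]
  degree <- (d1 + d2) / 2 - 1
  labs <- tree$tip.label
  a <- labs[pairs[, 1]]; b <- labs[pairs[, 2]]
  out <- data.frame(a = pmin(a, b), b = pmax(a, b), degree = degree,
                    stringsAsFactors = FALSE)
  out <- out[out$degree <= maxDegree, , drop = FALSE]
  out[cOrder(out$a, out$b), , drop = FALSE]
}

cousinTuples <- function(tree, maxDegree) {
  cp <- cousinPairs(tree, maxDegree)
  sprintf("%s|%s|%.1f", cp$a, cp$b, cp$degree)
}

#' Cousin-pair tree similarity
#'
#' The Jaccard index of the two trees' cousin-pair sets: pairs agree only if
#' both the leaf pair and its cousin degree coincide. Identical trees score
#' 1; trees sharing no (pair, degree) tuple score 0.
#'
#' @param t1,t2 rooted `ape::phylo` trees over the same leaf set.
#' @param maxDegree only pairs with degree up to this bound are compared
#'   (default 2).
#' @return a similarity in `[0,1]`.
#' @export
treeSimilarity <- function(t1, t2, maxDegree = 2) {
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    stop("trees have different leaf sets; symmetric difference: ",
         paste(c(setdiff(l1, l2), setdiff(l2, l1)), collapse = ", "),
         call. = FALSE)
  }
  s1 <- cousinTuples(t1, maxDegree)
  s2 <- cousinTuples(t2, maxDegree)
  un <- union(s1, s2)
  if (length(un) == 0) return(1)
  length(intersect(s1, s2)) / length(un)
}

#' Randomly perturb a pathway
#'
#' Emulates errors in curated pathway data: deletes `floor(nodeRate * n)`
#' randomly chosen reactions (with their incident edges) and inserts an equal
#' number of new reactions with random EC numbers and compounds drawn from
#' the pathway's own alphabet (new reactions connect to the rest of the
#' pathway via the substrate-product rule); likewise deletes
#' `floor(edgeRate * |E|)` random edges and inserts an equal number of new
#' random edges between reaction pairs. The reversible closure is re-applied,
#' so an inserted edge between two reversible reactions implies its reverse.
#' Reproducible for a fixed seed.
#'
#' @param p a [Pathway-class].
#' @param nodeRate,edgeRate perturbation rates in `[0,1]`.
#' @param seed integer seed.
#' @return the perturbed [Pathway-class].
#' @export
perturbPathway <- function(p, nodeRate = 0, edgeRate = 0, seed = 1) {
  stopIfNot(nodeRate >= 0 && nodeRate <= 1 && edgeRate >= 0 && edgeRate <= 1,
            "rates must lie in [0,1]")
  if (nodeRate == 0 && edgeRate == 0) return(p)
  withSeed(seed, {
    rx <- reactions(p)
    edges <- pathwayEdges(p)
    nDel <- floor(nodeRate * nrow(rx))
    compoundAlphabet <- unique(c(unlist(rx$inputs), unlist(rx$outputs)))
    ecAlphabet <- unique(unlist(rx$ec))
    if (nDel > 0) {
      drop <- sample(rx$id, nDel)
      rx <- rx[!(rx$id %in% drop), , drop = FALSE]
      edges <- edges[!(edges[, 1] %in% drop) & !(edges[, 2] %in% drop), ,
                     drop = FALSE]
      for (i in seq_len(nDel)) {
        newId <- sprintf("ins%03d", i)
        while (newId %in% rx$id) newId <- paste0(newId, "x")
        newRow <- reactionTable(
          id = newId,
          ec = list(sample(ecAlphabet, 1)),
          inputs = list(sample(compoundAlphabet,
                               min(length(compoundAlphabet),
                                   sample(1:2, 1)))),
          outputs = list(sample(compoundAlphabet,
                                min(length(compoundAlphabet),
                                    sample(1:2, 1)))),
          reversible = stats::runif(1) < 0.2
        )
        # connect the new reaction via the substrate-product rule
        for (j in seq_len(nrow(rx))) {
          if (any(newRow$outputs[[1]] %in% rx$inputs[[j]])) {
            edges <- rbind(edges, c(newId, rx$id[j]))
          }
          if (any(rx$outputs[[j]] %in% newRow$inputs[[1]])) {
            edges <- rbind(edges, c(rx$id[j], newId))
          }
        }
        rx <- rbind(rx, newRow)
      }
    }
    nEdgeDel <- floor(edgeRate * nrow(edges))
    if (nEdgeDel > 0) {
      del <- sample(nrow(edges), nEdgeDel)
      edges <- edges[-del, , drop = FALSE]
      present <- edgeKey(edges[, 1], edges[, 2])
      candidates <- expand.grid(from = rx$id, to = rx$id,
                                stringsAsFactors = FALSE)
      candidates <- candidates[candidates$from != candidates$to, ]
      candidates <- candidates[!(edgeKey(candidates$from, candidates$to)
                                 %in% present), , drop = FALSE]
      nAdd <- min(nEdgeDel, nrow(candidates))
      if (nAdd > 0) {
        add <- candidates[sample(nrow(candidates), nAdd), , drop = FALSE]
        edges <- rbind(edges, as.matrix(add))
      }
    }
    Pathway(pathwayId(p), organismId(p), rx, edges = edges)
  })
}

#' Perturb every pathway of an organism set
#'
#' Applies [perturbPathway] with the given rates to each organism's copy of
#' each common pathway, using a distinct sub-seed per pathway, and rebuilds
#' the organism set.
#'
#' @param os an [OrganismSet-class].
#' @inheritParams perturbPathway
#' @return the perturbed [OrganismSet-class].
#' @export
perturbOrganismSet <- function(os, nodeRate = 0, edgeRate = 0, seed = 1) {
  i <- 0
  perturbed <- list()
  for (org in organisms(os)) {
    for (pid in commonPathwayIds(os)) {
      i <- i + 1
      perturbed[[i]] <- perturbPathway(getPathway(os, org, pid),
                                       nodeRate = nodeRate,
                                       edgeRate = edgeRate, seed = seed + i)
    }
  }
  organismSet(perturbed)
}
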