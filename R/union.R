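# Phase I: pairwise union graphs by maximum-weight bipartite matching,
# homological similarity matrices, and the merged multi-pathway union graph.

#' Greedy maximum-weight bipartite matching
#'
#' Repeatedly selects the globally heaviest remaining edge whose endpoints are
#' both unused, until no admissible edge remains. Zero-weight edges are never
#' selected (a zero-weight mapping carries no evidence); ties are broken by
#' (row id, col id) in C-locale lexicographic order, so the result is
#' invariant under row/column permutation of the input.
#'
#' @param weights numeric matrix with row/column names (reaction IDs of the
#'   two pathways).
#' @param minWeight minimum admissible edge weight (default 0).
#' @return data.frame with columns `row`, `col`, `weight`.
#' @export
greedyMatching <- function(weights, minWeight = 0) {
  stopIfNot(is.matrix(weights) && all(is.finite(weights)),
            "weights must be a finite numeric matrix")
  stopIfNot(!is.null(rownames(weights)) && !is.null(colnames(weights)),
            "weights must have row and column names")
  empty <- data.frame(row = character(0), col = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  idx <- which(weights > 0 & weights >= minWeight, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  rid <- rownames(weights)[idx[, 1]]
  cid <- colnames(weights)[idx[, 2]]
  w <- weights[idx]
  o <- cOrder(-w, rid, cid)
  rid <- rid[o]; cid <- cid[o]; w <- w[o]
  usedR <- character(0); usedC <- character(0)
  keep <- logical(length(w))
  for (e in seq_along(w)) {
    if (!(rid[e] %in% usedR) && !(cid[e] %in% usedC)) {
      keep[e] <- TRUE
      usedR <- c(usedR, rid[e])
      usedC <- c(usedC, cid[e])
    }
  }
  data.frame(row = rid[keep], col = cid[keep], weight = w[keep],
             stringsAsFactors = FALSE)
}

# Optimal assignment (Hungarian algorithm with potentials, O(n^3)) on a
# rectangular weight matrix; maximizes total weight. Returns the same shape
# of result as greedyMatching, dropping pairs below minWeight or at 0.
exactMatching <- function(weights, minWeight = 0) {
  n <- nrow(weights); m <- ncol(weights)
  flip <- n > m
  w <- if (flip) t(weights) else weights
  nr <- nrow(w); nc <- ncol(w)
  cost <- max(w) - w                      # minimize cost == maximize weight
  # pad to square with zero cost (dummy columns never constrain real rows)
  sq <- matrix(max(cost), nc, nc)
  sq[seq_len(nr), ] <- cost
  a <- hungarian(sq)[seq_len(nr)]         # a[i] = column assigned to row i
  rid <- rownames(w); cid <- colnames(w)
  res <- data.frame(row = rid, col = cid[a], weight = w[cbind(seq_len(nr), a)],
                    stringsAsFactors = FALSE)
  if (flip) res <- data.frame(row = res$col, col = res$row, weight = res$weight,
                              stringsAsFactors = FALSE)
  res <- res[res$weight > 0 & res$weight >= minWeight, , drop = FALSE]
  res[cOrder(res$row, res$col), , drop = FALSE]
}

# Square-matrix Hungarian algorithm (potentials formulation). Returns, for
# each row, the assigned column index.
hungarian <- function(cost) {
  n <- nrow(cost)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j+1] = row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) ans[p[j + 1]] <- j
  ans
}

#' Homological similarity between two composite nodes
#'
#' For composite nodes `c1 = (u1, v1)` and `c2 = (u2, v2)` of one pairwise
#' union graph, combines the cross terms `S(u1,v2) + S(u2,v1)` with the
#' within-mapping terms `S(u1,v1) + S(u2,v2)`. With `rescale = TRUE` (the
#' default) the sum is divided by 4 so the score stays in `[0,1]`; with
#' `rescale = FALSE` the raw half-sums (range `[0,2]`) are returned. Any term
#' involving a gap contributes 0.
#'
#' @param s11,s22 within-mapping similarities `S(u1,v1)`, `S(u2,v2)`.
#' @param s12,s21 cross similarities `S(u1,v2)`, `S(u2,v1)`.
#' @param rescale honour the `[0,1]` range by halving the raw combination.
#' @return the homological similarity.
#' @export
homologicalSimilarity <- function(s11, s22, s12, s21, rescale = TRUE) {
  raw <- 0.5 * (s12 + s21) + 0.5 * (s11 + s22)
  if (rescale) raw / 2 else raw
}

#' Build the pairwise union graph of an anchor pathway and another pathway
#'
#' Extracts one-to-one reaction mappings between `gmax` (the anchor, at least
#' as large as `gi`) and `gi` by maximum-weight bipartite matching on reaction
#' similarity, builds one composite node per anchor reaction (unmatched
#' anchors carry a gap), and computes the homological similarity matrix over
#' composite nodes. The union graph itself has no edges.
#'
#' @param gmax,gi [Pathway-class] objects; `gmax` must have at least as many
#'   reactions as `gi`.
#' @param table a [CompoundSimilarityTable-class] or `NULL`.
#' @param weights a [scoringWeights] object.
#' @param minWeight minimum matching weight (see [greedyMatching]).
#' @param matching `"greedy"` (the default, sequential heaviest-edge
#'   selection) or `"exact"` (optimal assignment).
#' @param rescale passed to [homologicalSimilarity].
#' @return a [UnionGraph-class] with two member columns (anchor organism
#'   first).
#' @export
buildPairwiseUnion <- function(gmax, gi, table = NULL,
                               weights = scoringWeights(), minWeight = 0,
                               matching = c("greedy", "exact"),
                               rescale = TRUE) {
  matching <- match.arg(matching)
  stopIfNot(nReactions(gmax) >= nReactions(gi),
            "anchor pathway must have at least as many reactions")
  S <- nodeSimilarityMatrix(gmax, gi, table, weights)
  m <- if (matching == "greedy") greedyMatching(S, minWeight)
       else exactMatching(S, minWeight)
  anchors <- reactionIds(gmax)
  partner <- rep(NA_character_, length(anchors))
  names(partner) <- anchors
  partner[m$row] <- m$col
  members <- cbind(anchors, unname(partner))
  colnames(members) <- c(organismId(gmax), organismId(gi))
  H <- pairwiseHomologyMatrix(S, anchors, partner, rescale)
  new("UnionGraph", pathwayId = pathwayId(gmax),
      anchorOrganism = organismId(gmax), anchors = anchors,
      members = members, H = H)
}

# Vectorized homological similarity matrix for one pairwise union.
# cross[i, j] = S(u_i, partner(u_j)); gap partners contribute 0.
pairwiseHomologyMatrix <- function(S, anchors, partner, rescale = TRUE) {
  n <- length(anchors)
  colIdx <- match(partner, colnames(S))        # NA for gaps
  cross <- matrix(0, n, n)
  ok <- which(!is.na(colIdx))
  if (length(ok) > 0) {
    cross[, ok] <- S[, colIdx[ok], drop = FALSE]
  }
  sm <- numeric(n)
  sm[ok] <- S[cbind(ok, colIdx[ok])]
  H <- 0.5 * (cross + t(cross)) + 0.5 * outer(sm, sm, `+`)
  if (rescale) H <- H / 2
  dimnames(H) <- list(anchors, anchors)
  H
}

#' Merge pairwise union graphs anchored on the same pathway
#'
#' Composite nodes sharing the same anchor reaction are merged (one member
#' slot per organism); the homological similarity matrix of the merged graph
#' is the element-wise sum of the pairwise matrices. With `hMean = TRUE` the
#' sum is divided by the number of pairwise graphs instead.
#'
#' @param unions list of [UnionGraph-class] objects sharing the anchor.
#' @param hMean average instead of sum the pairwise matrices.
#' @return the merged [UnionGraph-class].
#' @export
mergeUnions <- function(unions, hMean = FALSE) {
  stopIfNot(length(unions) >= 1, "need at least one pairwise union")
  u1 <- unions[[1]]
  for (u in unions[-1]) {
    stopIfNot(identical(u@anchors, u1@anchors) &&
                identical(u@anchorOrganism, u1@anchorOrganism) &&
                identical(u@pathwayId, u1@pathwayId),
              "all pairwise unions must share the same anchor pathway")
  }
  members <- do.call(cbind, c(list(u1@members),
                              lapply(unions[-1], function(u) {
                                u@members[, 2, drop = FALSE]
                              })))
  H <- Reduce(`+`, lapply(unions, homologicalMatrix))
  if (hMean) H <- H / length(unions)
  new("UnionGraph", pathwayId = u1@pathwayId,
      anchorOrganism = u1@anchorOrganism, anchors = u1@anchors,
      members = members, H = H)
}

#' Build the merged union graph for one common pathway of an organism set
#'
#' Selects the anchor pathway (maximal reaction count; ties broken by
#' lexicographic organism ID), aligns every other organism's pathway against
#' it, and merges the pairwise union graphs.
#'
#' @param os an [OrganismSet-class].
#' @param pid a common pathway ID.
#' @inheritParams buildPairwiseUnion
#' @param hMean see [mergeUnions].
#' @return a [UnionGraph-class] with one member column per organism.
#' @export
buildUnionGraph <- function(os, pid, table = NULL, weights = scoringWeights(),
                            minWeight = 0, matching = "greedy",
                            rescale = TRUE, hMean = FALSE) {
  orgs <- organisms(os)
  paths <- lapply(orgs, getPathway, x = os, pid = pid)
  names(paths) <- orgs
  sizes <- vapply(paths, nReactions, integer(1))
  anchorOrg <- orgs[cOrder(-sizes, orgs)][1]
  gmax <- paths[[anchorOrg]]
  others <- setdiff(orgs, anchorOrg)
  unions <- lapply(others, function(o) {
    buildPairwiseUnion(gmax, paths[[o]], table = table, weights = weights,
                       minWeight = minWeight, matching = matching,
                       rescale = rescale)
  })
  mergeUnions(unions, hMean = hMean)
}

# One-to-one reaction mapping between two organisms' pathways, read off the
# union graph: reactions sharing a composite node are mapped.
unionMapping <- function(u, orgFrom, orgTo) {
  mem <- compositeNodes(u)
  stopIfNot(all(c(orgFrom, orgTo) %in% colnames(mem)),
            "organism not present in union graph")
  keep <- !is.na(mem[, orgFrom]) & !is.na(mem[, orgTo])
  stats::setNames(mem[keep, orgTo], mem[keep, orgFrom])
}
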