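# Phase II clustering: affinity propagation (Frey & Dueck message passing)
# on the homological similarity matrix of the merged union graph.

#' Affinity propagation clustering
#'
#' Standard damped responsibility/availability message passing on a square
#' symmetric similarity matrix. Self-similarities (preferences) control the
#' emergent number of exemplars; the default is the median of the
#' off-diagonal similarities. A tiny seeded jitter (relative scale `1e-12`)
#' breaks symmetry-induced oscillations, as in reference implementations, so
#' results are reproducible for a given seed. After exemplars stabilise, each
#' cluster's exemplar is refined to the member maximising within-cluster
#' similarity and points are assigned to their most similar exemplar.
#'
#' @param S square symmetric numeric similarity matrix.
#' @param preference scalar self-similarity, or `"median"` (default).
#' @param damping damping factor in `[0.5, 1)`.
#' @param maxIter maximum number of iterations.
#' @param convIter iterations of unchanged exemplars required for convergence.
#' @param seed integer seed for the jitter.
#' @details When the similarity structure is degenerate (for example a
#' constant off-diagonal, as arises when aligning identical pathways) the
#' net-similarity objective ties over many exemplar counts and the jitter
#' alone decides. A deterministic post-pass therefore merges clusters
#' whenever absorbing one cluster into another does not decrease the
#' objective, breaking exact ties toward fewer clusters; clusterings
#' supported by actual similarity contrasts are unaffected.
#' @return a [ClusterResult-class]. If no exemplar emerges the node with the
#'   highest evidence is used as a single exemplar, `converged` is `FALSE`
#'   and a warning is raised.
#' @export
affinityPropagation <- function(S, preference = "median", damping = 0.9,
                                maxIter = 1000, convIter = 50, seed = 1) {
  stopIfNot(is.matrix(S) && nrow(S) == ncol(S),
            "similarity matrix must be square")
  stopIfNot(damping >= 0.5 && damping < 1, "damping must be in [0.5, 1)")
  n <- nrow(S)
  if (n == 1) {
    return(new("ClusterResult", exemplars = 1L, assignment = 1L,
               iterations = 0L, converged = TRUE))
  }
  off <- S[row(S) != col(S)]
  pref <- if (identical(preference, "median")) stats::median(off)
          else as.numeric(preference)
  W <- S
  diag(W) <- pref
  scale <- max(W) - min(W)
  if (scale <= 0) scale <- 1
  W <- W + withSeed(seed, matrix(stats::rnorm(n * n), n, n)) * 1e-12 * scale

  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  exemplarHistory <- rep(-1L, n)
  stable <- 0L
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    # responsibilities
    AS <- A + W
    firstMax <- apply(AS, 1, max)
    whichFirst <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), whichFirst)] <- -Inf
    secondMax <- apply(AS2, 1, max)
    Rnew <- W - firstMax
    Rnew[cbind(seq_len(n), whichFirst)] <- W[cbind(seq_len(n), whichFirst)] -
      secondMax
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    # convergence on the exemplar set
    ex <- as.integer(diag(A) + diag(R) > 0)
    if (identical(ex, exemplarHistory)) {
      stable <- stable + 1L
      if (stable >= convIter && any(ex == 1L)) {
        converged <- TRUE
        break
      }
    } else {
      exemplarHistory <- ex
      stable <- 0L
    }
  }
  ex <- which(diag(A) + diag(R) > 0)
  if (length(ex) == 0) {
    warning("affinity propagation did not identify exemplars; ",
            "falling back to the highest-evidence node")
    ex <- which.max(diag(A) + diag(R))
    converged <- FALSE
  }
  if (!converged && length(ex) > 0 && it >= maxIter) {
    warning("affinity propagation did not converge in ", maxIter,
            " iterations; returning best-effort assignment")
  }
  # assign to nearest exemplar, then refine exemplars within clusters
  assignTo <- function(exset) {
    cl <- apply(W[, exset, drop = FALSE], 1, which.max)
    cl[exset] <- seq_along(exset)
    cl
  }
  cl <- assignTo(ex)
  newEx <- vapply(seq_along(ex), function(kk) {
    memb <- which(cl == kk)
    memb[which.max(colSums(W[memb, memb, drop = FALSE]))]
  }, integer(1))
  newEx <- sort(unique(newEx))
  cl <- assignTo(newEx)
  # degeneracy resolution: merge clusters while the objective does not drop
  Wc <- S
  diag(Wc) <- pref
  merged <- mergeTiedClusters(Wc, newEx, cl)
  new("ClusterResult", exemplars = as.integer(merged$exemplars),
      assignment = as.integer(merged$assignment), iterations = it,
      converged = converged)
}

# Greedy cluster merging on the net-similarity objective (preferences of the
# exemplars plus each member's similarity to its exemplar): absorb a cluster
# into another whenever the objective does not drop, ties toward fewer
# clusters.
mergeTiedClusters <- function(W, exemplars, assignment) {
  eps <- 1e-9 * max(1, abs(max(W) - min(W)))
  repeat {
    k <- length(exemplars)
    if (k == 1) break
    best <- NULL
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        for (pair in list(c(a, b), c(b, a))) {
          into <- pair[1]; from <- pair[2]
          memb <- which(assignment == from)
          delta <- sum(W[memb, exemplars[into]]) -
            (W[exemplars[from], exemplars[from]] +
               sum(W[setdiff(memb, exemplars[from]), exemplars[from]]))
          if (delta >= -eps && (is.null(best) || delta > best$delta + eps)) {
            best <- list(into = into, from = from, delta = delta)
          }
        }
      }
    }
    if (is.null(best)) break
    assignment[assignment == best$from] <- best$into
    keep <- sort(unique(assignment))
    assignment <- match(assignment, keep)
    # re-centre each cluster's exemplar, then relabel in exemplar order
    exemplars <- vapply(seq_along(keep), function(kk) {
      memb <- which(assignment == kk)
      memb[which.max(colSums(W[memb, memb, drop = FALSE]))]
    }, integer(1))
    o <- order(exemplars)
    exemplars <- exemplars[o]
    relabel <- integer(length(o))
    relabel[o] <- seq_along(o)
    assignment <- relabel[assignment]
  }
  list(exemplars = exemplars, assignment = assignment)
}
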