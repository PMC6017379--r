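# Reaction-level similarity: EC-hierarchy enzyme score, average compound-set
# similarity, and their weighted combination.

#' Scoring weights for reaction similarity
#'
#' The reaction similarity is `alpha * Esim + beta * Csim(inputs) +
#' gamma * Csim(outputs)` with the constraint `alpha + beta + gamma = 1`.
#'
#' @param alpha,beta,gamma non-negative weights summing to 1 (tolerance 1e-9).
#'   Defaults 0.4 / 0.3 / 0.3.
#' @return a `scoring_weights` list.
#' @export
scoringWeights <- function(alpha = 0.4, beta = 0.3, gamma = 0.3) {
  stopIfNot(alpha >= 0 && beta >= 0 && gamma >= 0,
            "weights must be non-negative")
  stopIfNot(abs(alpha + beta + gamma - 1) <= 1e-9,
            "alpha + beta + gamma must equal 1")
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "scoring_weights")
}

# Count of matching leading EC fields for one pair of EC strings.
# Comparison stops at the first mismatching, wildcard ("-") or absent field;
# no rescaling for partial ECs ("1.2" vs "1.2" matches 2 fields).
ecFieldMatches <- function(a, b) {
  fa <- strsplit(a, ".", fixed = TRUE)[[1]]
  fb <- strsplit(b, ".", fixed = TRUE)[[1]]
  m <- 0L
  for (i in seq_len(min(length(fa), length(fb), 4L))) {
    if (fa[i] == "-" || fb[i] == "-" || !nzchar(fa[i]) || !nzchar(fb[i])) break
    if (fa[i] != fb[i]) break
    m <- m + 1L
  }
  m
}

#' Enzyme similarity from the EC hierarchy
#'
#' Scores 1, 0.75, 0.5, 0.25 or 0 for 4, 3, 2, 1 or 0 matching leading EC
#' fields. A `"-"` (or absent) field never matches. For reactions annotated
#' with several EC numbers the best pair wins.
#'
#' @param ecA,ecB character vectors of EC numbers (each argument is one
#'   reaction's annotation set).
#' @return a similarity in `{0, 0.25, 0.5, 0.75, 1}`.
#' @export
ecSimilarity <- function(ecA, ecB) {
  stopIfNot(length(ecA) >= 1 && length(ecB) >= 1,
            "each reaction needs >= 1 EC number")
  best <- 0L
  for (a in ecA) {
    for (b in ecB) {
      m <- ecFieldMatches(a, b)
      if (m > best) best <- m
      if (best == 4L) break
    }
  }
  best * 0.25
}

#' Average compound-set similarity
#'
#' The mean of `sim(A, B)` over the full Cartesian product of the two
#' compound sets.
#'
#' @param setA,setB non-empty character vectors of compound IDs.
#' @param table a [CompoundSimilarityTable-class] or `NULL` (identity policy:
#'   same ID scores 1, anything else 0).
#' @return a similarity in `[0,1]`.
#' @export
compoundSetSimilarity <- function(setA, setB, table = NULL) {
  stopIfNot(length(setA) >= 1 && length(setB) >= 1,
            "compound sets must be non-empty")
  g <- expand.grid(a = setA, b = setB, stringsAsFactors = FALSE)
  mean(compoundSimilarity(table, g$a, g$b))
}

asReactionRow <- function(u) {
  if (is.data.frame(u)) {
    list(ec = u$ec[[1]], inputs = u$inputs[[1]], outputs = u$outputs[[1]])
  } else {
    list(ec = u$ec %||% "-", inputs = u$inputs, outputs = u$outputs)
  }
}

#' Reaction similarity
#'
#' `S(u,v) = alpha * Esim(u_e, v_e) + beta * Csim(u_ic, v_ic) +
#' gamma * Csim(u_oc, v_oc)` over the enzymes and the input / output compound
#' sets of the two reactions.
#'
#' @param u,v reactions: either single rows of a [Pathway-class] reaction
#'   table or lists with elements `ec`, `inputs`, `outputs`.
#' @param table a [CompoundSimilarityTable-class] or `NULL`.
#' @param weights a [scoringWeights] object.
#' @return a similarity in `[0,1]`.
#' @export
nodeSimilarity <- function(u, v, table = NULL, weights = scoringWeights()) {
  u <- asReactionRow(u); v <- asReactionRow(v)
  weights$alpha * ecSimilarity(u$ec, v$ec) +
    weights$beta * compoundSetSimilarity(u$inputs, v$inputs, table) +
    weights$gamma * compoundSetSimilarity(u$outputs, v$outputs, table)
}

# EC prefixes of length 1..4 for a vector of EC strings; a prefix containing
# a wildcard or truncated field is NA and never matches.
ecPrefixes <- function(ecs) {
  fields <- strsplit(ecs, ".", fixed = TRUE)
  out <- matrix(NA_character_, length(ecs), 4)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    for (L in 1:4) {
      if (length(f) < L || any(f[seq_len(L)] == "-") ||
          any(!nzchar(f[seq_len(L)]))) break
      out[i, L] <- paste(f[seq_len(L)], collapse = ".")
    }
  }
  out
}

# Vectorized EC similarity matrix between two EC-list columns; multi-EC
# reactions take the best pair.
ecSimilarityMatrix <- function(ecListA, ecListB) {
  flatA <- unlist(ecListA); grpA <- rep(seq_along(ecListA),
                                        lengths(ecListA))
  flatB <- unlist(ecListB); grpB <- rep(seq_along(ecListB),
                                        lengths(ecListB))
  prefA <- ecPrefixes(flatA)
  prefB <- ecPrefixes(flatB)
  cnt <- matrix(0, length(flatA), length(flatB))
  for (L in 1:4) {
    eq <- outer(prefA[, L], prefB[, L], `==`)
    eq[is.na(eq)] <- FALSE
    cnt <- cnt + eq
  }
  full <- cnt * 0.25
  if (all(lengths(ecListA) == 1) && all(lengths(ecListB) == 1)) return(full)
  E <- matrix(0, length(ecListA), length(ecListB))
  for (i in seq_along(ecListA)) {
    rows <- which(grpA == i)
    sub <- full[rows, , drop = FALSE]
    E[i, ] <- vapply(seq_along(ecListB), function(j) {
      max(sub[, grpB == j])
    }, numeric(1))
  }
  E
}

# All-pairs reaction similarity between two pathways: the weight matrix of
# the bipartite graph whose partitions are the two reaction sets. Compound
# Cartesian-product means are computed in one pass as
# membership %*% pairSim %*% t(membership), normalised by the set sizes.
nodeSimilarityMatrix <- function(pA, pB, table = NULL,
                                 weights = scoringWeights()) {
  rA <- reactions(pA); rB <- reactions(pB)
  cmpA <- unique(c(unlist(rA$inputs), unlist(rA$outputs)))
  cmpB <- unique(c(unlist(rB$inputs), unlist(rB$outputs)))
  g <- expand.grid(a = cmpA, b = cmpB, stringsAsFactors = FALSE)
  simAB <- matrix(compoundSimilarity(table, g$a, g$b), length(cmpA),
                  length(cmpB))
  membership <- function(sets, alphabet) {
    m <- matrix(0, length(sets), length(alphabet))
    for (i in seq_along(sets)) m[i, match(sets[[i]], alphabet)] <- 1
    m
  }
  csimMean <- function(setsA, setsB) {
    mA <- membership(setsA, cmpA)
    mB <- membership(setsB, cmpB)
    (mA %*% simAB %*% t(mB)) / outer(rowSums(mA), rowSums(mB))
  }
  S <- weights$alpha * ecSimilarityMatrix(rA$ec, rB$ec) +
    weights$beta * csimMean(rA$inputs, rB$inputs) +
    weights$gamma * csimMean(rA$outputs, rB$outputs)
  dimnames(S) <- list(rA$id, rB$id)
  S
}
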