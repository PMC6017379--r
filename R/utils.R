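# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Canonical key for an unordered compound pair. "\r" cannot occur in IDs read
# from the line-oriented formats, so the key is unambiguous.
pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# Canonical key for a directed edge.
edgeKey <- function(from, to) paste(from, to, sep = "\r")

`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic (C-locale) string ordering, independent of the session locale.
cOrder <- function(...) order(..., method = "radix")

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# Normalise an edge specification (2-column matrix / data.frame / list of
# pairs) into a character matrix with columns "from", "to".
asEdgeMatrix <- function(edges) {
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0) ||
      (!is.matrix(edges) && length(edges) == 0)) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to"))))
  }
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.list(edges)) {
    edges <- do.call(rbind, lapply(edges, function(e) {
      stopIfNot(length(e) == 2, "each edge must be a pair of reaction ids")
      as.character(e)
    }))
  }
  stopIfNot(is.matrix(edges) && ncol(edges) == 2,
            "edges must be a two-column matrix of reaction ids")
  storage.mode(edges) <- "character"
  dimnames(edges) <- list(NULL, c("from", "to"))
  edges
}

# Drop duplicate edges and order rows deterministically.
canonicalEdges <- function(edges) {
  edges <- asEdgeMatrix(edges)
  if (nrow(edges) == 0) return(edges)
  keep <- !duplicated(edgeKey(edges[, 1], edges[, 2]))
  edges <- edges[keep, , drop = FALSE]
  edges[cOrder(edges[, 1], edges[, 2]), , drop = FALSE]
}
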