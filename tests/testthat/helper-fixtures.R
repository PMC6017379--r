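# Fixture builders and independent oracles shared across the test files.
# Fixtures are built in code; oracles are deliberately naive re-derivations
# of the quantities under test.

rxn <- function(id, ec = "1.1.1.1", inputs = "C1", outputs = "C2",
                reversible = FALSE) {
  list(id = id, ec = ec, inputs = inputs, outputs = outputs,
       reversible = reversible)
}

# A simple linear chain pathway r1 -> r2 -> ... -> rn via shared compounds.
chainPathway <- function(n, pid = "P", org = "O", reversible = FALSE,
                         ecs = NULL) {
  if (is.null(ecs)) {
    ecs <- sprintf("%d.%d.%d.%d", (seq_len(n) %% 6) + 1, seq_len(n),
                   seq_len(n), seq_len(n))
  }
  rx <- lapply(seq_len(n), function(i) {
    rxn(sprintf("r%02d", i), ec = ecs[i], inputs = sprintf("c%02d", i - 1),
        outputs = sprintf("c%02d", i), reversible = reversible)
  })
  Pathway(pid, org, rx, deriveEdges = TRUE)
}

randomECString <- function() {
  paste(sample(1:4, 1), sample(1:6, 1), sample(1:6, 1), sample(1:9, 1),
        sep = ".")
}

# A random pathway over a small compound alphabet (edges derived).
randomPathway <- function(n, pid = "P", org = "O", nCompounds = max(4, n)) {
  alphabet <- sprintf("c%02d", seq_len(nCompounds))
  rx <- lapply(seq_len(n), function(i) {
    rxn(sprintf("r%02d", i), ec = randomECString(),
        inputs = sample(alphabet, sample(1:2, 1)),
        outputs = sample(alphabet, sample(1:2, 1)),
        reversible = stats::runif(1) < 0.3)
  })
  Pathway(pid, org, rx, deriveEdges = TRUE)
}

# Independent greedy-matching trace: scan all admissible cells, repeatedly
# take the max (ties by row then column label), never reusing a row/column.
refGreedyTrace <- function(w, minWeight = 0) {
  res <- data.frame(row = character(0), col = character(0),
                    weight = numeric(0), stringsAsFactors = FALSE)
  w <- w[order(rownames(w)), order(colnames(w)), drop = FALSE]
  repeat {
    best <- NULL
    for (i in seq_len(nrow(w))) {
      for (j in seq_len(ncol(w))) {
        ok <- w[i, j] > 0 && w[i, j] >= minWeight
        if (ok && (is.null(best) || w[i, j] > best$w)) {
          best <- list(i = i, j = j, w = w[i, j])
        }
      }
    }
    if (is.null(best)) break
    res <- rbind(res, data.frame(row = rownames(w)[best$i],
                                 col = colnames(w)[best$j], weight = best$w,
                                 stringsAsFactors = FALSE))
    w <- w[-best$i, -best$j, drop = FALSE]
    if (nrow(w) == 0 || ncol(w) == 0) break
  }
  res[order(res$row), , drop = FALSE]
}

# Brute-force optimal assignment value by enumerating all injections of the
# smaller side into the larger.
bruteAssignmentValue <- function(w) {
  if (nrow(w) > ncol(w)) w <- t(w)
  n <- nrow(w)
  best <- -Inf
  rec <- function(i, used, acc) {
    if (i > n) {
      if (acc > best) best <<- acc
      return(invisible(NULL))
    }
    for (j in setdiff(seq_len(ncol(w)), used)) {
      rec(i + 1, c(used, j), acc + w[i, j])
    }
  }
  rec(1, integer(0), 0)
  best
}

# Exhaustive LCCS oracle: enumerate all non-empty subsets of the mapped
# nodes; keep those inducing a weakly connected conserved sub-graph;
# maximise node count, then conserved-edge count.
bruteLccs <- function(module, target, mapping) {
  mapped <- intersect(module$nodes, names(mapping))
  m <- length(mapped)
  if (m == 0) return(list(nNodes = 0L, nEdges = 0L))
  te <- pathwayEdges(target)
  teKeys <- paste(te[, 1], te[, 2])
  adj <- matrix(FALSE, m, m, dimnames = list(mapped, mapped))
  me <- module$edges
  for (e in seq_len(nrow(me))) {
    a1 <- me[e, 1]; a2 <- me[e, 2]
    if (a1 %in% mapped && a2 %in% mapped &&
        paste(mapping[a1], mapping[a2]) %in% teKeys) {
      adj[a1, a2] <- TRUE
    }
  }
  sym <- adj | t(adj)
  bestN <- 0L; bestE <- 0L
  for (mask in seq_len(2^m) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    if (length(sel) == 0 || length(sel) < bestN) next
    # BFS connectivity on the selected nodes
    seen <- sel[1]
    frontier <- sel[1]
    while (length(frontier) > 0) {
      nxt <- setdiff(sel[colSums(sym[frontier, sel, drop = FALSE]) > 0], seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    if (length(seen) < length(sel)) next
    ne <- sum(adj[sel, sel])
    if (length(sel) > bestN || (length(sel) == bestN && ne > bestE)) {
      bestN <- length(sel)
      bestE <- ne
    }
  }
  list(nNodes = bestN, nEdges = as.integer(bestE))
}

# k byte-identical copies of one organism's pathway set.
cloneOrganismSet <- function(base, k) {
  orgs <- sprintf("org%02d", seq_len(k))
  organismSet(unlist(lapply(orgs, function(o) {
    lapply(base, function(p) Pathway(pathwayId(p), o, reactions(p),
                                     edges = pathwayEdges(p)))
  }), recursive = FALSE))
}
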