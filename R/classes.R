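#' @import methods
NULL

# ---------------------------------------------------------------------------
# Pathway
# ---------------------------------------------------------------------------

#' Pathway: a directed reaction graph for one metabolic pathway
#'
#' Nodes are enzymatic reactions; a directed edge u -> v means an output
#' compound of u is an input compound of v. If both endpoints are reversible
#' the reverse edge is also present (reversible closure). Self-loops are
#' dropped.
#'
#' @slot pathwayId pathway identifier (e.g. a KEGG map number).
#' @slot organismId organism identifier.
#' @slot reactions data.frame with columns `id` (character), `ec` (list of
#'   character vectors, one or more EC numbers per reaction; `"-"` marks an
#'   unknown enzyme), `inputs` / `outputs` (lists of character vectors of
#'   compound IDs) and `reversible` (logical).
#' @slot edges two-column character matrix of directed reaction-id pairs.
#'
#' @exportClass Pathway
setClass("Pathway",
  representation(
    pathwayId = "character",
    organismId = "character",
    reactions = "data.frame",
    edges = "matrix"
  )
)

validPathway <- function(object) {
  rx <- object@reactions
  msgs <- character(0)
  need <- c("id", "ec", "inputs", "outputs", "reversible")
  if (!all(need %in% names(rx))) {
    return(paste("reactions must have columns:", paste(need, collapse = ", ")))
  }
  if (length(object@pathwayId) != 1 || !nzchar(object@pathwayId)) {
    msgs <- c(msgs, "pathwayId must be a non-empty string")
  }
  if (length(object@organismId) != 1 || !nzchar(object@organismId)) {
    msgs <- c(msgs, "organismId must be a non-empty string")
  }
  if (anyDuplicated(rx$id)) {
    msgs <- c(msgs, paste("duplicate reaction id:",
                          rx$id[duplicated(rx$id)][1]))
  }
  if (any(!nzchar(rx$id))) msgs <- c(msgs, "reaction ids must be non-empty")
  badEC <- vapply(rx$ec, function(e) length(e) < 1 || any(!nzchar(e)),
                  logical(1))
  if (any(badEC)) msgs <- c(msgs, "each reaction needs >= 1 non-empty EC field")
  emptyC <- vapply(rx$inputs, length, integer(1)) < 1 |
    vapply(rx$outputs, length, integer(1)) < 1
  if (any(emptyC)) {
    msgs <- c(msgs, paste("reaction with empty input or output compound set:",
                          rx$id[emptyC][1]))
  }
  e <- object@edges
  if (nrow(e) > 0) {
    unknown <- setdiff(c(e[, 1], e[, 2]), rx$id)
    if (length(unknown) > 0) {
      msgs <- c(msgs, paste("edge endpoint not a reaction:", unknown[1]))
    }
    if (any(e[, 1] == e[, 2])) msgs <- c(msgs, "self-loop edges not allowed")
    # reversible closure
    rev <- rx$reversible
    names(rev) <- rx$id
    both <- rev[e[, 1]] & rev[e[, 2]]
    if (any(both)) {
      have <- edgeKey(e[, 1], e[, 2])
      missingRev <- !(edgeKey(e[both, 2], e[both, 1]) %in% have)
      if (any(missingRev)) {
        msgs <- c(msgs, "reversible closure violated (missing reverse edge)")
      }
    }
  }
  if (length(msgs) == 0) TRUE else msgs
}
setValidity("Pathway", validPathway)

reactionTable <- function(id, ec, inputs, outputs, reversible) {
  ec <- lapply(ec, as.character)
  inputs <- lapply(inputs, function(x) unique(as.character(x)))
  outputs <- lapply(outputs, function(x) unique(as.character(x)))
  df <- data.frame(id = as.character(id), reversible = as.logical(reversible),
                   stringsAsFactors = FALSE)
  df$ec <- ec
  df$inputs <- inputs
  df$outputs <- outputs
  df[, c("id", "ec", "inputs", "outputs", "reversible")]
}

# Add reverse edges wherever both endpoints are reversible.
reversibleClosure <- function(edges, reactions) {
  edges <- asEdgeMatrix(edges)
  if (nrow(edges) == 0) return(edges)
  rev <- reactions$reversible
  names(rev) <- reactions$id
  both <- rev[edges[, 1]] & rev[edges[, 2]]
  if (any(both)) {
    edges <- rbind(edges, edges[both, c(2, 1), drop = FALSE])
  }
  canonicalEdges(edges)
}

# Substrate-product rule: u -> w whenever an output compound of u is an input
# compound of w (u != w).
substrateEdges <- function(reactions) {
  n <- nrow(reactions)
  if (n < 2) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to"))))
  }
  from <- character(0); to <- character(0)
  for (i in seq_len(n)) {
    out_i <- reactions$outputs[[i]]
    for (j in seq_len(n)) {
      if (i == j) next
      if (any(out_i %in% reactions$inputs[[j]])) {
        from <- c(from, reactions$id[i])
        to <- c(to, reactions$id[j])
      }
    }
  }
  cbind(from = from, to = to)
}

#' Construct a Pathway
#'
#' @param pathwayId,organismId identifiers.
#' @param reactions a data.frame as documented in [Pathway-class], or a list
#'   of per-reaction lists with elements `id`, `ec`, `inputs`, `outputs`,
#'   `reversible`.
#' @param edges optional explicit directed edges (two-column matrix or list of
#'   pairs of reaction ids). Self-loops are dropped; the reversible closure is
#'   always applied.
#' @param deriveEdges if `TRUE`, edges implied by the substrate-product rule
#'   (an output compound of u is an input compound of w) are added to any
#'   explicit ones.
#' @return a validated [Pathway-class] object.
#' @export
Pathway <- function(pathwayId, organismId, reactions, edges = NULL,
                    deriveEdges = FALSE) {
  if (!is.data.frame(reactions)) {
    reactions <- reactionTable(
      id = vapply(reactions, function(r) as.character(r$id), character(1)),
      ec = lapply(reactions, function(r) r$ec %||% "-"),
      inputs = lapply(reactions, `[[`, "inputs"),
      outputs = lapply(reactions, `[[`, "outputs"),
      reversible = vapply(reactions, function(r) isTRUE(r$reversible),
                          logical(1))
    )
  }
  edges <- asEdgeMatrix(edges)
  if (deriveEdges) edges <- rbind(edges, substrateEdges(reactions))
  if (nrow(edges) > 0) {
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  }
  edges <- reversibleClosure(canonicalEdges(edges), reactions)
  new("Pathway", pathwayId = as.character(pathwayId),
      organismId = as.character(organismId),
      reactions = reactions, edges = edges)
}

#' @describeIn Pathway-class pathway identifier
#' @param x,object a `Pathway`
#' @export
pathwayId <- function(x) x@pathwayId

#' @describeIn Pathway-class organism identifier
#' @export
organismId <- function(x) x@organismId

#' @describeIn Pathway-class reaction table
#' @export
reactions <- function(x) x@reactions

#' @describeIn Pathway-class reaction identifiers in pathway order
#' @export
reactionIds <- function(x) x@reactions$id

#' @describeIn Pathway-class number of reactions
#' @export
nReactions <- function(x) nrow(x@reactions)

#' @describeIn Pathway-class directed edge matrix
#' @export
pathwayEdges <- function(x) x@edges

setMethod("show", "Pathway", function(object) {
  cat(sprintf("Pathway '%s' of organism '%s': %d reactions, %d edges\n",
              object@pathwayId, object@organismId,
              nrow(object@reactions), nrow(object@edges)))
})

# ---------------------------------------------------------------------------
# CompoundSimilarityTable
# ---------------------------------------------------------------------------

#' Compound similarity lookup table
#'
#' Symmetric map from unordered compound-ID pairs to similarities in `[0,1]`.
#' Lookup policy: identical IDs always score 1; pairs absent from the table
#' score 0.
#'
#' @slot scores named numeric vector keyed by canonical unordered pair.
#' @exportClass CompoundSimilarityTable
setClass("CompoundSimilarityTable", representation(scores = "numeric"))

setValidity("CompoundSimilarityTable", function(object) {
  s <- object@scores
  if (length(s) > 0 && (any(s < 0) || any(s > 1))) {
    return("compound similarity scores must lie in [0,1]")
  }
  TRUE
})

#' Construct a compound similarity table
#'
#' @param compoundA,compoundB character vectors of compound IDs.
#' @param score numeric similarities in `[0,1]`.
#' @return a [CompoundSimilarityTable-class].
#' @export
compoundTable <- function(compoundA = character(0),
                          compoundB = character(0),
                          score = numeric(0)) {
  stopIfNot(length(compoundA) == length(compoundB) &&
              length(compoundB) == length(score),
            "compoundA, compoundB and score must have equal length")
  if (any(score < 0 | score > 1)) {
    stop("compound similarity score outside [0,1]", call. = FALSE)
  }
  self <- compoundA == compoundB
  if (any(self & score != 1)) {
    warning("identity pair(s) with score != 1 overridden to 1")
  }
  keep <- !self
  scores <- score[keep]
  names(scores) <- pairKey(compoundA[keep], compoundB[keep])
  scores <- scores[!duplicated(names(scores))]
  new("CompoundSimilarityTable", scores = scores)
}

#' Look up compound similarities
#'
#' Vectorised over pairs. Identical IDs score 1; pairs not in the table score
#' 0; `NULL` table means pure identity lookup.
#'
#' @param table a [CompoundSimilarityTable-class] or `NULL`.
#' @param a,b character vectors of compound IDs (recycled to equal length).
#' @return numeric vector of similarities in `[0,1]`.
#' @export
compoundSimilarity <- function(table, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- numeric(n)
  ident <- a == b
  out[ident] <- 1
  if (!is.null(table) && any(!ident)) {
    hit <- table@scores[pairKey(a[!ident], b[!ident])]
    hit[is.na(hit)] <- 0
    out[!ident] <- hit
  }
  out
}

setMethod("show", "CompoundSimilarityTable", function(object) {
  cat(sprintf("CompoundSimilarityTable: %d stored pair(s) (identity fallback)\n",
              length(object@scores)))
})

# ---------------------------------------------------------------------------
# OrganismSet
# ---------------------------------------------------------------------------

osKey <- function(org, pid) paste(org, pid, sep = "\r")

#' A set of organisms with common pathways
#'
#' @slot organisms ordered character vector of organism IDs (k >= 2).
#' @slot pathways named list of [Pathway-class] objects keyed by
#'   (organism, pathway).
#' @slot commonPathwayIds ordered character vector of the pathway IDs present
#'   for every organism.
#' @exportClass OrganismSet
setClass("OrganismSet",
  representation(
    organisms = "character",
    pathways = "list",
    commonPathwayIds = "character"
  )
)

setValidity("OrganismSet", function(object) {
  if (length(object@organisms) < 2) return("need >= 2 organisms")
  if (anyDuplicated(object@organisms)) return("duplicate organism IDs")
  for (org in object@organisms) {
    for (pid in object@commonPathwayIds) {
      p <- object@pathways[[osKey(org, pid)]]
      if (is.null(p)) {
        return(sprintf("organism '%s' lacks common pathway '%s'", org, pid))
      }
      if (organismId(p) != org || pathwayId(p) != pid) {
        return("pathway stored under inconsistent key")
      }
    }
  }
  TRUE
})

#' Construct an OrganismSet from a list of pathways
#'
#' Common pathways are those present for every organism; pathways outside the
#' intersection are kept but ignored by the alignment pipeline.
#'
#' @param pathways list of [Pathway-class] objects.
#' @return an [OrganismSet-class].
#' @export
organismSet <- function(pathways) {
  stopIfNot(length(pathways) > 0, "no pathways given")
  orgs <- sort(unique(vapply(pathways, organismId, character(1))))
  byKey <- list()
  for (p in pathways) {
    byKey[[osKey(organismId(p), pathwayId(p))]] <- p
  }
  pids <- sort(unique(vapply(pathways, pathwayId, character(1))))
  common <- pids[vapply(pids, function(pid) {
    all(vapply(orgs, function(o) !is.null(byKey[[osKey(o, pid)]]), logical(1)))
  }, logical(1))]
  new("OrganismSet", organisms = orgs, pathways = byKey,
      commonPathwayIds = common)
}

#' @describeIn OrganismSet-class organism IDs
#' @param x,object an `OrganismSet`
#' @export
organisms <- function(x) x@organisms

#' @describeIn OrganismSet-class IDs of pathways shared by all organisms
#' @export
commonPathwayIds <- function(x) x@commonPathwayIds

#' @describeIn OrganismSet-class retrieve one pathway
#' @param org,pid organism and pathway identifiers
#' @export
getPathway <- function(x, org, pid) {
  p <- x@pathways[[osKey(org, pid)]]
  if (is.null(p)) {
    stop(sprintf("no pathway '%s' for organism '%s'", pid, org), call. = FALSE)
  }
  p
}

setMethod("show", "OrganismSet", function(object) {
  cat(sprintf("OrganismSet: %d organisms, %d common pathway(s)\n",
              length(object@organisms), length(object@commonPathwayIds)))
  cat("  organisms:", paste(object@organisms, collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# UnionGraph
# ---------------------------------------------------------------------------

#' Union graph of aligned pathways
#'
#' An edge-less graph whose nodes are composite nodes: tuples of one-to-one
#' mapped reactions across pathways, anchored on the reactions of the largest
#' pathway. `H` is the homological similarity matrix over composite nodes
#' (for a merged union graph, the element-wise sum of the pairwise matrices).
#'
#' @slot pathwayId the pathway being aligned.
#' @slot anchorOrganism organism owning the anchor pathway (largest pathway).
#' @slot anchors reaction IDs of the anchor pathway, in pathway order.
#' @slot members character matrix (n x m): one row per composite node, one
#'   column per organism (anchor first); `NA` marks a gap.
#' @slot H numeric n x n homological similarity matrix.
#' @exportClass UnionGraph
setClass("UnionGraph",
  representation(
    pathwayId = "character",
    anchorOrganism = "character",
    anchors = "character",
    members = "matrix",
    H = "matrix"
  )
)

setValidity("UnionGraph", function(object) {
  n <- length(object@anchors)
  if (nrow(object@members) != n) return("members rows must match anchors")
  if (!identical(dim(object@H), c(n, n))) return("H must be n x n")
  if (n > 0 && max(abs(object@H - t(object@H))) > 1e-9) {
    return("H must be symmetric")
  }
  if (is.null(colnames(object@members))) {
    return("members must have organism column names")
  }
  if (colnames(object@members)[1] != object@anchorOrganism) {
    return("first members column must be the anchor organism")
  }
  if (!identical(unname(object@members[, 1]), unname(object@anchors))) {
    return("anchor column must equal anchors")
  }
  TRUE
})

#' @describeIn UnionGraph-class composite-node member matrix
#' @param x,object a `UnionGraph`
#' @export
compositeNodes <- function(x) x@members

#' @describeIn UnionGraph-class homological similarity matrix
#' @export
homologicalMatrix <- function(x) x@H

setMethod("show", "UnionGraph", function(object) {
  cat(sprintf(
    "UnionGraph for pathway '%s': %d composite nodes, anchor '%s', %d organism slot(s)\n",
    object@pathwayId, length(object@anchors), object@anchorOrganism,
    ncol(object@members)))
  gaps <- sum(is.na(object@members))
  cat(sprintf("  gaps: %d of %d member slot(s)\n", gaps,
              length(object@members)))
})

# ---------------------------------------------------------------------------
# ClusterResult / ModuleMapping
# ---------------------------------------------------------------------------

#' Affinity propagation clustering result
#'
#' @slot exemplars indices of exemplar nodes.
#' @slot assignment integer vector: node index -> cluster id (1..K, in order
#'   of sorted exemplar indices).
#' @slot iterations number of message-passing iterations run.
#' @slot converged whether the exemplar set was stable for the required
#'   number of iterations.
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(
    exemplars = "integer",
    assignment = "integer",
    iterations = "integer",
    converged = "logical"
  )
)

setValidity("ClusterResult", function(object) {
  if (length(object@exemplars) < 1) return("need >= 1 exemplar")
  if (any(is.na(object@assignment))) return("every node must be assigned")
  k <- length(object@exemplars)
  if (any(object@assignment < 1 | object@assignment > k)) {
    return("assignment out of range")
  }
  selfIds <- object@assignment[object@exemplars]
  if (!identical(selfIds, seq_len(k))) {
    return("each exemplar must be assigned to its own cluster")
  }
  TRUE
})

#' @describeIn ClusterResult-class exemplar node indices
#' @param x,object a `ClusterResult`
#' @export
exemplars <- function(x) x@exemplars

#' @describeIn ClusterResult-class cluster assignment vector
#' @export
clusterAssignment <- function(x) x@assignment

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d cluster(s) over %d node(s); %s after %d iteration(s)\n",
              length(object@exemplars), length(object@assignment),
              if (object@converged) "converged" else "NOT converged",
              object@iterations))
})

#' Mapped functional modules across organisms
#'
#' One entry per cluster of composite nodes; each entry holds, per organism,
#' the functional module (induced sub-graph of that organism's pathway on the
#' cluster's member reactions). Modules within a cluster are mutually mapped.
#'
#' @slot pathwayId the pathway the modules come from.
#' @slot clusters list (one per cluster) of named lists of modules; each
#'   module is a list with elements `organismId`, `pathwayId`, `nodes`
#'   (character) and `edges` (two-column character matrix).
#' @exportClass ModuleMapping
setClass("ModuleMapping",
  representation(pathwayId = "character", clusters = "list"))

#' @describeIn ModuleMapping-class per-cluster module lists
#' @param x,object a `ModuleMapping`
#' @export
moduleClusters <- function(x) x@clusters

setMethod("show", "ModuleMapping", function(object) {
  sizes <- vapply(object@clusters, function(cl) {
    max(c(0L, vapply(cl, function(m) length(m$nodes), integer(1))))
  }, integer(1))
  cat(sprintf("ModuleMapping for pathway '%s': %d cluster(s), largest module %d node(s)\n",
              object@pathwayId, length(object@clusters),
              if (length(sizes)) max(sizes) else 0L))
})
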