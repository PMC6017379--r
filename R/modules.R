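# Phase II module extraction: per-pathway induced sub-graphs of the
# composite-node clusters, and the cross-organism module mappings.

inducedEdges <- function(p, nodes) {
  e <- pathwayEdges(p)
  if (nrow(e) == 0 || length(nodes) == 0) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to"))))
  }
  e[e[, 1] %in% nodes & e[, 2] %in% nodes, , drop = FALSE]
}

#' Extract mapped functional modules from a clustered union graph
#'
#' For every cluster of composite nodes and every organism, collects that
#' organism's member reactions (skipping gaps) and takes the induced
#' sub-graph in the organism's pathway. Modules in the same cluster are
#' mutually mapped.
#'
#' @param clusters a [ClusterResult-class] over the union graph's composite
#'   nodes.
#' @param u the [UnionGraph-class] that was clustered.
#' @param os the [OrganismSet-class] the pathways come from.
#' @return a [ModuleMapping-class].
#' @export
extractModules <- function(clusters, u, os) {
  mem <- compositeNodes(u)
  stopIfNot(length(clusterAssignment(clusters)) == nrow(mem),
            "clustering does not cover the union graph's nodes")
  orgs <- colnames(mem)
  pid <- u@pathwayId
  asn <- clusterAssignment(clusters)
  cls <- lapply(seq_along(exemplars(clusters)), function(cid) {
    rows <- which(asn == cid)
    mods <- lapply(orgs, function(org) {
      nodes <- mem[rows, org]
      nodes <- nodes[!is.na(nodes)]
      p <- getPathway(os, org, pid)
      list(organismId = org, pathwayId = pid, nodes = unname(nodes),
           edges = inducedEdges(p, nodes))
    })
    names(mods) <- orgs
    mods
  })
  new("ModuleMapping", pathwayId = pid, clusters = cls)
}

# The module of `org` with the maximal node count (ties: first cluster).
# Returns NULL when the organism has no mapped reactions at all.
largestModule <- function(mm, org) {
  sizes <- vapply(moduleClusters(mm), function(cl) length(cl[[org]]$nodes),
                  integer(1))
  if (length(sizes) == 0 || max(sizes) == 0) return(NULL)
  moduleClusters(mm)[[which.max(sizes)]][[org]]
}

# Cluster index maximizing min(|M_i|, |M_j|) over the two organisms.
largestJointCluster <- function(mm, orgI, orgJ) {
  sizes <- vapply(moduleClusters(mm), function(cl) {
    min(length(cl[[orgI]]$nodes), length(cl[[orgJ]]$nodes))
  }, integer(1))
  if (length(sizes) == 0 || max(sizes) == 0) return(NULL)
  which.max(sizes)
}
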