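# End-to-end orchestration: align all common pathways, score organisms,
# build the tree, write artifacts.

#' Run the full alignment-to-tree pipeline
#'
#' Phase I builds a merged union graph per common pathway (greedy
#' maximum-weight bipartite matching against the largest pathway); Phase II
#' clusters its composite nodes by affinity propagation and extracts mapped
#' functional modules; Phase III scores organism pairs from the largest
#' common connected sub-graphs of the largest mapped modules, averages over
#' pathways into the BSim similarity matrix, takes distances `1 - BSim` and
#' builds the tree.
#'
#' @param os an [OrganismSet-class] (or a directory of pathway files, passed
#'   through [readOrganismSet]).
#' @param table optional [CompoundSimilarityTable-class] (or a TSV path).
#' @param weights a [scoringWeights] object.
#' @param minWeight,matching,rescale,hMean see [buildUnionGraph].
#' @param preference,damping,maxIter,convIter see [affinityPropagation].
#' @param jointMmax see [pathwaySimScore].
#' @param treeMethod `"nj"` or `"upgma"`.
#' @param seed integer seed for the clustering jitter.
#' @param outDir if non-`NULL`, write artifacts there: `bsim.tsv`,
#'   `dist.phylip`, `tree.nwk`, per-pathway `union_<id>.json` and
#'   `modules_<id>.json`.
#' @param verbose print per-phase summaries.
#' @return list with `bsim`, `dist`, `tree`, `perPathway`, `unions`,
#'   `modules`.
#' @export
runPipeline <- function(os, table = NULL, weights = scoringWeights(),
                        minWeight = 0, matching = "greedy", rescale = TRUE,
                        hMean = FALSE, preference = "median", damping = 0.9,
                        maxIter = 1000, convIter = 50, jointMmax = FALSE,
                        treeMethod = "nj", seed = 1, outDir = NULL,
                        verbose = FALSE) {
  if (is.character(os)) os <- readOrganismSet(os)
  stopIfNot(is(os, "OrganismSet"), "os must be an OrganismSet or a directory")
  stopIfNot(length(organisms(os)) >= 2, "need >= 2 organisms")
  stopIfNot(length(commonPathwayIds(os)) >= 1,
            "organisms share no common pathways")
  if (is.character(table)) table <- readCompoundTable(table)
  sim <- organismSimilarity(os, table = table, weights = weights,
                            minWeight = minWeight, matching = matching,
                            rescale = rescale, hMean = hMean,
                            preference = preference, damping = damping,
                            maxIter = maxIter, convIter = convIter,
                            jointMmax = jointMmax, seed = seed)
  d <- distanceMatrix(sim$bsim)
  tree <- buildTree(d, method = treeMethod)
  if (verbose) {
    for (pid in names(sim$unions)) {
      u <- sim$unions[[pid]]
      mem <- compositeNodes(u)
      message(sprintf(
        "pathway %s: %d composite nodes, %d gaps, %d clusters", pid,
        nrow(mem), sum(is.na(mem)),
        length(moduleClusters(sim$modules[[pid]]))))
    }
    message(sprintf("mean off-diagonal BSim: %.4f",
                    mean(sim$bsim[row(sim$bsim) != col(sim$bsim)])))
  }
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(sim$bsim, file.path(outDir, "bsim.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    writePhylipDist(d, file.path(outDir, "dist.phylip"))
    ape::write.tree(tree, file.path(outDir, "tree.nwk"))
    for (pid in names(sim$unions)) {
      exportUnionGraph(sim$unions[[pid]],
                       file.path(outDir, sprintf("union_%s.json", pid)))
      exportModuleMapping(sim$modules[[pid]],
                          file.path(outDir, sprintf("modules_%s.json", pid)))
    }
  }
  list(bsim = sim$bsim, dist = d, tree = tree, perPathway = sim$perPathway,
       unions = sim$unions, modules = sim$modules)
}

asPhylo <- function(x) {
  if (inherits(x, "phylo")) return(x)
  stopIfNot(is.character(x) && length(x) == 1, "expected a phylo, file or Newick string")
  tr <- tryCatch(
    if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x),
    error = function(e) NULL
  )
  if (is.null(tr)) stop("could not parse Newick input: ", x, call. = FALSE)
  tr
}

#' Compare two trees by cousin-pair similarity
#'
#' @param a,b trees: `ape::phylo` objects, Newick strings or file paths.
#' @param maxDegree degree bound for the comparison (default 2).
#' @return list with `similarity`, `shared`, `onlyA`, `onlyB` (the (pair,
#'   degree) tuples involved).
#' @export
compareTrees <- function(a, b, maxDegree = 2) {
  ta <- asPhylo(a); tb <- asPhylo(b)
  sim <- treeSimilarity(ta, tb, maxDegree)
  sa <- cousinTuples(ta, maxDegree)
  sb <- cousinTuples(tb, maxDegree)
  list(similarity = sim, shared = intersect(sa, sb),
       onlyA = setdiff(sa, sb), onlyB = setdiff(sb, sa))
}
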