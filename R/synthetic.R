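# Synthetic organism sets with a known generating tree: shared pathway
# templates per lineage, seeded per-organism divergence.

#' Configuration for the synthetic organism-set generator
#'
#' Defaults describe a moderate-divergence scenario at the scale of published
#' pathway-based phylogenies: 10 organisms in 2 lineages sharing 20 pathways
#' of 20 reactions, with per-organism EC-mutation, compound-substitution and
#' reaction-indel rates of 0.1 and inter-lineage divergence 3 times the
#' intra-lineage divergence.
#'
#' @param k number of organisms (>= 2).
#' @param p number of common pathways (>= 1).
#' @param templateSize reactions per pathway template.
#' @param nLineages number of lineages; organisms are split into contiguous
#'   groups of (near) equal size.
#' @param ecRate per-reaction probability of redrawing one EC digit (deeper
#'   digits are more likely to mutate).
#' @param compoundRate per-compound-slot substitution probability.
#' @param indelRate fraction of reactions deleted and replaced by random new
#'   ones.
#' @param clockLike if `TRUE`, the mutation rounds on an edge double with
#'   the height of the subtree below it (capped at 8), giving approximately
#'   clock-like branch lengths with divergence signal at several nested
#'   scales; if `FALSE` (default) every edge applies one round.
#' @param interScale inter- vs intra-lineage divergence ratio: the edge from
#'   the shared ancestor into each lineage receives `ceiling(interScale * d)`
#'   rounds of mutation at the per-organism rates, where `d` is the deepest
#'   root-to-leaf mutation-round total inside that lineage, so inter-lineage
#'   organism pairs are at least `interScale` times as diverged as
#'   intra-lineage ones.
#' @param seed integer seed.
#' @return a validated `generator_config` list.
#' @export
generatorConfig <- function(k = 10, p = 20, templateSize = 20, nLineages = 2,
                            ecRate = 0.1, compoundRate = 0.1, indelRate = 0.1,
                            interScale = 3, clockLike = FALSE, seed = 1) {
  stopIfNot(k >= 2, "need k >= 2 organisms")
  stopIfNot(p >= 1, "need p >= 1 pathways")
  stopIfNot(templateSize >= 2, "templates need >= 2 reactions")
  stopIfNot(nLineages >= 1 && nLineages <= k, "invalid lineage count")
  for (r in c(ecRate, compoundRate, indelRate)) {
    stopIfNot(r >= 0 && r <= 1, "rates must lie in [0,1]")
  }
  stopIfNot(interScale >= 0, "interScale must be non-negative")
  groups <- rep(seq_len(nLineages), each = ceiling(k / nLineages))[seq_len(k)]
  structure(list(k = k, p = p, templateSize = templateSize,
                 nLineages = nLineages, groups = groups, ecRate = ecRate,
                 compoundRate = compoundRate, indelRate = indelRate,
                 interScale = interScale, clockLike = isTRUE(clockLike),
                 seed = seed),
            class = "generator_config")
}

randomEC <- function() {
  paste(sample(1:6, 1), sample(1:20, 1), sample(1:20, 1), sample(1:99, 1),
        sep = ".")
}

# A random pathway template: a reaction chain through shared compounds, with
# occasional extra branch outputs and cofactor-like extra compounds, so the
# derived substrate-product graph is connected but not a pure path.
makeTemplate <- function(pid, size) {
  chain <- sprintf("%s_c%02d", pid, 0:size)
  extras <- sprintf("%s_x%02d", pid, 1:5)
  rx <- lapply(seq_len(size), function(i) {
    inputs <- chain[i]
    outputs <- chain[i + 1]
    if (stats::runif(1) < 0.3) inputs <- c(inputs, sample(extras, 1))
    if (stats::runif(1) < 0.3) outputs <- c(outputs, sample(extras, 1))
    if (i < size - 1 && stats::runif(1) < 0.25) {
      outputs <- c(outputs, chain[i + 2])    # shortcut branch
    }
    list(id = sprintf("r%02d", i), ec = randomEC(), inputs = inputs,
         outputs = outputs, reversible = stats::runif(1) < 0.2)
  })
  list(reactions = rx, alphabet = c(chain, extras))
}

mutateDigit <- function(ec) {
  f <- strsplit(ec, ".", fixed = TRUE)[[1]]
  if (length(f) < 1) return(ec)
  pos <- sample(seq_along(f), 1,
                prob = c(0.1, 0.2, 0.3, 0.4)[seq_along(f)])
  lim <- c(6, 20, 20, 99)[min(pos, 4)]
  f[pos] <- as.character(sample(seq_len(lim), 1))
  paste(f, collapse = ".")
}

# Apply seeded mutations to a template's reaction list.
mutateReactions <- function(rx, alphabet, ecRate, compoundRate, indelRate,
                            tag) {
  substituteCompounds <- function(set) {
    hit <- stats::runif(length(set)) < compoundRate
    set[hit] <- sample(alphabet, sum(hit), replace = TRUE)
    unique(set)
  }
  rx <- lapply(rx, function(r) {
    if (stats::runif(1) < ecRate) r$ec <- vapply(r$ec, mutateDigit, character(1))
    r$inputs <- substituteCompounds(r$inputs)
    r$outputs <- substituteCompounds(r$outputs)
    r
  })
  nDel <- round(indelRate * length(rx))
  if (nDel > 0) {
    drop <- sample(seq_along(rx), nDel)
    rx <- rx[-drop]
    for (i in seq_len(nDel)) {
      rx[[length(rx) + 1]] <- list(
        id = sprintf("n%s%02d", tag, i),
        ec = randomEC(),
        inputs = sample(alphabet, sample(1:2, 1)),
        outputs = sample(alphabet, sample(1:2, 1)),
        reversible = stats::runif(1) < 0.2
      )
    }
  }
  rx
}

# Random rooted binary topology over a label set, as a nested list
# (leaf = label, internal node = list of two subtrees).
randomTopology <- function(labs) {
  if (length(labs) == 1) return(labs)
  perm <- sample(labs)
  s <- if (length(labs) == 2) 1 else sample(seq_len(length(labs) - 1), 1)
  list(randomTopology(perm[seq_len(s)]), randomTopology(perm[-seq_len(s)]))
}

topoHeight <- function(node) {
  if (!is.list(node)) return(0L)
  1L + max(vapply(node, topoHeight, integer(1)))
}

# Mutation rounds applied on the edge into a node: one per edge (uniform
# divergence per split), or, in the clock-like regime, doubling with the
# height of the subtree below the edge (capped at 8) so deep splits carry
# proportionally more divergence.
edgeRounds <- function(node, clockLike = FALSE) {
  if (clockLike) as.integer(min(2^topoHeight(node), 8)) else 1L
}

# Deepest root-to-leaf mutation-round total of a subtree.
pathRounds <- function(node, clockLike = FALSE) {
  if (!is.list(node)) return(0L)
  max(vapply(node, function(ch) {
    edgeRounds(ch, clockLike) + pathRounds(ch, clockLike)
  }, integer(1)))
}

# Newick for a subtree: each edge's length is its mutation-round count times
# the per-round divergence `bl`; the edge into the subtree's own root can be
# overridden with `rootRounds`.
topoNewick <- function(node, bl, clockLike = FALSE, rootRounds = NULL) {
  r <- rootRounds %||% edgeRounds(node, clockLike)
  if (!is.list(node)) return(sprintf("%s:%.6f", node, r * bl))
  paste0("(", paste(vapply(node, topoNewick, character(1), bl = bl,
                           clockLike = clockLike),
                    collapse = ","), "):", sprintf("%.6f", r * bl))
}

#' Generate a synthetic organism set with a known generating tree
#'
#' Draws a random binary generating tree (one clade per lineage), builds `p`
#' random ancestral pathway templates, and evolves each template down the
#' tree: every within-lineage edge applies one round of seeded mutations
#' (EC-digit redraws, compound substitutions, reaction indels) at the
#' per-organism rates, and the edge from the ancestor into each lineage
#' applies `ceiling(interScale * d)` rounds (`d` = the lineage's deepest
#' root-to-leaf round total), so inter-lineage pairs diverge at least
#' `interScale` times as much as intra-lineage ones. With
#' `cfg$clockLike = TRUE`, within-lineage edges instead apply rounds doubling
#' with the height of the subtree below them (capped at 8), spreading the
#' divergence signal over nested scales. Mutation counts accumulate with tree
#' distance. Edges of the generated pathways are derived from compounds via
#' the substrate-product rule, so compound substitutions and indels perturb
#' topology organically.
#'
#' @param cfg a [generatorConfig].
#' @return list with `organisms` (an [OrganismSet-class]), `tree` (the
#'   generating `ape::phylo` tree), `newick` (its Newick string) and `config`.
#' @export
generateOrganismSet <- function(cfg = generatorConfig()) {
  stopIfNot(inherits(cfg, "generator_config"),
            "cfg must come from generatorConfig()")
  withSeed(cfg$seed, {
    orgIds <- sprintf("org%02d", seq_len(cfg$k))
    pids <- sprintf("path%d", seq_len(cfg$p))
    lineageTopos <- lapply(seq_len(cfg$nLineages), function(l) {
      randomTopology(orgIds[cfg$groups == l])
    })
    interRounds <- vapply(lineageTopos, function(tp) {
      max(1L, as.integer(ceiling(cfg$interScale *
                                   max(1L, pathRounds(tp, cfg$clockLike)))))
    }, integer(1))
    intra <- max(cfg$ecRate + cfg$compoundRate + cfg$indelRate, 1e-6)
    newick <- if (cfg$nLineages == 1 && is.list(lineageTopos[[1]])) {
      paste0("(", paste(vapply(lineageTopos[[1]], topoNewick, character(1),
                               bl = intra, clockLike = cfg$clockLike),
                        collapse = ","), ");")
    } else {
      paste0("(", paste(vapply(seq_along(lineageTopos), function(l) {
        topoNewick(lineageTopos[[l]], bl = intra, clockLike = cfg$clockLike,
                   rootRounds = interRounds[l])
      }, character(1)), collapse = ","), ");")
    }
    pathways <- list()
    counter <- new.env()
    counter$n <- 0L
    evolve <- function(node, rx, pid, alphabet) {
      if (!is.list(node)) {
        pathways[[length(pathways) + 1]] <<-
          Pathway(pid, node, rx, deriveEdges = TRUE)
        return(invisible(NULL))
      }
      for (child in node) {
        childRx <- rx
        for (r in seq_len(edgeRounds(child, cfg$clockLike))) {
          counter$n <- counter$n + 1L
          childRx <- mutateReactions(childRx, alphabet, cfg$ecRate,
                                     cfg$compoundRate, cfg$indelRate,
                                     tag = sprintf("%04d", counter$n))
        }
        evolve(child, childRx, pid, alphabet)
      }
    }
    for (pid in pids) {
      tmpl <- makeTemplate(pid, cfg$templateSize)
      for (l in seq_len(cfg$nLineages)) {
        rootRx <- if (cfg$nLineages == 1) tmpl$reactions else {
          rx <- tmpl$reactions
          for (r in seq_len(interRounds[l])) {
            counter$n <- counter$n + 1L
            rx <- mutateReactions(rx, tmpl$alphabet, cfg$ecRate,
                                  cfg$compoundRate, cfg$indelRate,
                                  tag = sprintf("%04d", counter$n))
          }
          rx
        }
        if (!is.list(lineageTopos[[l]])) {
          pathways[[length(pathways) + 1]] <-
            Pathway(pid, lineageTopos[[l]], rootRx, deriveEdges = TRUE)
        } else {
          evolve(lineageTopos[[l]], rootRx, pid, tmpl$alphabet)
        }
      }
    }
    os <- organismSet(pathways)
    list(organisms = os, tree = ape::read.tree(text = newick),
         newick = newick, config = cfg)
  })
}
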