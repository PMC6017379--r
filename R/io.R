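# Pathway and table I/O: native JSON / TSV dialects, a minimal KGML subset,
# compound similarity tables and PHYLIP distance matrices.

#' Read a pathway file
#'
#' Native JSON schema:
#' `{"pathway_id", "organism_id", "reactions": [{"id","ec","inputs","outputs",
#' "reversible"}], "edges": [["u","v"], ...]}`. The TSV dialect mirrors it
#' with `#pathway_id` / `#organism_id` header lines and `#reactions` /
#' `#edges` sections (see [writePathway]). The KGML dialect reads a subset of
#' KEGG pathway XML: `<reaction>` entries become reactions,
#' `type="reversible"` sets reversibility, substrate/product names become
#' compound IDs, EC numbers are taken from `<entry type="enzyme">` elements
#' naming the reaction, relations are ignored and edges are always derived
#' from compounds.
#'
#' @param source path to the file.
#' @param dialect one of `"native-json"`, `"native-tsv"`, `"kgml"`.
#' @param deriveEdges add edges implied by the substrate-product rule to any
#'   explicitly listed ones (always `TRUE` for KGML).
#' @return a validated [Pathway-class].
#' @export
readPathway <- function(source, dialect = c("native-json", "native-tsv", "kgml"),
                        deriveEdges = FALSE) {
  dialect <- match.arg(dialect)
  switch(dialect,
    "native-json" = readPathwayJson(source, deriveEdges),
    "native-tsv" = readPathwayTsv(source, deriveEdges),
    "kgml" = readPathwayKgml(source)
  )
}

readPathwayJson <- function(source, deriveEdges) {
  x <- tryCatch(
    jsonlite::fromJSON(source, simplifyVector = FALSE),
    error = function(e) {
      stop(sprintf("malformed JSON pathway file '%s': %s", source,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  for (f in c("pathway_id", "organism_id", "reactions")) {
    if (is.null(x[[f]])) {
      stop(sprintf("pathway file '%s': missing element '%s'", source, f),
           call. = FALSE)
    }
  }
  rx <- lapply(x$reactions, function(r) {
    for (f in c("id", "inputs", "outputs")) {
      if (is.null(r[[f]])) {
        stop(sprintf("pathway file '%s': reaction missing '%s'", source, f),
             call. = FALSE)
      }
    }
    list(id = r$id,
         ec = unlist(r$ec) %||% "-",
         inputs = unlist(r$inputs),
         outputs = unlist(r$outputs),
         reversible = isTRUE(r$reversible))
  })
  edges <- lapply(x$edges %||% list(), unlist)
  Pathway(x$pathway_id, x$organism_id, rx, edges = edges,
          deriveEdges = isTRUE(x$derive_edges) || deriveEdges)
}

splitField <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ",", fixed = TRUE)[[1]]
}

readPathwayTsv <- function(source, deriveEdges) {
  lines <- readLines(source, encoding = "UTF-8")
  pid <- NULL; org <- NULL
  section <- ""
  rx <- list(); edges <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, "#")) {
      parts <- strsplit(sub("^#", "", line), "\t", fixed = TRUE)[[1]]
      key <- trimws(parts[1])
      if (key == "pathway_id") pid <- parts[2]
      else if (key == "organism_id") org <- parts[2]
      else if (key %in% c("reactions", "edges")) section <- key
      else stop(sprintf("line %d of '%s': unknown header '%s'", i, source, key),
                call. = FALSE)
      next
    }
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (section == "reactions") {
      if (length(f) != 5) {
        stop(sprintf("line %d of '%s': reaction rows need 5 tab-separated fields",
                     i, source), call. = FALSE)
      }
      rx[[length(rx) + 1]] <- list(
        id = f[1], ec = splitField(f[2]), inputs = splitField(f[3]),
        outputs = splitField(f[4]), reversible = tolower(f[5]) %in% c("true", "1")
      )
    } else if (section == "edges") {
      if (length(f) != 2) {
        stop(sprintf("line %d of '%s': edge rows need 2 fields", i, source),
             call. = FALSE)
      }
      edges[[length(edges) + 1]] <- f
    } else {
      stop(sprintf("line %d of '%s': data before a section header", i, source),
           call. = FALSE)
    }
  }
  if (is.null(pid) || is.null(org)) {
    stop(sprintf("'%s': missing #pathway_id or #organism_id header", source),
         call. = FALSE)
  }
  Pathway(pid, org, rx, edges = edges, deriveEdges = deriveEdges)
}

readPathwayKgml <- function(source) {
  doc <- tryCatch(xml2::read_xml(source), error = function(e) {
    stop(sprintf("malformed KGML file '%s': %s", source, conditionMessage(e)),
         call. = FALSE)
  })
  root <- xml2::xml_find_first(doc, "/pathway")
  if (inherits(root, "xml_missing")) {
    stop(sprintf("'%s': no <pathway> root element", source), call. = FALSE)
  }
  pid <- xml2::xml_attr(root, "name") %||% "unknown"
  org <- xml2::xml_attr(root, "org")
  if (is.na(org)) org <- "unknown"
  # EC numbers from enzyme entries, keyed by the reaction name they catalyze
  ecByReaction <- list()
  for (entry in xml2::xml_find_all(doc, "//entry[@type='enzyme']")) {
    rns <- strsplit(xml2::xml_attr(entry, "reaction") %||% "", " ")[[1]]
    ecs <- sub("^ec:", "", strsplit(xml2::xml_attr(entry, "name") %||% "", " ")[[1]])
    ecs <- ecs[nzchar(ecs)]
    for (rn in rns[nzchar(rns)]) {
      ecByReaction[[rn]] <- unique(c(ecByReaction[[rn]], ecs))
    }
  }
  stripPrefix <- function(x) sub("^(cpd|gl|rn):", "", x)
  rx <- lapply(xml2::xml_find_all(doc, "//reaction"), function(rxn) {
    name <- xml2::xml_attr(rxn, "name")
    subs <- xml2::xml_attr(xml2::xml_find_all(rxn, "substrate"), "name")
    prods <- xml2::xml_attr(xml2::xml_find_all(rxn, "product"), "name")
    if (length(subs) == 0 || length(prods) == 0) {
      stop(sprintf("'%s': reaction '%s' lacks substrates or products",
                   source, name), call. = FALSE)
    }
    list(id = stripPrefix(name),
         ec = ecByReaction[[name]] %||% "-",
         inputs = stripPrefix(subs),
         outputs = stripPrefix(prods),
         reversible = identical(xml2::xml_attr(rxn, "type"), "reversible"))
  })
  if (length(rx) == 0) {
    stop(sprintf("'%s': no <reaction> elements", source), call. = FALSE)
  }
  Pathway(pid, org, rx, deriveEdges = TRUE)
}

#' Write a pathway file
#'
#' Round-trips with [readPathway]: re-reading the written file yields a
#' pathway equal to `p` up to reaction ordering.
#'
#' @param p a [Pathway-class].
#' @param file output path.
#' @param dialect `"native-json"` or `"native-tsv"`.
#' @return `file`, invisibly.
#' @export
writePathway <- function(p, file, dialect = c("native-json", "native-tsv")) {
  dialect <- match.arg(dialect)
  rx <- reactions(p)
  if (dialect == "native-json") {
    obj <- list(
      pathway_id = pathwayId(p),
      organism_id = organismId(p),
      reactions = lapply(seq_len(nrow(rx)), function(i) {
        list(id = rx$id[i], ec = as.list(rx$ec[[i]]),
             inputs = as.list(rx$inputs[[i]]),
             outputs = as.list(rx$outputs[[i]]),
             reversible = rx$reversible[i])
      }),
      edges = apply(pathwayEdges(p), 1, as.list, simplify = FALSE)
    )
    jsonlite::write_json(obj, file, auto_unbox = TRUE, pretty = TRUE)
  } else {
    con <- file(file, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(c(
      paste0("#pathway_id\t", pathwayId(p)),
      paste0("#organism_id\t", organismId(p)),
      "#reactions",
      vapply(seq_len(nrow(rx)), function(i) {
        paste(rx$id[i], paste(rx$ec[[i]], collapse = ","),
              paste(rx$inputs[[i]], collapse = ","),
              paste(rx$outputs[[i]], collapse = ","),
              if (rx$reversible[i]) "true" else "false", sep = "\t")
      }, character(1)),
      "#edges",
      apply(pathwayEdges(p), 1, paste, collapse = "\t")
    ), con)
  }
  invisible(file)
}

#' Read a compound similarity table from TSV
#'
#' Expects three tab-separated columns (compoundA, compoundB, score), no
#' header. Identity pairs with score != 1 are overridden to 1 with a warning;
#' scores outside `[0,1]` are an error. An empty file yields the identity-only
#' table.
#'
#' @param source path to the TSV file.
#' @return a [CompoundSimilarityTable-class].
#' @export
readCompoundTable <- function(source) {
  lines <- readLines(source, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(compoundTable())
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(f, length, integer(1)) != 3)
  if (length(bad) > 0) {
    stop(sprintf("line %d of '%s': expected 3 tab-separated columns", bad[1],
                 source), call. = FALSE)
  }
  m <- do.call(rbind, f)
  score <- suppressWarnings(as.numeric(m[, 3]))
  if (any(is.na(score))) {
    stop(sprintf("line %d of '%s': non-numeric score",
                 which(is.na(score))[1], source), call. = FALSE)
  }
  if (any(score < 0 | score > 1)) {
    stop(sprintf("line %d of '%s': score outside [0,1]",
                 which(score < 0 | score > 1)[1], source), call. = FALSE)
  }
  compoundTable(m[, 1], m[, 2], score)
}

#' Read all pathway files in a directory into an OrganismSet
#'
#' Reads every `*.json` (native JSON), `*.tsv` (native TSV) and `*.xml`
#' (KGML) file in `dir`; organism and pathway identity come from the files.
#'
#' @param dir directory of pathway files.
#' @param deriveEdges passed to [readPathway] for the native dialects.
#' @return an [OrganismSet-class].
#' @export
readOrganismSet <- function(dir, deriveEdges = FALSE) {
  files <- list.files(dir, pattern = "\\.(json|tsv|xml)$", full.names = TRUE)
  stopIfNot(length(files) > 0, sprintf("no pathway files found in '%s'", dir))
  paths <- lapply(files, function(f) {
    d <- switch(tolower(tools::file_ext(f)),
                json = "native-json", tsv = "native-tsv", xml = "kgml")
    readPathway(f, dialect = d, deriveEdges = deriveEdges)
  })
  organismSet(paths)
}

#' Write / read a PHYLIP square distance matrix
#'
#' @param d symmetric numeric matrix with organism dimnames.
#' @param file path.
#' @return `writePhylipDist`: `file`, invisibly. `readPhylipDist`: the matrix.
#' @export
writePhylipDist <- function(d, file) {
  stopIfNot(is.matrix(d) && nrow(d) == ncol(d), "d must be a square matrix")
  labs <- rownames(d) %||% paste0("t", seq_len(nrow(d)))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste0(formatC(substr(labs[i], 1, 10), width = -10),
                      paste(sprintf("%.6f", d[i, ]), collapse = "  ")), con)
  }
  invisible(file)
}

#' @rdname writePhylipDist
#' @export
readPhylipDist <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1]))
  stopIfNot(!is.na(n) && length(lines) >= n + 1, "malformed PHYLIP distance file")
  labs <- character(n)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i + 1]), "[[:space:]]+")[[1]]
    labs[i] <- f[1]
    vals <- as.numeric(f[-1])
    stopIfNot(length(vals) == n, "malformed PHYLIP distance row")
    d[i, ] <- vals
  }
  dimnames(d) <- list(labs, labs)
  d
}

#' Export a union graph as JSON
#'
#' Writes the composite-node member table and the homological similarity
#' matrix.
#'
#' @param u a [UnionGraph-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
exportUnionGraph <- function(u, file) {
  mem <- compositeNodes(u)
  obj <- list(
    pathway_id = u@pathwayId,
    anchor_organism = u@anchorOrganism,
    organisms = colnames(mem),
    composite_nodes = lapply(seq_len(nrow(mem)), function(i) {
      as.list(ifelse(is.na(mem[i, ]), "", mem[i, ]))
    }),
    H = apply(homologicalMatrix(u), 1, as.list, simplify = FALSE)
  )
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Export module mappings as JSON
#'
#' @param mm a [ModuleMapping-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
exportModuleMapping <- function(mm, file) {
  obj <- list(
    pathway_id = mm@pathwayId,
    clusters = lapply(moduleClusters(mm), function(cl) {
      lapply(cl, function(m) {
        list(organism_id = m$organismId, nodes = as.list(m$nodes),
             edges = apply(m$edges, 1, as.list, simplify = FALSE))
      })
    })
  )
  jsonlite::write_json(obj, file, auto_unbox = TRUE)
  invisible(file)
}
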