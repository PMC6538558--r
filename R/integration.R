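# Multi-model integration: provenance-merging deduplication by canonical
# key, context-aware contradiction detection, configurable resolution, and
# graph export. The central rule, following the context-oriented design of
# the format, is that only context-identical signed opposites conflict:
# the conflict signature includes anatomy (inside the entity keys), the
# environmental-context set and the species, so events that differ in any
# context are simply distinct units, never contradictions.

.kuList <- function(x) {
  if (is(x, "UnifiedModel")) return(x@units)
  if (is(x, "CodamlDocument")) return(x@knowledgeUnits)
  stopifnot(is.list(x))
  x
}

.isUndirectedFamily <- function(p) predicateFamily(p) == "undirected link"

# conflict bucket: species + environmental contexts + unordered entity pair
.conflictBucket <- function(ku) {
  s <- canonicalKey(ku@subject)
  o <- canonicalKey(ku@object)
  env <- paste(sort(vapply(ku@environmentalContexts, canonicalKey,
                           character(1))), collapse = ";")
  paste(ku@species, env, min(s, o), max(s, o), sep = " :: ")
}

# do two units (already in one bucket) form a contradictory pair?
.pairConflicts <- function(a, b) {
  if (!isContradictory(a@predicate, b@predicate)) return(FALSE)
  sa <- canonicalKey(a@subject); oa <- canonicalKey(a@object)
  sb <- canonicalKey(b@subject); ob <- canonicalKey(b@object)
  if (sa == sb && oa == ob) return(TRUE)
  # symmetric matching only when both predicates are non-causal
  .isUndirectedFamily(a@predicate) && .isUndirectedFamily(b@predicate) &&
    sa == ob && oa == sb
}

#' Detect context-identical contradictory associations
#'
#' Groups knowledge units that share a conflict signature — subject, object
#' (including each entity's anatomical context), environmental-context set
#' and species — and whose predicates are contradictory under
#' \code{\link{isContradictory}}. Direction matters: A to B and B to A are
#' distinct signatures, except that pairs of non-causal (undirected-family)
#' predicates match symmetrically. Groups are the connected components of
#' the pairwise-contradiction graph within a signature.
#'
#' @param units a list of \linkS4class{KnowledgeUnit},
#'   a \linkS4class{CodamlDocument}, or a \linkS4class{UnifiedModel}.
#' @return list of \linkS4class{ConflictGroup}.
#' @export
findConflicts <- function(units) {
  units <- .kuList(units)
  if (!length(units)) return(list())
  buckets <- split(seq_along(units),
                   vapply(units, .conflictBucket, character(1)))
  out <- list()
  for (bname in names(buckets)) {
    idx <- buckets[[bname]]
    if (length(idx) < 2L) next
    # pairwise scan within the bucket; union-find for components
    parent <- seq_along(idx)
    findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    pairs <- matrix(character(0), ncol = 2)
    conflicted <- logical(length(idx))
    for (i in seq_along(idx)[-length(idx)]) {
      for (j in seq.int(i + 1L, length(idx))) {
        if (.pairConflicts(units[[idx[i]]], units[[idx[j]]])) {
          pairs <- rbind(pairs, c(canonicalKey(units[[idx[i]]]),
                                  canonicalKey(units[[idx[j]]])))
          conflicted[i] <- conflicted[j] <- TRUE
          ri <- findRoot(i); rj <- findRoot(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
    if (!any(conflicted)) next
    roots <- vapply(seq_along(idx), findRoot, integer(1))
    for (r in unique(roots[conflicted])) {
      members <- idx[roots == r & conflicted]
      memberKeys <- vapply(units[members], canonicalKey, character(1))
      gp <- pairs[pairs[, 1] %in% memberKeys | pairs[, 2] %in% memberKeys, ,
                  drop = FALSE]
      out[[length(out) + 1L]] <-
        new("ConflictGroup", memberKeys = memberKeys, signature = bname,
            pairs = gp, status = "open", strategy = character(0))
    }
  }
  # deterministic ledger order
  if (length(out))
    out <- out[order(vapply(out, function(g) g@signature, character(1)),
                     vapply(out, function(g) g@memberKeys[1], character(1)))]
  out
}

#' Integrate several source models into one unified model
#'
#' Deduplicates knowledge units across source documents by canonical key
#' (same triple, environmental contexts and species): duplicates are
#' collapsed into one unit whose reference list is the concatenation of all
#' contributed references, so no provenance is lost. Evidence scores of
#' merged duplicates are logged per source; the merged unit carries the
#' maximum score when all contributions share one score type, and mixed
#' discrete/continuous scores are kept side by side in the log without
#' comparison. The conflict ledger is populated with
#' \code{\link{findConflicts}}.
#'
#' @param models a named list of \linkS4class{CodamlDocument} (names are
#'   the source-model names; unnamed sources are called "model1", ...), or
#'   a single document.
#' @param strict validation strictness applied to each source before
#'   integration; any error-severity issue aborts with a per-source report.
#' @return a \linkS4class{UnifiedModel}.
#' @export
integrateModels <- function(models, strict = FALSE) {
  if (is(models, "CodamlDocument")) models <- list(models)
  stopifnot(is.list(models), length(models) >= 1L)
  nm <- names(models)
  if (is.null(nm)) nm <- rep("", length(models))
  nm[!nzchar(nm)] <- paste0("model", seq_along(models))[!nzchar(nm)]
  for (i in seq_along(models)) {
    issues <- validateDocument(models[[i]], strict = strict)
    .stopOnIssues(issues, paste0("source '", nm[i], "' is invalid"))
  }
  units <- list(); keys <- character(0)
  provenance <- stats::setNames(vector("list", length(models)), nm)
  log <- list()
  for (i in seq_along(models)) {
    for (ku in models[[i]]@knowledgeUnits) {
      k <- canonicalKey(ku)
      provenance[[i]] <- unique(c(provenance[[i]], k))
      if (length(ku@evidenceScore))
        log[[length(log) + 1L]] <-
          data.frame(key = k, source = nm[i], value = ku@evidenceScore,
                     type = ku@evidenceType, stringsAsFactors = FALSE)
      pos <- match(k, keys)
      if (is.na(pos)) {
        units[[length(units) + 1L]] <- ku
        keys <- c(keys, k)
      } else {
        merged <- units[[pos]]
        merged@references <- c(merged@references, ku@references)
        if (length(ku@evidenceScore)) {
          if (!length(merged@evidenceScore)) {
            merged@evidenceScore <- ku@evidenceScore
            merged@evidenceType <- ku@evidenceType
          } else if (identical(merged@evidenceType, ku@evidenceType)) {
            merged@evidenceScore <- max(merged@evidenceScore, ku@evidenceScore)
          } # mixed types: kept side by side in the evidence log only
        }
        units[[pos]] <- merged
      }
    }
  }
  evidenceLog <- if (length(log)) do.call(rbind, log) else
    new("UnifiedModel")@evidenceLog
  new("UnifiedModel", units = units, keys = keys, provenance = provenance,
      conflicts = findConflicts(units), evidenceLog = evidenceLog,
      suppressed = character(0))
}

#' Convert a unified model back to a document
#'
#' Suppressed units (see \code{\link{resolveConflicts}}) are excluded.
#'
#' @param model a \linkS4class{UnifiedModel}.
#' @param creationDate optional ISO date text for the document metadata.
#' @return a \linkS4class{CodamlDocument}.
#' @export
asDocument <- function(model, creationDate = NULL) {
  stopifnot(is(model, "UnifiedModel"))
  keep <- !(model@keys %in% model@suppressed)
  CodamlDocument(model@units[keep], creationDate = creationDate)
}

#' Resolve the conflict ledger of a unified model
#'
#' Applies one resolution strategy to every open conflict group:
#' \describe{
#'   \item{keep_all_flagged}{No unit changes; groups are marked resolved so
#'     downstream analysis sees the flags. The default, and the only
#'     strategy that asserts nothing beyond what the sources say.}
#'   \item{prefer_higher_evidence}{Retains the member with the highest
#'     evidence score and suppresses the rest. Groups with missing scores,
#'     mixed discrete/continuous score types, or ties keep all members and
#'     stay open.}
#'   \item{generalize_to_lca}{Replaces the members by a single unit whose
#'     predicate is the least common ancestor of the member predicates
#'     (e.g. activation by increase vs inhibition by increase generalizes
#'     to directed link) and whose references are the union of the member
#'     references. Groups whose predicates span both root families have no
#'     LCA and are left open with a warning.}
#'   \item{context_split}{A reporting no-op: flags the groups, which by
#'     construction lack any distinguishing context, for manual context
#'     curation; units are unchanged and groups stay open.}
#' }
#'
#' @param model a \linkS4class{UnifiedModel} with a populated ledger.
#' @param strategy one of the four strategy ids above.
#' @return the updated \linkS4class{UnifiedModel}.
#' @export
resolveConflicts <- function(model,
                             strategy = c("keep_all_flagged",
                                          "prefer_higher_evidence",
                                          "generalize_to_lca",
                                          "context_split")) {
  stopifnot(is(model, "UnifiedModel"))
  strategy <- match.arg(strategy)
  for (gi in seq_along(model@conflicts)) {
    g <- model@conflicts[[gi]]
    if (g@status != "open") next
    if (strategy == "keep_all_flagged") {
      g@status <- "resolved"; g@strategy <- strategy
    } else if (strategy == "prefer_higher_evidence") {
      pos <- match(g@memberKeys, model@keys)
      scores <- lapply(model@units[pos], function(u)
        if (length(u@evidenceScore)) u else NULL)
      vals <- vapply(model@units[pos], function(u)
        if (length(u@evidenceScore)) u@evidenceScore else NA_real_, numeric(1))
      types <- vapply(model@units[pos], function(u)
        if (length(u@evidenceType)) u@evidenceType else NA_character_,
        character(1))
      if (anyNA(vals) || length(unique(types)) != 1L ||
          sum(vals == max(vals)) > 1L) {
        # missing, mixed-type or tied evidence: keep all, leave open
        model@conflicts[[gi]] <- g
        next
      }
      losers <- g@memberKeys[vals < max(vals)]
      model@suppressed <- unique(c(model@suppressed, losers))
      g@status <- "resolved"; g@strategy <- strategy
    } else if (strategy == "generalize_to_lca") {
      pos <- match(g@memberKeys, model@keys)
      preds <- vapply(model@units[pos], function(u) u@predicate, character(1))
      lca <- Reduce(function(a, b)
        if (is.null(a) || is.null(b)) NULL else leastCommonAncestor(a, b),
        preds)
      if (is.null(lca)) {
        warning("conflict group ", gi, " spans both root families; no LCA, ",
                "left open", call. = FALSE)
        model@conflicts[[gi]] <- g
        next
      }
      proto <- model@units[[pos[1]]]
      proto@predicate <- lca
      proto@predicateInReference <- character(0)
      proto@references <- do.call(c, lapply(model@units[pos],
                                            function(u) u@references))
      proto@evidenceScore <- numeric(0)
      proto@evidenceType <- character(0)
      newKey <- canonicalKey(proto)
      keep <- !(model@keys %in% g@memberKeys)
      units <- model@units[keep]; keys <- model@keys[keep]
      at <- match(newKey, keys)
      if (is.na(at)) {
        units[[length(units) + 1L]] <- proto
        keys <- c(keys, newKey)
      } else {
        units[[at]]@references <- c(units[[at]]@references, proto@references)
      }
      model@units <- units; model@keys <- keys
      model@provenance <- lapply(model@provenance, function(ks)
        unique(ifelse(ks %in% g@memberKeys, newKey, ks)))
      g@status <- "resolved"; g@strategy <- strategy
    } else if (strategy == "context_split") {
      message("conflict group ", gi, " (", length(g@memberKeys),
              " units) lacks distinguishing anatomical or environmental ",
              "context; manual context curation required")
    }
    model@conflicts[[gi]] <- g
  }
  model
}

.graphFromUnits <- function(units, explodeComplexes = FALSE) {
  if (!length(units)) {
    return(igraph::make_empty_graph(directed = TRUE))
  }
  edges <- list()
  nodes <- list()
  addNode <- function(id, label) {
    if (is.null(nodes[[id]])) nodes[[id]] <<- label
    id
  }
  nodeFor <- function(entity) {
    if (!explodeComplexes) {
      addNode(canonicalKey(entity), .entityLabel(entity))
    } else {
      vapply(entity@cores, function(core) {
        e1 <- new("Entity", cores = list(core), anatomy = entity@anatomy)
        addNode(canonicalKey(e1), .entityLabel(e1))
      }, character(1))
    }
  }
  for (ku in units) {
    from <- nodeFor(ku@subject)
    to <- nodeFor(ku@object)
    env <- paste(vapply(ku@environmentalContexts,
                        function(x) paste0(x@contextType, "/", x@contextId),
                        character(1)), collapse = ";")
    for (f in from) for (t in to)
      edges[[length(edges) + 1L]] <- data.frame(
        from = f, to = t, predicate = ku@predicate,
        environmentalContexts = env, species = ku@species,
        evidenceScore = if (length(ku@evidenceScore)) ku@evidenceScore else
          NA_real_,
        undirected = .isUndirectedFamily(ku@predicate),
        stringsAsFactors = FALSE)
  }
  vertices <- data.frame(name = names(nodes),
                         label = unlist(nodes, use.names = FALSE),
                         stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(do.call(rbind, edges), directed = TRUE,
                                vertices = vertices)
}

#' @describeIn toGraph graph of a document's units.
#' @export
setMethod("toGraph", "CodamlDocument", function(x, explodeComplexes = FALSE)
  .graphFromUnits(x@knowledgeUnits, explodeComplexes))

#' @describeIn toGraph graph of the non-suppressed units of a unified model.
#' @export
setMethod("toGraph", "UnifiedModel", function(x, explodeComplexes = FALSE)
  .graphFromUnits(x@units[!(x@keys %in% x@suppressed)], explodeComplexes))

#' Export to GraphML
#'
#' Writes the \code{\link{toGraph}} multigraph (typed node and edge
#' attributes) in GraphML via \pkg{igraph}.
#'
#' @param x a CodamlDocument or UnifiedModel.
#' @param file output path.
#' @param explodeComplexes see \code{\link{toGraph}}.
#' @return invisibly, the graph.
#' @export
writeGraphML <- function(x, file, explodeComplexes = FALSE) {
  g <- toGraph(x, explodeComplexes)
  igraph::write_graph(g, file, format = "graphml")
  invisible(g)
}
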