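#' Canonical key of a model object
#'
#' Deterministic, delimiter-escaped string key. For a
#' \linkS4class{KnowledgeUnit} the key covers subject, predicate, object,
#' environmental contexts and species — not references, the raw predicate
#' text or the evidence score — so two units get equal keys exactly when
#' they are duplicates eligible for provenance merging.
#'
#' @param x an EntityCore, Entity, EnvironmentalContext, KnowledgeUnit or
#'   AnatomicalContext.
#' @return character(1) opaque key.
#' @export
setGeneric("canonicalKey", function(x) standardGeneric("canonicalKey"))

#' Knowledge units held by a container
#'
#' @param x a CodamlDocument or UnifiedModel.
#' @return list of \linkS4class{KnowledgeUnit}.
#' @export
setGeneric("knowledgeUnits", function(x) standardGeneric("knowledgeUnits"))

#' @rdname accessors
#' @export
setGeneric("coreId", function(x) standardGeneric("coreId"))
#' @rdname accessors
#' @export
setGeneric("coreType", function(x) standardGeneric("coreType"))
#' @rdname accessors
#' @export
setGeneric("moleculeType", function(x) standardGeneric("moleculeType"))
#' @rdname accessors
#' @export
setGeneric("isoform", function(x) standardGeneric("isoform"))
#' @rdname accessors
#' @export
setGeneric("modifications", function(x) standardGeneric("modifications"))
#' @rdname accessors
#' @export
setGeneric("cores", function(x) standardGeneric("cores"))
#' @rdname accessors
#' @export
setGeneric("anatomy", function(x) standardGeneric("anatomy"))
#' @rdname accessors
#' @export
setGeneric("kuSubject", function(x) standardGeneric("kuSubject"))
#' @rdname accessors
#' @export
setGeneric("kuObject", function(x) standardGeneric("kuObject"))
#' @rdname accessors
#' @export
setGeneric("predicate", function(x) standardGeneric("predicate"))
#' @rdname accessors
#' @export
setGeneric("environmentalContexts",
           function(x) standardGeneric("environmentalContexts"))
#' @rdname accessors
#' @export
setGeneric("references", function(x) standardGeneric("references"))
#' @rdname accessors
#' @export
setGeneric("species", function(x) standardGeneric("species"))
#' @rdname accessors
#' @export
setGeneric("evidenceScore", function(x) standardGeneric("evidenceScore"))

#' Export a model or document as a directed multigraph
#'
#' One node per distinct (entity-core multiset, anatomical context) pair and
#' one edge per knowledge unit, labelled with predicate, environmental
#' contexts and evidence. Undirected-family predicates produce a single edge
#' flagged \code{undirected = TRUE}.
#'
#' @param x a CodamlDocument or UnifiedModel.
#' @param explodeComplexes if TRUE, multi-core entities are exploded into one
#'   node per core instead of one complex node.
#' @return an \pkg{igraph} directed graph.
#' @export
setGeneric("toGraph", function(x, explodeComplexes = FALSE)
  standardGeneric("toGraph"))
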