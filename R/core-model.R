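# Constructors enforce the domain invariants at construction time
# (vocabulary errors, specification-on-non-gene errors, empty-core errors);
# class validity only guards slot shapes so that parsed documents can hold
# rule-violating content for the validator to report (see validate.R).

.escKey <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  for (p in c("|", "&", "@", ";", ">", ",", "/"))
    x <- gsub(p, sprintf("%%%02X", utf8ToInt(p)), x, fixed = TRUE)
  x
}

#' Construct a MolecularSpecification
#'
#' @param moleculeType "DNA", "RNA", "protein" or "unspecified".
#' @param isoform optional isoform accession (transcript or protein level);
#'   permitted only for moleculeType "RNA" or "protein".
#' @param modifications character vector of modification labels; normalized
#'   via the shipped table (e.g. "phosphorylation" -> "phosphorylated"),
#'   lowercased, deduplicated and sorted.
#' @return a \linkS4class{MolecularSpecification}.
#' @examples
#' MolecularSpecification("protein", isoform = "ENSP00000312236",
#'                        modifications = c("methylated", "phosphorylated"))
#' @export
MolecularSpecification <- function(moleculeType = "unspecified",
                                   isoform = NULL,
                                   modifications = character(0)) {
  if (!moleculeType %in% .MOLECULE_TYPES)
    stop("specification error: unknown molecule type ", deparse(moleculeType),
         call. = FALSE)
  isoform <- as.character(isoform %||% character(0))
  if (length(isoform) && !moleculeType %in% c("RNA", "protein"))
    stop("specification error: isoform requires molecule type RNA or protein, ",
         "not ", deparse(moleculeType), call. = FALSE)
  new("MolecularSpecification", moleculeType = moleculeType,
      isoform = isoform,
      modifications = .normalizeModifications(modifications))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an EntityCore
#'
#' @param coreId namespaced identifier (or free-text label for
#'   coreType "user_defined").
#' @param coreType one of gene, compound, biological_process,
#'   molecular_function, phenotype, user_defined.
#' @param moleculeType,isoform,modifications convenience arguments building
#'   a \linkS4class{MolecularSpecification}; only allowed for gene cores.
#' @param spec an explicit MolecularSpecification (alternative to the
#'   convenience arguments).
#' @return an \linkS4class{EntityCore}.
#' @examples
#' EntityCore("ENSG00000012048", "gene", moleculeType = "protein",
#'            isoform = "ENSP00000312236")
#' @export
EntityCore <- function(coreId, coreType = "gene", moleculeType = NULL,
                       isoform = NULL, modifications = NULL, spec = NULL) {
  if (!is.character(coreId) || length(coreId) != 1L || is.na(coreId) ||
      !nzchar(coreId))
    stop("structure error: coreId must be a non-empty string", call. = FALSE)
  if (!coreType %in% .CORE_TYPES)
    stop("structure error: unknown core type ", deparse(coreType),
         call. = FALSE)
  if (is.null(spec) &&
      (!is.null(moleculeType) || !is.null(isoform) || !is.null(modifications)))
    spec <- MolecularSpecification(moleculeType %||% "unspecified", isoform,
                                   modifications %||% character(0))
  if (!is.null(spec) && coreType != "gene")
    stop("specification error: molecular specification is permitted only on ",
         "gene cores, not ", deparse(coreType), call. = FALSE)
  new("EntityCore", coreId = coreId, coreType = coreType, spec = spec)
}

#' Construct an AnatomicalContext
#'
#' @param organ,tissue,cell optional identifiers, broad to narrow.
#' @return an \linkS4class{AnatomicalContext}; with no arguments, the
#'   distinguished "unspecified" context.
#' @examples
#' AnatomicalContext(organ = "D010053", cell = "D006107")
#' @export
AnatomicalContext <- function(organ = NULL, tissue = NULL, cell = NULL) {
  new("AnatomicalContext",
      organ = as.character(organ %||% character(0)),
      tissue = as.character(tissue %||% character(0)),
      cell = as.character(cell %||% character(0)))
}

#' Construct an Entity
#'
#' @param cores an \linkS4class{EntityCore} or non-empty list of them; a
#'   multi-core entity represents a complex or a multi-participant side of
#'   a reaction.
#' @param anatomy an \linkS4class{AnatomicalContext}.
#' @return an \linkS4class{Entity}.
#' @export
Entity <- function(cores, anatomy = AnatomicalContext()) {
  if (is(cores, "EntityCore")) cores <- list(cores)
  if (!length(cores))
    stop("structure error: an entity needs at least one core", call. = FALSE)
  if (!all(vapply(cores, is, logical(1), "EntityCore")))
    stop("structure error: cores must be EntityCore objects", call. = FALSE)
  new("Entity", cores = cores, anatomy = anatomy)
}

#' Construct an EnvironmentalContext
#'
#' @param contextType one of phenotype, cell_line, drug_treatment,
#'   siRNA_treatment, herb_treatment, user_defined.
#' @param contextId namespaced identifier.
#' @return an \linkS4class{EnvironmentalContext}.
#' @examples
#' EnvironmentalContext("phenotype", "C0678222")
#' @export
EnvironmentalContext <- function(contextType, contextId) {
  if (!contextType %in% .ENV_CONTEXT_TYPES)
    stop("structure error: unknown environmental context type ",
         deparse(contextType), call. = FALSE)
  if (!is.character(contextId) || length(contextId) != 1L || !nzchar(contextId))
    stop("structure error: contextId must be a non-empty string",
         call. = FALSE)
  new("EnvironmentalContext", contextType = contextType, contextId = contextId)
}

#' Construct a Reference
#'
#' @param referenceType one of database, literature, wet_experiment,
#'   user_defined.
#' @param name exact name of the reference model (e.g. "KEGG", "PubMed").
#' @param description,recordId,version,acquisitionDate optional text.
#' @return a \linkS4class{Reference}.
#' @export
Reference <- function(referenceType, name, description = NULL,
                      recordId = NULL, version = NULL,
                      acquisitionDate = NULL) {
  if (!referenceType %in% .REFERENCE_TYPES)
    stop("structure error: unknown reference type ", deparse(referenceType),
         call. = FALSE)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("structure error: reference name must be a non-empty string",
         call. = FALSE)
  new("Reference", referenceType = referenceType, name = name,
      description = as.character(description %||% character(0)),
      recordId = as.character(recordId %||% character(0)),
      version = as.character(version %||% character(0)),
      acquisitionDate = as.character(acquisitionDate %||% character(0)))
}

#' Construct a KnowledgeUnit
#'
#' Builds and validates one atomic biological event: a triple plus its
#' additional information. All structural invariants are enforced here: the
#' predicate must be one of the 11 controlled terms (a raw term such as
#' "up-regulate" belongs in \code{predicateInReference}), entities must
#' have at least one core, molecular specifications are only allowed on
#' gene cores, at least one reference is required, and an evidence score
#' must carry its "discrete"/"continuous" type tag.
#'
#' @param subject,object an \linkS4class{Entity} (or a single
#'   \linkS4class{EntityCore}, which is wrapped).
#' @param predicate one of \code{\link{predicateTerms}()}.
#' @param object the object entity.
#' @param predicateInReference optional raw relation text from the source.
#' @param environmentalContexts list of
#'   \linkS4class{EnvironmentalContext}; empty means normal condition.
#' @param species single species identifier or text.
#' @param references non-empty list of \linkS4class{Reference} (a single
#'   Reference is wrapped).
#' @param evidenceScore optional numeric score.
#' @param evidenceType "discrete" or "continuous"; required with a score.
#' @return a validated \linkS4class{KnowledgeUnit}.
#' @examples
#' brca1 <- EntityCore("ENSG00000012048", "gene", moleculeType = "protein",
#'                     isoform = "ENSP00000312236")
#' bap1 <- EntityCore("unverified:BAP1", "gene", moleculeType = "protein")
#' KnowledgeUnit(brca1, "undirected link", bap1,
#'               predicateInReference = "physically interact",
#'               references = Reference("database", "BioGrid"))
#' @export
KnowledgeUnit <- function(subject, predicate, object,
                          predicateInReference = NULL,
                          environmentalContexts = list(),
                          species = "Homo sapiens",
                          references = list(),
                          evidenceScore = NULL, evidenceType = NULL) {
  if (is(subject, "EntityCore")) subject <- Entity(subject)
  if (is(object, "EntityCore")) object <- Entity(object)
  if (!is(subject, "Entity") || !is(object, "Entity"))
    stop("structure error: subject and object must be Entity objects",
         call. = FALSE)
  if (!length(subject@cores) || !length(object@cores))
    stop("structure error: subject and object need at least one core",
         call. = FALSE)
  if (!is.character(predicate) || length(predicate) != 1L ||
      !predicate %in% predicateTerms())
    stop("vocabulary error: predicate must be one of the 11 controlled ",
         "terms, got ", deparse(predicate), call. = FALSE)
  if (is(environmentalContexts, "EnvironmentalContext"))
    environmentalContexts <- list(environmentalContexts)
  if (is(references, "Reference")) references <- list(references)
  if (!length(references))
    stop("structure error: at least one reference is required", call. = FALSE)
  score <- as.numeric(evidenceScore %||% numeric(0))
  etype <- as.character(evidenceType %||% character(0))
  if (length(score) && (!length(etype) || !etype %in% .EVIDENCE_TYPES))
    stop("structure error: evidenceScore requires evidenceType ",
         "\"discrete\" or \"continuous\"", call. = FALSE)
  # environmental contexts are a set: canonical order, no duplicates
  if (length(environmentalContexts)) {
    ek <- vapply(environmentalContexts, canonicalKey, character(1))
    environmentalContexts <- environmentalContexts[order(ek)][!duplicated(sort(ek))]
  }
  ku <- new("KnowledgeUnit", subject = subject, predicate = predicate,
            object = object,
            predicateInReference = as.character(predicateInReference %||%
                                                  character(0)),
            environmentalContexts = environmentalContexts,
            species = species, references = references,
            evidenceScore = score, evidenceType = etype)
  ku
}

#' Construct a CodamlDocument
#'
#' @param knowledgeUnits a \linkS4class{KnowledgeUnit} or list of them.
#' @param formatVersion dialect version string.
#' @param creationDate optional ISO date text; recorded in the document so
#'   serialization stays deterministic.
#' @return a \linkS4class{CodamlDocument}.
#' @export
CodamlDocument <- function(knowledgeUnits = list(), formatVersion = "1.0",
                           creationDate = NULL) {
  if (is(knowledgeUnits, "KnowledgeUnit"))
    knowledgeUnits <- list(knowledgeUnits)
  new("CodamlDocument", knowledgeUnits = knowledgeUnits,
      formatVersion = formatVersion,
      creationDate = as.character(creationDate %||% character(0)))
}

## -------- canonical keys --------

#' @describeIn canonicalKey key over coreId, coreType and the full
#'   molecular specification (type, isoform, sorted modifications).
#' @export
setMethod("canonicalKey", "EntityCore", function(x) {
  if (is.null(x@spec)) {
    mt <- ""; iso <- ""; mods <- ""
  } else {
    mt <- x@spec@moleculeType
    iso <- if (length(x@spec@isoform)) x@spec@isoform else ""
    mods <- paste(x@spec@modifications, collapse = ",")
  }
  paste(.escKey(x@coreId), x@coreType, mt, .escKey(iso), .escKey(mods),
        sep = "|")
})

#' @describeIn canonicalKey organ/tissue/cell slots, empty slots as "".
#' @export
setMethod("canonicalKey", "AnatomicalContext", function(x) {
  slotval <- function(s) if (length(s)) .escKey(s) else ""
  paste(slotval(x@organ), slotval(x@tissue), slotval(x@cell), sep = "|")
})

#' @describeIn canonicalKey sorted core keys (multiset semantics) plus the
#'   anatomy key.
#' @export
setMethod("canonicalKey", "Entity", function(x) {
  ck <- sort(vapply(x@cores, canonicalKey, character(1)))
  paste0(paste(ck, collapse = "&"), "@", canonicalKey(x@anatomy))
})

#' @describeIn canonicalKey contextType/contextId pair.
#' @export
setMethod("canonicalKey", "EnvironmentalContext", function(x)
  paste(x@contextType, .escKey(x@contextId), sep = "/"))

#' @describeIn canonicalKey duplicate-eligibility key: subject, predicate,
#'   object, environmental-context set and species; excludes references,
#'   predicate-in-reference and evidence score.
#' @export
setMethod("canonicalKey", "KnowledgeUnit", function(x) {
  env <- sort(vapply(x@environmentalContexts, canonicalKey, character(1)))
  paste(canonicalKey(x@subject), .escKey(x@predicate), canonicalKey(x@object),
        paste(env, collapse = ";"), .escKey(x@species), sep = ">")
})

#' Canonical deduplication key of a knowledge unit
#'
#' Functional alias for \code{canonicalKey} on a
#' \linkS4class{KnowledgeUnit}: two units get equal keys exactly when they
#' describe the same event (same triple, environmental contexts and
#' species) and differ at most in provenance, raw predicate text or
#' evidence score.
#'
#' @param ku a \linkS4class{KnowledgeUnit}.
#' @return character(1).
#' @export
kuCanonicalKey <- function(ku) canonicalKey(ku)

## -------- equality --------

#' Exact equality of two entity cores
#'
#' True iff coreId, coreType, molecule type, isoform and modification set
#' all match. The match is exact, not subsumption-aware: a core with a
#' stated isoform and one without are unequal, and a modified molecule is
#' distinguished from its unmodified form. Granularity-tolerant matching is
#' available only as an explicit integration strategy, never silently.
#'
#' @param a,b \linkS4class{EntityCore} objects.
#' @return logical(1).
#' @examples
#' a <- EntityCore("ENSG00000012048", "gene", moleculeType = "protein",
#'                 isoform = "ENSP00000312236")
#' b <- EntityCore("ENSG00000012048", "gene", moleculeType = "protein",
#'                 isoform = "ENSP00000312236",
#'                 modifications = "phosphorylated")
#' entityCoreEquals(a, b)  # FALSE: modification-sensitive
#' @export
entityCoreEquals <- function(a, b) canonicalKey(a) == canonicalKey(b)

#' Equality of two entities
#'
#' True iff the core multisets are equal under
#' \code{\link{entityCoreEquals}} (order-insensitive) and the anatomical
#' contexts agree slot-wise.
#'
#' @param a,b \linkS4class{Entity} objects.
#' @return logical(1).
#' @export
entityEquals <- function(a, b) canonicalKey(a) == canonicalKey(b)

## -------- accessors --------

#' Accessors for model objects
#'
#' Slot accessors for the CODA-ML data model classes.
#'
#' @param x a model object.
#' @name accessors
#' @return the corresponding component.
NULL

#' @rdname accessors
#' @export
setMethod("coreId", "EntityCore", function(x) x@coreId)
#' @rdname accessors
#' @export
setMethod("coreType", "EntityCore", function(x) x@coreType)
#' @rdname accessors
#' @export
setMethod("moleculeType", "EntityCore", function(x)
  if (is.null(x@spec)) NULL else x@spec@moleculeType)
#' @rdname accessors
#' @export
setMethod("isoform", "EntityCore", function(x)
  if (is.null(x@spec) || !length(x@spec@isoform)) NULL else x@spec@isoform)
#' @rdname accessors
#' @export
setMethod("modifications", "EntityCore", function(x)
  if (is.null(x@spec)) character(0) else x@spec@modifications)
#' @rdname accessors
#' @export
setMethod("cores", "Entity", function(x) x@cores)
#' @rdname accessors
#' @export
setMethod("anatomy", "Entity", function(x) x@anatomy)
#' @rdname accessors
#' @export
setMethod("kuSubject", "KnowledgeUnit", function(x) x@subject)
#' @rdname accessors
#' @export
setMethod("kuObject", "KnowledgeUnit", function(x) x@object)
#' @rdname accessors
#' @export
setMethod("predicate", "KnowledgeUnit", function(x) x@predicate)
#' @rdname accessors
#' @export
setMethod("environmentalContexts", "KnowledgeUnit",
          function(x) x@environmentalContexts)
#' @rdname accessors
#' @export
setMethod("references", "KnowledgeUnit", function(x) x@references)
#' @rdname accessors
#' @export
setMethod("species", "KnowledgeUnit", function(x) x@species)
#' @rdname accessors
#' @export
setMethod("evidenceScore", "KnowledgeUnit", function(x)
  if (length(x@evidenceScore))
    structure(x@evidenceScore, type = x@evidenceType) else NULL)
#' @rdname accessors
#' @export
setMethod("knowledgeUnits", "CodamlDocument", function(x) x@knowledgeUnits)
#' @rdname accessors
#' @export
setMethod("knowledgeUnits", "UnifiedModel", function(x) x@units)

## -------- display --------

.coreLabel <- function(core) {
  lab <- core@coreId
  if (!is.null(core@spec)) {
    parts <- core@spec@moleculeType
    if (length(core@spec@isoform)) parts <- c(parts, core@spec@isoform)
    if (length(core@spec@modifications))
      parts <- c(parts, paste(core@spec@modifications, collapse = "/"))
    lab <- paste(c(lab, parts), collapse = ", ")
  }
  lab
}

.entityLabel <- function(e) {
  lab <- paste(vapply(e@cores, .coreLabel, character(1)), collapse = " + ")
  a <- e@anatomy
  slots <- c(a@organ, a@tissue, a@cell)
  if (length(slots)) lab <- paste0(lab, " [", paste(slots, collapse = "/"), "]")
  lab
}

setMethod("show", "EntityCore", function(object)
  cat("EntityCore(", object@coreType, "): ", .coreLabel(object), "\n",
      sep = ""))

setMethod("show", "Entity", function(object)
  cat("Entity: ", .entityLabel(object), "\n", sep = ""))

setMethod("show", "KnowledgeUnit", function(object) {
  cat("KnowledgeUnit\n")
  cat("  subject:   ", .entityLabel(object@subject), "\n", sep = "")
  cat("  predicate: ", object@predicate, "\n", sep = "")
  cat("  object:    ", .entityLabel(object@object), "\n", sep = "")
  if (length(object@environmentalContexts)) {
    ec <- vapply(object@environmentalContexts,
                 function(x) paste0(x@contextType, "/", x@contextId),
                 character(1))
    cat("  contexts:  ", paste(ec, collapse = ", "), "\n", sep = "")
  }
  cat("  species:   ", object@species, " (", length(object@references),
      " reference", if (length(object@references) != 1L) "s", ")\n", sep = "")
})

setMethod("show", "CodamlDocument", function(object)
  cat("CodamlDocument with ", length(object@knowledgeUnits),
      " knowledge unit", if (length(object@knowledgeUnits) != 1L) "s",
      " (format ", object@formatVersion, ")\n", sep = ""))

setMethod("show", "UnifiedModel", function(object) {
  cat("UnifiedModel: ", length(object@units), " units from ",
      length(object@provenance), " source model",
      if (length(object@provenance) != 1L) "s", "\n", sep = "")
  open <- sum(vapply(object@conflicts, function(g) g@status == "open",
                     logical(1)))
  cat("  conflict ledger: ", length(object@conflicts), " group",
      if (length(object@conflicts) != 1L) "s", " (", open, " open)\n",
      sep = "")
})

setMethod("show", "ConflictGroup", function(object)
  cat("ConflictGroup of ", length(object@memberKeys), " units [",
      object@status, "]\n", sep = ""))
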