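#' @import methods
NULL

# Enumerations used by validity checks and validators. Closed sets; the
# predicate vocabulary lives in inst/extdata/predicate_vocab.yaml.
.MOLECULE_TYPES <- c("DNA", "RNA", "protein", "unspecified")
.CORE_TYPES <- c("gene", "compound", "biological_process",
                 "molecular_function", "phenotype", "user_defined")
.ENV_CONTEXT_TYPES <- c("phenotype", "cell_line", "drug_treatment",
                        "siRNA_treatment", "herb_treatment", "user_defined")
.REFERENCE_TYPES <- c("database", "literature", "wet_experiment", "user_defined")
.EVIDENCE_TYPES <- c("discrete", "continuous")

.chr01 <- function(x) is.character(x) && length(x) <= 1L && !anyNA(x)

#' MolecularSpecification: molecule-level refinement of a gene-type core
#'
#' Refines a gene-type entity core with the molecule type (DNA, RNA, protein
#' or unspecified), an optional isoform accession (transcript or protein
#' level) and a possibly empty set of modification labels such as
#' "phosphorylated". Modifications are stored as a canonical (lexicographic,
#' duplicate-free) character vector so that serialization is invariant under
#' input order.
#'
#' @slot moleculeType character(1), one of DNA, RNA, protein, unspecified.
#' @slot isoform character(0) or character(1) isoform accession.
#' @slot modifications character vector of modification labels.
#' @exportClass MolecularSpecification
setClass("MolecularSpecification",
  representation(moleculeType = "character",
                 isoform = "character",
                 modifications = "character"),
  prototype(moleculeType = "unspecified",
            isoform = character(0),
            modifications = character(0)),
  validity = function(object) {
    msg <- character(0)
    if (length(object@moleculeType) != 1L)
      msg <- c(msg, "moleculeType must be a single string")
    if (!.chr01(object@isoform))
      msg <- c(msg, "isoform must be character of length 0 or 1")
    if (anyDuplicated(object@modifications))
      msg <- c(msg, "modifications must not contain duplicates")
    if (length(msg)) msg else TRUE
  })

setClassUnion("MolecularSpecificationOrNULL", c("MolecularSpecification", "NULL"))

#' EntityCore: one identified biological participant
#'
#' A single identified participant: a gene-family molecule (gene, transcript
#' or protein of a coding gene), compound, biological process, molecular
#' function, phenotype, or a user-defined term. Gene-type cores may carry a
#' \linkS4class{MolecularSpecification}.
#'
#' @slot coreId namespaced identifier string (e.g. "ENSG00000012048").
#' @slot coreType one of gene, compound, biological_process,
#'   molecular_function, phenotype, user_defined.
#' @slot spec a \linkS4class{MolecularSpecification} or NULL.
#' @exportClass EntityCore
setClass("EntityCore",
  representation(coreId = "character",
                 coreType = "character",
                 spec = "MolecularSpecificationOrNULL"),
  prototype(coreId = NA_character_, coreType = "gene", spec = NULL),
  validity = function(object) {
    msg <- character(0)
    if (length(object@coreId) != 1L)
      msg <- c(msg, "coreId must be a single string")
    if (length(object@coreType) != 1L)
      msg <- c(msg, "coreType must be a single string")
    if (length(msg)) msg else TRUE
  })

#' AnatomicalContext: the organ/tissue/cell placement of an entity
#'
#' Three ordered, individually optional slots following anatomical
#' containment (organ contains tissue contains cell). The empty context
#' (all three absent) is the distinguished "unspecified" value. Because the
#' context is attached per entity, a knowledge unit whose subject and object
#' carry different contexts represents an inter-cellular (or inter-organ)
#' event.
#'
#' @slot organ character(0) or character(1) MeSH-style identifier.
#' @slot tissue character(0) or character(1).
#' @slot cell character(0) or character(1).
#' @exportClass AnatomicalContext
setClass("AnatomicalContext",
  representation(organ = "character", tissue = "character", cell = "character"),
  prototype(organ = character(0), tissue = character(0), cell = character(0)),
  validity = function(object) {
    for (s in c("organ", "tissue", "cell"))
      if (!.chr01(slot(object, s)))
        return(sprintf("%s must be character of length 0 or 1", s))
    TRUE
  })

#' Entity: one side of a triple
#'
#' One or more entity cores (multi-core entities represent complexes or the
#' multi-participant side of a reaction) plus an anatomical context. Core
#' multiset, not listing order, determines equality.
#'
#' @slot cores list of \linkS4class{EntityCore}.
#' @slot anatomy an \linkS4class{AnatomicalContext}.
#' @exportClass Entity
setClass("Entity",
  representation(cores = "list", anatomy = "AnatomicalContext"),
  prototype(cores = list(), anatomy = new("AnatomicalContext")),
  validity = function(object) {
    if (!all(vapply(object@cores, is, logical(1), "EntityCore")))
      return("cores must be a list of EntityCore objects")
    TRUE
  })

#' EnvironmentalContext: a condition under which an event holds
#'
#' A typed condition (disease phenotype, cell line, drug / siRNA / herb
#' treatment, or user-defined) with its identifier. A knowledge unit with an
#' empty environmental-context set describes the normal, unperturbed
#' condition.
#'
#' @slot contextType one of phenotype, cell_line, drug_treatment,
#'   siRNA_treatment, herb_treatment, user_defined.
#' @slot contextId namespaced identifier string.
#' @exportClass EnvironmentalContext
setClass("EnvironmentalContext",
  representation(contextType = "character", contextId = "character"),
  prototype(contextType = NA_character_, contextId = NA_character_),
  validity = function(object) {
    if (length(object@contextType) != 1L || length(object@contextId) != 1L)
      return("contextType and contextId must be single strings")
    TRUE
  })

#' Reference: provenance of a knowledge unit
#'
#' Describes the reference model a knowledge unit came from: its type
#' (database, literature, wet experiment, user-defined), name, free-text
#' description, record locator, version and acquisition date. Type and name
#' are required; the rest are optional.
#'
#' @slot referenceType character(1).
#' @slot name character(1).
#' @slot description,recordId,version,acquisitionDate character(0) or
#'   character(1).
#' @exportClass Reference
setClass("Reference",
  representation(referenceType = "character", name = "character",
                 description = "character", recordId = "character",
                 version = "character", acquisitionDate = "character"),
  prototype(referenceType = NA_character_, name = NA_character_,
            description = character(0), recordId = character(0),
            version = character(0), acquisitionDate = character(0)),
  validity = function(object) {
    if (length(object@referenceType) != 1L || length(object@name) != 1L)
      return("referenceType and name must be single strings")
    for (s in c("description", "recordId", "version", "acquisitionDate"))
      if (!.chr01(slot(object, s)))
        return(sprintf("%s must be character of length 0 or 1", s))
    TRUE
  })

#' KnowledgeUnit: one atomic biological event
#'
#' A subject-predicate-object triple plus its additional information:
#' environmental contexts, the raw predicate text found in the reference
#' model, species, one or more provenance references, and an optional
#' evidence score tagged discrete or continuous.
#'
#' @slot subject,object \linkS4class{Entity}.
#' @slot predicate character(1), one of the 11 controlled terms.
#' @slot predicateInReference character(0/1) raw relation text.
#' @slot environmentalContexts list of \linkS4class{EnvironmentalContext}.
#' @slot species character(1) identifier or text (e.g. "Homo sapiens").
#' @slot references non-empty list of \linkS4class{Reference}.
#' @slot evidenceScore numeric(0/1).
#' @slot evidenceType character(0/1), "discrete" or "continuous".
#' @exportClass KnowledgeUnit
setClass("KnowledgeUnit",
  representation(subject = "Entity", predicate = "character",
                 object = "Entity", predicateInReference = "character",
                 environmentalContexts = "list", species = "character",
                 references = "list", evidenceScore = "numeric",
                 evidenceType = "character"),
  prototype(predicate = NA_character_, predicateInReference = character(0),
            environmentalContexts = list(), species = NA_character_,
            references = list(), evidenceScore = numeric(0),
            evidenceType = character(0)),
  validity = function(object) {
    msg <- character(0)
    if (length(object@predicate) != 1L)
      msg <- c(msg, "predicate must be a single string")
    if (!all(vapply(object@environmentalContexts, is, logical(1),
                    "EnvironmentalContext")))
      msg <- c(msg, "environmentalContexts must be EnvironmentalContext objects")
    if (!all(vapply(object@references, is, logical(1), "Reference")))
      msg <- c(msg, "references must be Reference objects")
    if (length(object@species) != 1L)
      msg <- c(msg, "species must be a single string")
    if (length(object@evidenceScore) > 1L)
      msg <- c(msg, "evidenceScore must have length 0 or 1")
    if (!.chr01(object@evidenceType))
      msg <- c(msg, "evidenceType must be character of length 0 or 1")
    if (length(msg)) msg else TRUE
  })

#' CodamlDocument: an ordered collection of knowledge units
#'
#' The unit of serialization: an ordered list of knowledge units plus
#' document metadata (format version and an optional creation date).
#'
#' @slot knowledgeUnits list of \linkS4class{KnowledgeUnit}.
#' @slot formatVersion character(1).
#' @slot creationDate character(0/1) ISO date text.
#' @exportClass CodamlDocument
setClass("CodamlDocument",
  representation(knowledgeUnits = "list", formatVersion = "character",
                 creationDate = "character"),
  prototype(knowledgeUnits = list(), formatVersion = "1.0",
            creationDate = character(0)),
  validity = function(object) {
    if (!all(vapply(object@knowledgeUnits, is, logical(1), "KnowledgeUnit")))
      return("knowledgeUnits must be a list of KnowledgeUnit objects")
    if (length(object@formatVersion) != 1L)
      return("formatVersion must be a single string")
    if (!.chr01(object@creationDate))
      return("creationDate must be character of length 0 or 1")
    TRUE
  })

#' ConflictGroup: a set of context-identical contradictory units
#'
#' Units sharing one conflict signature (subject, object, anatomy,
#' environmental contexts, species) among which at least one pair of
#' predicates is contradictory.
#'
#' @slot memberKeys canonical keys of the member units.
#' @slot signature the shared signature string.
#' @slot pairs two-column character matrix of contradictory key pairs.
#' @slot status "open", "resolved" or "suppressed".
#' @slot strategy character(0/1): resolution strategy applied, if any.
#' @exportClass ConflictGroup
setClass("ConflictGroup",
  representation(memberKeys = "character", signature = "character",
                 pairs = "matrix", status = "character",
                 strategy = "character"),
  prototype(memberKeys = character(0), signature = NA_character_,
            pairs = matrix(character(0), ncol = 2), status = "open",
            strategy = character(0)))

#' UnifiedModel: the deduplicated union of several source models
#'
#' Knowledge units from several source documents merged into one model:
#' duplicates (equal canonical keys) are collapsed with their reference
#' lists concatenated, a provenance index records which source contributed
#' which keys, and a conflict ledger lists context-identical contradictory
#' groups.
#'
#' @slot units list of merged \linkS4class{KnowledgeUnit}.
#' @slot keys canonical key per unit (parallel to units).
#' @slot provenance named list: source name -> contributed keys.
#' @slot conflicts list of \linkS4class{ConflictGroup}.
#' @slot evidenceLog data.frame (key, source, value, type) of all evidence
#'   scores seen during merging.
#' @slot suppressed keys suppressed by a resolution strategy.
#' @exportClass UnifiedModel
setClass("UnifiedModel",
  representation(units = "list", keys = "character", provenance = "list",
                 conflicts = "list", evidenceLog = "data.frame",
                 suppressed = "character"),
  prototype(units = list(), keys = character(0), provenance = list(),
            conflicts = list(),
            evidenceLog = data.frame(key = character(0), source = character(0),
                                     value = numeric(0), type = character(0),
                                     stringsAsFactors = FALSE),
            suppressed = character(0)),
  validity = function(object) {
    if (length(object@units) != length(object@keys))
      return("units and keys must be parallel")
    if (anyDuplicated(object@keys))
      return("no two units may share a canonical key")
    TRUE
  })

#' GeneratorConfig: parameters of the synthetic-corpus generator
#'
#' Fully determines (together with the seed) a corpus of source documents
#' with planted duplicates and contradictions and its ground truth.
#'
#' @slot nModels number of source documents.
#' @slot kusPerModel base knowledge units per document.
#' @slot duplicateRate fraction of base units duplicated into another model.
#' @slot contradictions number k of planted contradiction pairs.
#' @slot pAnatomy probability an entity carries an anatomical context.
#' @slot pEnvironment probability a unit carries an environmental context.
#' @slot nGenes,nCompounds entity-pool sizes.
#' @slot seed integer random seed.
#' @exportClass GeneratorConfig
setClass("GeneratorConfig",
  representation(nModels = "integer", kusPerModel = "integer",
                 duplicateRate = "numeric", contradictions = "integer",
                 pAnatomy = "numeric", pEnvironment = "numeric",
                 nGenes = "integer", nCompounds = "integer", seed = "integer"),
  prototype(nModels = 3L, kusPerModel = 50L, duplicateRate = 0.1,
            contradictions = 0L, pAnatomy = 0.5, pEnvironment = 0.3,
            nGenes = 120L, nCompounds = 40L, seed = 1L),
  validity = function(object) {
    p <- c(object@duplicateRate, object@pAnatomy, object@pEnvironment)
    if (any(p < 0 | p > 1)) return("rates/probabilities must be in [0, 1]")
    if (object@nModels < 1L || object@kusPerModel < 1L)
      return("nModels and kusPerModel must be positive")
    if (object@contradictions < 0L) return("contradictions must be >= 0")
    TRUE
  })

#' GroundTruth: planted structure of a generated corpus
#'
#' @slot duplicateKeys canonical keys of units planted in more than one
#'   source document.
#' @slot contradictionPairs two-column character matrix of planted
#'   contradictory key pairs.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(duplicateKeys = "character", contradictionPairs = "matrix"),
  prototype(duplicateKeys = character(0),
            contradictionPairs = matrix(character(0), ncol = 2)))
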