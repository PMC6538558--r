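# Seeded synthetic-corpus generator. The seed fully determines the output;
# base units are constructed on pairwise-distinct entity pairs so that the
# only duplicates and contradictions in a corpus are the planted ones, and
# planted-structure recovery is exact by construction.

#' Construct a GeneratorConfig
#'
#' Defaults describe a small multi-model integration scenario: three source
#' models of fifty units each over a shared pool of 120 genes and 40
#' compounds, half of all entities localized anatomically, 30 percent of
#' units carrying an environmental context, a 10 percent duplicate rate
#' across models, and no contradictions unless requested.
#'
#' @param nModels number of source documents.
#' @param kusPerModel base knowledge units per document.
#' @param duplicateRate fraction of base units copied into a second model
#'   with a fresh reference.
#' @param contradictions number k of planted contradiction pairs.
#' @param pAnatomy probability an entity carries an anatomical context.
#' @param pEnvironment probability a unit carries an environmental context.
#' @param nGenes,nCompounds entity-pool sizes.
#' @param seed integer random seed.
#' @return a \linkS4class{GeneratorConfig}.
#' @export
GeneratorConfig <- function(nModels = 3, kusPerModel = 50,
                            duplicateRate = 0.1, contradictions = 0,
                            pAnatomy = 0.5, pEnvironment = 0.3,
                            nGenes = 120, nCompounds = 40, seed = 1) {
  new("GeneratorConfig", nModels = as.integer(nModels),
      kusPerModel = as.integer(kusPerModel),
      duplicateRate = as.numeric(duplicateRate),
      contradictions = as.integer(contradictions),
      pAnatomy = as.numeric(pAnatomy), pEnvironment = as.numeric(pEnvironment),
      nGenes = as.integer(nGenes), nCompounds = as.integer(nCompounds),
      seed = as.integer(seed))
}

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.MOD_POOL <- c("phosphorylated", "methylated", "acetylated", "ubiquitinated")

.randPools <- function(nGenes, nCompounds) {
  list(genes = sprintf("ENSG%011d", sample.int(99999999L, nGenes)),
       compounds = sprintf("CIDs%08d", sample.int(99999999L, nCompounds)),
       organs = sprintf("D%06d", sample.int(999999L, 12L)),
       tissues = sprintf("D%06d", sample.int(999999L, 12L)),
       cells = sprintf("D%06d", sample.int(999999L, 12L)),
       phenotypes = sprintf("C%07d", sample.int(9999999L, 8L)),
       cellLines = sprintf("CLO%07d", sample.int(9999999L, 8L)))
}

.randCore <- function(pools, biopaxSafe = FALSE) {
  kind <- sample(c("gene", "compound"), 1L, prob = c(0.75, 0.25))
  if (kind == "gene") {
    mt <- sample(c("protein", "RNA", "DNA", "unspecified"), 1L,
                 prob = c(0.6, 0.2, 0.1, 0.1))
    iso <- NULL
    if (mt == "protein" && stats::runif(1) < 0.3)
      iso <- sprintf("ENSP%011d", sample.int(99999999L, 1L))
    if (mt == "RNA" && stats::runif(1) < 0.3)
      iso <- sprintf("ENST%011d", sample.int(99999999L, 1L))
    mods <- if (stats::runif(1) < 0.25)
      sample(.MOD_POOL, sample.int(2L, 1L)) else NULL
    EntityCore(sample(pools$genes, 1L), "gene", moleculeType = mt,
               isoform = iso, modifications = mods)
  } else {
    EntityCore(sample(pools$compounds, 1L), "compound")
  }
}

.randAnatomy <- function(pools, pAnatomy) {
  if (stats::runif(1) >= pAnatomy) return(AnatomicalContext())
  organ <- sample(pools$organs, 1L)
  tissue <- if (stats::runif(1) < 0.5) sample(pools$tissues, 1L) else NULL
  cell <- if (stats::runif(1) < 0.5) sample(pools$cells, 1L) else NULL
  AnatomicalContext(organ = organ, tissue = tissue, cell = cell)
}

.randEntity <- function(pools, pAnatomy, biopaxSafe = FALSE) {
  nCores <- if (stats::runif(1) < 0.12) 2L else 1L
  cores <- lapply(seq_len(nCores), function(i) .randCore(pools, biopaxSafe))
  Entity(cores, .randAnatomy(pools, pAnatomy))
}

.randEnvContexts <- function(pools, pEnvironment) {
  if (stats::runif(1) >= pEnvironment) return(list())
  if (stats::runif(1) < 0.5)
    list(EnvironmentalContext("phenotype", sample(pools$phenotypes, 1L)))
  else
    list(EnvironmentalContext("cell_line", sample(pools$cellLines, 1L)))
}

.randKu <- function(pools, pAnatomy, pEnvironment, biopaxSafe = FALSE) {
  terms <- predicateTerms()
  if (biopaxSafe) terms <- setdiff(terms, "missing interaction")
  refNames <- c("KEGG", "BioGrid", "STRING", "PubMed", "in vitro")
  refs <- lapply(seq_len(sample.int(2L, 1L)), function(i)
    Reference(sample(.REFERENCE_TYPES[1:3], 1L), sample(refNames, 1L),
              version = as.character(sample(2015:2019, 1L)),
              acquisitionDate = "2019-01-01"))
  score <- NULL; stype <- NULL
  if (stats::runif(1) < 0.4) {
    score <- round(stats::runif(1), 3); stype <- "continuous"
  } else if (stats::runif(1) < 0.15) {
    score <- sample(1:5, 1L); stype <- "discrete"
  }
  raw <- if (stats::runif(1) < 0.5)
    sample(c("activate", "express", "up-regulate", "inhibit", "bind"), 1L)
  else NULL
  KnowledgeUnit(.randEntity(pools, pAnatomy, biopaxSafe),
                sample(terms, 1L),
                .randEntity(pools, pAnatomy, biopaxSafe),
                predicateInReference = raw,
                environmentalContexts = .randEnvContexts(pools, pEnvironment),
                species = "Homo sapiens",
                references = refs,
                evidenceScore = score, evidenceType = stype)
}

#' A seeded random document
#'
#' Generates a valid document of random knowledge units exercising the full
#' dialect (molecular specifications, multi-core entities, anatomical and
#' environmental contexts, multiple references, both evidence-score types).
#' Used by the round-trip and interchange test suites.
#'
#' @param nKU number of units.
#' @param seed optional integer seed; when given the result is
#'   deterministic and the caller's RNG state is untouched.
#' @param biopaxSafe if TRUE the "missing interaction" predicate (which the
#'   BioPAX subset cannot express) is excluded, keeping the document inside
#'   the lossless interchange subset.
#' @return a \linkS4class{CodamlDocument}.
#' @export
randomDocument <- function(nKU = 5, seed = NULL, biopaxSafe = FALSE) {
  build <- function() {
    pools <- .randPools(60L, 25L)
    CodamlDocument(lapply(seq_len(nKU), function(i)
      .randKu(pools, 0.5, 0.3, biopaxSafe)), creationDate = "2020-01-01")
  }
  if (is.null(seed)) build() else .withSeed(seed, build())
}

.OPPOSITE_PREDICATE <- c(
  "induction" = "reduction", "reduction" = "induction",
  "activation by increase" = "inhibition by increase",
  "inhibition by increase" = "activation by increase",
  "activation by decrease" = "inhibition by decrease",
  "inhibition by decrease" = "activation by decrease",
  "positive correlation" = "negative correlation",
  "negative correlation" = "positive correlation")

#' Generate a synthetic corpus with planted ground truth
#'
#' Emits \code{nModels} source documents whose base units sit on pairwise
#' distinct entity pairs (so the corpus contains no accidental duplicates
#' or contradictions), then plants structure: a fraction
#' \code{duplicateRate} of units is copied into another model with a fresh
#' reference, and \code{contradictions} pairs are planted by adding, for a
#' base unit with a signed predicate, a signature-identical unit with the
#' opposite-signed predicate to another model. The returned
#' \linkS4class{GroundTruth} records the duplicate keys and contradiction
#' key pairs; integration recovers exactly this structure.
#'
#' @param cfg a \linkS4class{GeneratorConfig}.
#' @return list with elements \code{documents} (named list of
#'   \linkS4class{CodamlDocument}) and \code{truth}
#'   (a \linkS4class{GroundTruth}).
#' @export
generateCorpus <- function(cfg = GeneratorConfig()) {
  stopifnot(is(cfg, "GeneratorConfig"))
  validObject(cfg)
  .withSeed(cfg@seed, {
    pools <- .randPools(cfg@nGenes, cfg@nCompounds)
    total <- cfg@nModels * cfg@kusPerModel
    units <- vector("list", total)
    pairKeys <- character(total)
    seen <- character(0)
    for (i in seq_len(total)) {
      repeat {
        ku <- .randKu(pools, cfg@pAnatomy, cfg@pEnvironment)
        s <- canonicalKey(ku@subject); o <- canonicalKey(ku@object)
        pk <- paste(min(s, o), max(s, o), sep = " :: ")
        if (!pk %in% seen) break
      }
      units[[i]] <- ku
      pairKeys[i] <- pk
      seen <- c(seen, pk)
    }
    model <- rep(seq_len(cfg@nModels), each = cfg@kusPerModel)
    extras <- vector("list", cfg@nModels)

    otherModel <- function(m) {
      if (cfg@nModels == 1L) return(m)
      sample(setdiff(seq_len(cfg@nModels), m), 1L)
    }

    # planted duplicates: same key, fresh reference
    nDup <- round(cfg@duplicateRate * total)
    dupIdx <- if (nDup) sample.int(total, nDup) else integer(0)
    duplicateKeys <- character(0)
    for (i in dupIdx) {
      copy <- units[[i]]
      copy@references <- list(Reference("database", "replica-source",
                                        acquisitionDate = "2020-06-01"))
      m <- otherModel(model[i])
      extras[[m]] <- c(extras[[m]], list(copy))
      duplicateKeys <- c(duplicateKeys, canonicalKey(copy))
    }

    # planted contradictions: signature-identical, opposite-signed predicate
    signed <- which(vapply(units, function(u)
      u@predicate %in% names(.OPPOSITE_PREDICATE), logical(1)))
    if (cfg@contradictions > length(signed))
      stop("config error: cannot plant ", cfg@contradictions,
           " contradictions; only ", length(signed),
           " base units have signed predicates", call. = FALSE)
    conIdx <- if (cfg@contradictions)
      sample(signed, cfg@contradictions) else integer(0)
    contradictionPairs <- matrix(character(0), ncol = 2)
    for (i in conIdx) {
      partner <- units[[i]]
      partner@predicate <- unname(.OPPOSITE_PREDICATE[partner@predicate])
      partner@predicateInReference <- character(0)
      partner@references <- list(Reference("literature", "conflicting-report",
                                           acquisitionDate = "2020-06-01"))
      m <- otherModel(model[i])
      extras[[m]] <- c(extras[[m]], list(partner))
      contradictionPairs <- rbind(contradictionPairs,
                                  c(canonicalKey(units[[i]]),
                                    canonicalKey(partner)))
    }

    documents <- lapply(seq_len(cfg@nModels), function(m)
      CodamlDocument(c(units[model == m], extras[[m]]),
                     creationDate = "2020-01-01"))
    names(documents) <- paste0("model", seq_len(cfg@nModels))
    list(documents = documents,
         truth = new("GroundTruth", duplicateKeys = duplicateKeys,
                     contradictionPairs = contradictionPairs))
  })
}
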