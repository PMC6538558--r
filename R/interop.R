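# Interchange with a declared BioPAX Level-3 subset (RDF/XML), plus flat
# SIF export. The conversion is explicitly lossy and every conversion emits
# a report accounting for each construct:
#   * gene cores -> Protein/Rna/Dna with an EntityReference carrying an
#     Ensembl UnificationXref; compound cores -> SmallMolecule with a STITCH
#     xref; process/function/phenotype/user-defined cores -> generic
#     PhysicalEntity (core type kept in a structured comment);
#   * multi-core entities -> Complex with component physical entities;
#   * induction/reduction families -> Control with controlType
#     ACTIVATION/INHIBITION; bare directed link -> Control without a
#     controlType; the undirected family -> MolecularInteraction;
#     missing interaction -> skipped (reported);
#   * anatomy -> a CellularLocationVocabulary whose terms are
#     "organ:<id>"/"tissue:<id>"/"cell:<id>" with MeSH xrefs;
#   * environmental contexts and species -> structured comments
#     ("codaml:environmentalContext=type/id"), round-trippable through our
#     own exports while readable by generic BioPAX tools;
#   * sign-resolved leaf predicates are flattened to their family on export
#     and restored only as the family on import (BioPAX controlType has no
#     by-increase/by-decrease axis); references and evidence scores are
#     dropped with a report line.
# Import additionally accepts BiochemicalReaction (left/right participants
# become multi-core subject/object with predicate "directed link").

.BP <- "http://www.biopax.org/release/biopax-level3.owl#"

.bpCoreClass <- function(core) {
  if (core@coreType == "gene") {
    mt <- if (is.null(core@spec)) "protein" else core@spec@moleculeType
    switch(mt, DNA = "Dna", RNA = "Rna", "Protein")
  } else if (core@coreType == "compound") "SmallMolecule" else "PhysicalEntity"
}

.bpRefClass <- function(peClass)
  switch(peClass, Protein = "ProteinReference", Rna = "RnaReference",
         Dna = "DnaReference", SmallMolecule = "SmallMoleculeReference", NA)

.specComment <- function(core) {
  if (is.null(core@spec)) return("codaml:spec=none")
  paste0("codaml:spec=", core@spec@moleculeType, "|",
         if (length(core@spec@isoform)) core@spec@isoform else "", "|",
         paste(core@spec@modifications, collapse = ","))
}

# state: mutable environment carrying element text and shared-id maps
.bpState <- function() {
  st <- new.env(parent = emptyenv())
  st$elements <- character(0)
  st$xrefs <- character(0)     # db|id -> xref element id
  st$ers <- character(0)       # class|coreId -> entity reference id
  st$cvs <- character(0)       # anatomy key -> vocabulary id
  st$n <- 0L
  st
}

.bpId <- function(st, prefix) {
  st$n <- st$n + 1L
  paste0(prefix, "_", st$n)
}

.bpEmit <- function(st, lines) st$elements <- c(st$elements, lines)

.bpXref <- function(st, db, id) {
  key <- paste0(db, "|", id)
  if (!is.na(hit <- st$xrefs[key])) return(unname(hit))
  xid <- .bpId(st, "XREF")
  .bpEmit(st, c(
    paste0("  <bp:UnificationXref rdf:ID=\"", xid, "\">"),
    paste0("    <bp:db rdf:datatype=\"http://www.w3.org/2001/XMLSchema#string\">",
           .xmlEsc(db), "</bp:db>"),
    paste0("    <bp:id rdf:datatype=\"http://www.w3.org/2001/XMLSchema#string\">",
           .xmlEsc(id), "</bp:id>"),
    "  </bp:UnificationXref>"))
  st$xrefs[key] <- xid
  xid
}

.bpAnatomyCV <- function(st, anatomy) {
  key <- canonicalKey(anatomy)
  if (key == "||") return(NA_character_)
  if (!is.na(hit <- st$cvs[key])) return(unname(hit))
  cvid <- .bpId(st, "CV")
  lines <- paste0("  <bp:CellularLocationVocabulary rdf:ID=\"", cvid, "\">")
  for (s in c("organ", "tissue", "cell")) {
    v <- slot(anatomy, s)
    if (length(v)) {
      lines <- c(lines,
        paste0("    <bp:term rdf:datatype=\"http://www.w3.org/2001/XMLSchema#string\">",
               s, ":", .xmlEsc(v), "</bp:term>"),
        paste0("    <bp:xref rdf:resource=\"#", .bpXref(st, "MeSH", v), "\"/>"))
    }
  }
  .bpEmit(st, c(lines, "  </bp:CellularLocationVocabulary>"))
  st$cvs[key] <- cvid
  cvid
}

.bpEntityRef <- function(st, core, peClass) {
  refClass <- .bpRefClass(peClass)
  if (is.na(refClass)) return(NA_character_)
  key <- paste0(refClass, "|", core@coreId)
  if (!is.na(hit <- st$ers[key])) return(unname(hit))
  erid <- .bpId(st, "ER")
  db <- if (core@coreType == "gene") "Ensembl" else "STITCH"
  .bpEmit(st, c(
    paste0("  <bp:", refClass, " rdf:ID=\"", erid, "\">"),
    paste0("    <bp:xref rdf:resource=\"#", .bpXref(st, db, core@coreId), "\"/>"),
    paste0("  </bp:", refClass, ">")))
  st$ers[key] <- erid
  erid
}

.bpComment <- function(text)
  paste0("    <bp:comment rdf:datatype=\"http://www.w3.org/2001/XMLSchema#string\">",
         .xmlEsc(text), "</bp:comment>")

.bpCorePE <- function(st, core, cvid = NA_character_) {
  peClass <- .bpCoreClass(core)
  peid <- .bpId(st, "PE")
  lines <- c(
    paste0("  <bp:", peClass, " rdf:ID=\"", peid, "\">"),
    paste0("    <bp:displayName rdf:datatype=\"http://www.w3.org/2001/XMLSchema#string\">",
           .xmlEsc(core@coreId), "</bp:displayName>"))
  erid <- .bpEntityRef(st, core, peClass)
  if (!is.na(erid))
    lines <- c(lines, paste0("    <bp:entityReference rdf:resource=\"#", erid,
                             "\"/>"))
  lines <- c(lines, .bpComment(paste0("codaml:coreType=", core@coreType)))
  if (core@coreType == "gene")
    lines <- c(lines, .bpComment(.specComment(core)))
  if (!is.na(cvid))
    lines <- c(lines, paste0("    <bp:cellularLocation rdf:resource=\"#",
                             cvid, "\"/>"))
  .bpEmit(st, c(lines, paste0("  </bp:", peClass, ">")))
  peid
}

.bpEntity <- function(st, entity) {
  cvid <- .bpAnatomyCV(st, entity@anatomy)
  if (length(entity@cores) == 1L)
    return(.bpCorePE(st, entity@cores[[1]], cvid))
  compIds <- vapply(entity@cores, function(core) .bpCorePE(st, core),
                    character(1))
  cid <- .bpId(st, "PE")
  lines <- paste0("  <bp:Complex rdf:ID=\"", cid, "\">")
  for (ci in compIds)
    lines <- c(lines, paste0("    <bp:component rdf:resource=\"#", ci, "\"/>"))
  if (!is.na(cvid))
    lines <- c(lines, paste0("    <bp:cellularLocation rdf:resource=\"#",
                             cvid, "\"/>"))
  .bpEmit(st, c(lines, "  </bp:Complex>"))
  cid
}

#' Convert a document to the BioPAX Level-3 subset
#'
#' See the mapping summary in the package's methods vignette. The
#' conversion never fails on supported documents; constructs outside the
#' subset are enumerated in the report. Report accounting: one row per
#' knowledge unit (converted or skipped), one row per reference and per
#' evidence score (dropped), one row per environmental context (encoded as
#' a structured comment, or skipped when its unit is skipped).
#'
#' @param doc a valid \linkS4class{CodamlDocument}.
#' @param file optional output path for the OWL text.
#' @return list with elements \code{owl} (character(1) RDF/XML) and
#'   \code{report} (data.frame: ku, construct, status, detail).
#' @export
toBiopax <- function(doc, file = NULL) {
  stopifnot(is(doc, "CodamlDocument"))
  st <- .bpState()
  report <- list()
  addRow <- function(ku, construct, status, detail)
    report[[length(report) + 1L]] <<-
      data.frame(ku = ku, construct = construct, status = status,
                 detail = detail, stringsAsFactors = FALSE)
  for (i in seq_along(doc@knowledgeUnits)) {
    ku <- doc@knowledgeUnits[[i]]
    fam <- predicateFamily(ku@predicate)
    envStatus <- "encoded"
    if (fam == "missing interaction") {
      addRow(i, "ku", "skipped",
             "missing interaction has no BioPAX counterpart")
      envStatus <- "skipped"
    } else {
      subjId <- .bpEntity(st, ku@subject)
      objId <- .bpEntity(st, ku@object)
      intId <- .bpId(st, "INT")
      comments <- c(.bpComment(paste0("codaml:species=", ku@species)),
                    vapply(ku@environmentalContexts, function(ctx)
                      .bpComment(paste0("codaml:environmentalContext=",
                                        ctx@contextType, "/", ctx@contextId)),
                      character(1)))
      if (fam == "undirected link") {
        .bpEmit(st, c(
          paste0("  <bp:MolecularInteraction rdf:ID=\"", intId, "\">"),
          paste0("    <bp:participant rdf:resource=\"#", subjId, "\"/>"),
          paste0("    <bp:participant rdf:resource=\"#", objId, "\"/>"),
          comments,
          "  </bp:MolecularInteraction>"))
        addRow(i, "ku", "converted",
               "undirected family -> MolecularInteraction (sign dropped)")
      } else {
        ctype <- switch(fam, induction = "ACTIVATION",
                        reduction = "INHIBITION", NA_character_)
        lines <- c(paste0("  <bp:Control rdf:ID=\"", intId, "\">"),
                   paste0("    <bp:controller rdf:resource=\"#", subjId,
                          "\"/>"),
                   paste0("    <bp:controlled rdf:resource=\"#", objId,
                          "\"/>"))
        if (!is.na(ctype))
          lines <- c(lines,
            paste0("    <bp:controlType rdf:datatype=\"http://www.w3.org/2001/XMLSchema#string\">",
                   ctype, "</bp:controlType>"))
        .bpEmit(st, c(lines, comments, "  </bp:Control>"))
        addRow(i, "ku", "converted",
               paste0(fam, " family -> Control",
                      if (!is.na(ctype)) paste0("(", ctype, ")") else ""))
      }
    }
    for (ctx in ku@environmentalContexts)
      addRow(i, "environmentalContext", envStatus,
             paste0(ctx@contextType, "/", ctx@contextId))
    for (r in ku@references)
      addRow(i, "reference", "skipped",
             paste0(r@referenceType, ":", r@name))
    if (length(ku@evidenceScore))
      addRow(i, "evidenceScore", "skipped",
             paste0(ku@evidenceType, " score dropped"))
  }
  owl <- paste0(paste(c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
           " xmlns:owl=\"http://www.w3.org/2002/07/owl#\"",
           " xmlns:bp=\"", .BP, "\"",
           " xml:base=\"http://codaml.example.org/biopax/\">"),
    "  <owl:Ontology rdf:about=\"\">",
    paste0("    <owl:imports rdf:resource=\"", .BP, "\"/>"),
    "  </owl:Ontology>",
    st$elements,
    "</rdf:RDF>"), collapse = "\n"), "\n")
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(ku = integer(0), construct = character(0),
               status = character(0), detail = character(0),
               stringsAsFactors = FALSE)
  if (!is.null(file)) {
    con <- base::file(file, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(enc2utf8(owl)), con)
  }
  list(owl = owl, report = report)
}

## ----- import -----

.localName <- function(node) xml2::xml_name(node)

.rdfAttr <- function(node, what) {
  at <- xml2::xml_attrs(node)
  hit <- at[names(at) == what | endsWith(names(at), paste0(":", what))]
  if (length(hit)) unname(hit[1]) else NA_character_
}

.bpChildren <- function(node, local)
  xml2::xml_find_all(node, paste0("./*[local-name()='", local, "']"))

.bpChildText <- function(node, local) {
  hits <- .bpChildren(node, local)
  if (length(hits)) xml2::xml_text(hits[[1]]) else NA_character_
}

.bpResolve <- function(index, node, local) {
  hits <- .bpChildren(node, local)
  lapply(hits, function(h) {
    ref <- .rdfAttr(h, "resource")
    if (is.na(ref)) return(NULL)
    index[[sub("^#", "", ref)]]
  })
}

.bpComments <- function(node)
  vapply(.bpChildren(node, "comment"), xml2::xml_text, character(1))

.bpParseAnatomy <- function(index, peNode) {
  cvs <- .bpResolve(index, peNode, "cellularLocation")
  if (!length(cvs) || is.null(cvs[[1]])) return(new("AnatomicalContext"))
  terms <- vapply(.bpChildren(cvs[[1]], "term"), xml2::xml_text, character(1))
  pick <- function(prefix) {
    hit <- terms[startsWith(terms, paste0(prefix, ":"))]
    if (length(hit)) sub(paste0("^", prefix, ":"), "", hit[1]) else character(0)
  }
  new("AnatomicalContext", organ = pick("organ"), tissue = pick("tissue"),
      cell = pick("cell"))
}

.bpParseCore <- function(index, peNode) {
  cls <- .localName(peNode)
  comments <- .bpComments(peNode)
  coreId <- .bpChildText(peNode, "displayName")
  if (is.na(coreId)) {
    # fall back to the entity reference's xref id
    ers <- .bpResolve(index, peNode, "entityReference")
    coreId <- "unknown"
    if (length(ers) && !is.null(ers[[1]])) {
      xr <- .bpResolve(index, ers[[1]], "xref")
      if (length(xr) && !is.null(xr[[1]]))
        coreId <- .bpChildText(xr[[1]], "id")
    }
  }
  ctHit <- comments[startsWith(comments, "codaml:coreType=")]
  coreType <- if (length(ctHit)) sub("^codaml:coreType=", "", ctHit[1]) else
    switch(cls, Protein = "gene", Rna = "gene", Dna = "gene",
           SmallMolecule = "compound", "user_defined")
  spec <- NULL
  if (coreType == "gene") {
    spHit <- comments[startsWith(comments, "codaml:spec=")]
    if (length(spHit) && spHit[1] != "codaml:spec=none") {
      parts <- strsplit(sub("^codaml:spec=", "", spHit[1]), "|",
                        fixed = TRUE)[[1]]
      parts <- c(parts, rep("", 3L - length(parts)))
      mods <- if (nzchar(parts[3])) strsplit(parts[3], ",", fixed = TRUE)[[1]]
              else character(0)
      spec <- new("MolecularSpecification", moleculeType = parts[1],
                  isoform = if (nzchar(parts[2])) parts[2] else character(0),
                  modifications = sort(unique(mods)))
    } else if (!length(spHit)) {
      # foreign BioPAX: derive the molecule type from the class
      spec <- new("MolecularSpecification",
                  moleculeType = switch(cls, Rna = "RNA", Dna = "DNA",
                                        "protein"),
                  isoform = character(0), modifications = character(0))
    }
  }
  new("EntityCore", coreId = coreId, coreType = coreType, spec = spec)
}

.bpParseEntity <- function(index, peNode) {
  if (.localName(peNode) == "Complex") {
    comps <- .bpResolve(index, peNode, "component")
    cores <- lapply(Filter(Negate(is.null), comps),
                    function(n) .bpParseCore(index, n))
    return(new("Entity", cores = cores,
               anatomy = .bpParseAnatomy(index, peNode)))
  }
  new("Entity", cores = list(.bpParseCore(index, peNode)),
      anatomy = .bpParseAnatomy(index, peNode))
}

.bpCtxFromComments <- function(comments) {
  hits <- comments[startsWith(comments, "codaml:environmentalContext=")]
  ctxs <- lapply(hits, function(h) {
    parts <- strsplit(sub("^codaml:environmentalContext=", "", h), "/",
                      fixed = TRUE)[[1]]
    new("EnvironmentalContext", contextType = parts[1],
        contextId = paste(parts[-1], collapse = "/"))
  })
  if (length(ctxs)) {
    ek <- vapply(ctxs, canonicalKey, character(1))
    ctxs <- ctxs[order(ek)][!duplicated(sort(ek))]
  }
  ctxs
}

#' Import a BioPAX Level-3 subset document
#'
#' Inverse of the lossless rows of \code{\link{toBiopax}}: Control becomes
#' an induction/reduction-family or directed-link unit,
#' MolecularInteraction an undirected link, and BiochemicalReaction a
#' directed link whose left/right participants become multi-core subject
#' and object. Cores, core types, molecular specifications, anatomy,
#' environmental contexts and species encoded by our exporter are
#' restored; constructs outside the subset are reported and skipped.
#' Imported units carry a synthesized provenance reference naming the
#' import.
#'
#' @param x OWL (RDF/XML) text or a file path.
#' @param sourceName reference name recorded on imported units.
#' @return list with elements \code{document}
#'   (a \linkS4class{CodamlDocument}) and \code{report} (data.frame).
#' @export
fromBiopax <- function(x, sourceName = "BioPAX import") {
  xml <- xml2::read_xml(x)
  tops <- xml2::xml_find_all(xml, "./*")
  index <- list()
  for (node in tops) {
    id <- .rdfAttr(node, "ID")
    if (is.na(id)) id <- sub("^#", "", .rdfAttr(node, "about"))
    if (!is.na(id) && nzchar(id)) index[[id]] <- node
  }
  supportClasses <- c("Ontology", "Protein", "Rna", "Dna", "SmallMolecule",
                      "PhysicalEntity", "Complex", "ProteinReference",
                      "RnaReference", "DnaReference", "SmallMoleculeReference",
                      "UnificationXref", "CellularLocationVocabulary")
  importRef <- list(new("Reference", referenceType = "user_defined",
                        name = sourceName, description = character(0),
                        recordId = character(0), version = character(0),
                        acquisitionDate = character(0)))
  kus <- list()
  report <- list()
  addRow <- function(construct, status, detail)
    report[[length(report) + 1L]] <<-
      data.frame(construct = construct, status = status, detail = detail,
                 stringsAsFactors = FALSE)
  mkKu <- function(subject, predicate, object, node) {
    comments <- .bpComments(node)
    spHit <- comments[startsWith(comments, "codaml:species=")]
    new("KnowledgeUnit", subject = subject, predicate = predicate,
        object = object, predicateInReference = character(0),
        environmentalContexts = .bpCtxFromComments(comments),
        species = if (length(spHit)) sub("^codaml:species=", "", spHit[1])
                  else "Homo sapiens",
        references = importRef, evidenceScore = numeric(0),
        evidenceType = character(0))
  }
  for (node in tops) {
    cls <- .localName(node)
    if (cls %in% supportClasses) next
    if (cls == "Control") {
      controller <- .bpResolve(index, node, "controller")
      controlled <- .bpResolve(index, node, "controlled")
      if (!length(controller) || !length(controlled) ||
          is.null(controller[[1]]) || is.null(controlled[[1]])) {
        addRow(cls, "skipped", "unresolvable controller/controlled")
        next
      }
      ctype <- .bpChildText(node, "controlType")
      predicate <- if (is.na(ctype)) "directed link" else
        switch(ctype, ACTIVATION = "induction", INHIBITION = "reduction",
               "directed link")
      kus[[length(kus) + 1L]] <-
        mkKu(.bpParseEntity(index, controller[[1]]), predicate,
             .bpParseEntity(index, controlled[[1]]), node)
      addRow(cls, "converted", predicate)
    } else if (cls == "MolecularInteraction") {
      parts <- Filter(Negate(is.null), .bpResolve(index, node, "participant"))
      if (length(parts) < 2L) {
        addRow(cls, "skipped", "needs two participants")
        next
      }
      kus[[length(kus) + 1L]] <-
        mkKu(.bpParseEntity(index, parts[[1]]), "undirected link",
             .bpParseEntity(index, parts[[2]]), node)
      addRow(cls, "converted", "undirected link")
    } else if (cls == "BiochemicalReaction") {
      left <- Filter(Negate(is.null), .bpResolve(index, node, "left"))
      right <- Filter(Negate(is.null), .bpResolve(index, node, "right"))
      if (!length(left) || !length(right)) {
        addRow(cls, "skipped", "needs left and right participants")
        next
      }
      mkSide <- function(pes) {
        cores <- lapply(pes, function(n) .bpParseCore(index, n))
        new("Entity", cores = cores, anatomy = .bpParseAnatomy(index, pes[[1]]))
      }
      kus[[length(kus) + 1L]] <-
        mkKu(mkSide(left), "directed link", mkSide(right), node)
      addRow(cls, "converted", "reaction -> directed link")
    } else {
      addRow(cls, "skipped", "construct outside the declared subset")
    }
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(construct = character(0), status = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  list(document = new("CodamlDocument", knowledgeUnits = kus,
                      formatVersion = "1.0", creationDate = character(0)),
       report = report)
}

#' Flat SIF export
#'
#' One tab-separated line per knowledge unit: subject label, predicate,
#' object label, in document order. Multi-core entities appear as one
#' complex label.
#'
#' @param doc a \linkS4class{CodamlDocument}.
#' @return character vector of SIF lines (length zero for an empty
#'   document).
#' @export
toSIF <- function(doc) {
  stopifnot(is(doc, "CodamlDocument"))
  vapply(doc@knowledgeUnits, function(ku)
    paste(.entityLabel(ku@subject), ku@predicate, .entityLabel(ku@object),
          sep = "\t"), character(1))
}

#' Write SIF to a file
#'
#' @param doc a \linkS4class{CodamlDocument}.
#' @param file output path.
#' @return invisibly, the SIF lines.
#' @export
writeSIF <- function(doc, file) {
  lines <- toSIF(doc)
  writeLines(lines, file)
  invisible(lines)
}
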