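# Canonical XML serialization of the CODA-ML dialect.
#
# The writer is a deterministic string builder: fixed element order, 2-space
# indent, UTF-8, LF line endings, lexicographic ordering of modification and
# environmental-context sets. Equal documents therefore serialize to
# byte-identical text. Parsing goes through xml2 with XSD validation against
# the schema shipped in inst/extdata/codaml.xsd.

.xmlEsc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

.tag <- function(depth, name, text)
  paste0(strrep("  ", depth), "<", name, ">", .xmlEsc(text), "</", name, ">")

.optTag <- function(depth, name, value)
  if (length(value)) .tag(depth, name, value) else character(0)

.writeEntity <- function(entity, holder, depth) {
  out <- c(paste0(strrep("  ", depth), "<", holder, ">"),
           paste0(strrep("  ", depth + 1L), "<entity>"))
  for (core in entity@cores) {
    out <- c(out, paste0(strrep("  ", depth + 2L), "<entityCore>"),
             .tag(depth + 3L, "id", core@coreId),
             .tag(depth + 3L, "coreType", core@coreType))
    if (!is.null(core@spec)) {
      out <- c(out, .tag(depth + 3L, "moleculeType", core@spec@moleculeType),
               .optTag(depth + 3L, "isoform", core@spec@isoform))
      for (m in sort(core@spec@modifications))
        out <- c(out, .tag(depth + 3L, "modification", m))
    }
    out <- c(out, paste0(strrep("  ", depth + 2L), "</entityCore>"))
  }
  a <- entity@anatomy
  if (length(a@organ) || length(a@tissue) || length(a@cell)) {
    out <- c(out, paste0(strrep("  ", depth + 2L), "<anatomicalContext>"),
             .optTag(depth + 3L, "organ", a@organ),
             .optTag(depth + 3L, "tissue", a@tissue),
             .optTag(depth + 3L, "cell", a@cell),
             paste0(strrep("  ", depth + 2L), "</anatomicalContext>"))
  }
  c(out, paste0(strrep("  ", depth + 1L), "</entity>"),
    paste0(strrep("  ", depth), "</", holder, ">"))
}

.writeKu <- function(ku, depth) {
  out <- c(paste0(strrep("  ", depth), "<ku>"),
           .writeEntity(ku@subject, "subject", depth + 1L),
           .tag(depth + 1L, "predicate", ku@predicate),
           .optTag(depth + 1L, "predicateInReference", ku@predicateInReference),
           .writeEntity(ku@object, "object", depth + 1L))
  if (length(ku@environmentalContexts)) {
    ek <- vapply(ku@environmentalContexts, canonicalKey, character(1))
    for (ctx in ku@environmentalContexts[order(ek)])
      out <- c(out, paste0(strrep("  ", depth + 1L), "<environmentalContext>"),
               .tag(depth + 2L, "contextType", ctx@contextType),
               .tag(depth + 2L, "contextId", ctx@contextId),
               paste0(strrep("  ", depth + 1L), "</environmentalContext>"))
  }
  out <- c(out, .tag(depth + 1L, "species", ku@species))
  for (r in ku@references)
    out <- c(out, paste0(strrep("  ", depth + 1L), "<reference>"),
             .tag(depth + 2L, "referenceType", r@referenceType),
             .tag(depth + 2L, "name", r@name),
             .optTag(depth + 2L, "description", r@description),
             .optTag(depth + 2L, "recordId", r@recordId),
             .optTag(depth + 2L, "version", r@version),
             .optTag(depth + 2L, "acquisitionDate", r@acquisitionDate),
             paste0(strrep("  ", depth + 1L), "</reference>"))
  if (length(ku@evidenceScore))
    out <- c(out, paste0(strrep("  ", depth + 1L),
                         "<evidenceScore type=\"", ku@evidenceType, "\">",
                         as.character(ku@evidenceScore), "</evidenceScore>"))
  c(out, paste0(strrep("  ", depth), "</ku>"))
}

#' Serialize a document to canonical CODA-ML XML
#'
#' Produces the canonical byte-stable serialization: UTF-8, LF, 2-space
#' indent, fixed element order, modifications and environmental contexts in
#' lexicographic order. Equal documents serialize byte-identically. The
#' document is validated first and serialization is refused (with the issue
#' list in the error) if any error-severity issue is present.
#'
#' @param doc a \linkS4class{CodamlDocument}.
#' @param file optional path; when given the text is also written to disk.
#' @param validate set FALSE to skip validation (used internally).
#' @return character(1): the XML text (invisibly when \code{file} is given).
#' @export
writeDocument <- function(doc, file = NULL, validate = TRUE) {
  stopifnot(is(doc, "CodamlDocument"))
  if (validate) {
    issues <- validateDocument(doc, strict = FALSE)
    .stopOnIssues(issues, "cannot serialize invalid document")
  }
  attrs <- paste0(" formatVersion=\"", .xmlEsc(doc@formatVersion), "\"")
  if (length(doc@creationDate))
    attrs <- paste0(attrs, " creationDate=\"", .xmlEsc(doc@creationDate), "\"")
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             paste0("<codaml", attrs, ">"))
  for (ku in doc@knowledgeUnits) lines <- c(lines, .writeKu(ku, 1L))
  lines <- c(lines, "</codaml>")
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) {
    con <- file(file, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(enc2utf8(text)), con)
    return(invisible(text))
  }
  text
}

#' Path to the CODA-ML XML schema
#'
#' The XSD mirrors the same structural table that drives the validator:
#' element order, optionality and multiplicity of every component.
#'
#' @return character(1) file path.
#' @export
codamlSchema <- function()
  system.file("extdata", "codaml.xsd", package = "codamlr", mustWork = TRUE)

.orEmpty <- function(x) if (length(x)) x else ""

.xmlChildText <- function(node, name) {
  hit <- xml2::xml_find_first(node, name)
  if (inherits(hit, "xml_missing")) character(0) else xml2::xml_text(hit)
}

.parseEntity <- function(holderNode) {
  entityNode <- xml2::xml_find_first(holderNode, "./entity")
  cores <- lapply(xml2::xml_find_all(entityNode, "./entityCore"), function(cn) {
    mt <- .xmlChildText(cn, "./moleculeType")
    spec <- NULL
    if (length(mt)) {
      mods <- vapply(xml2::xml_find_all(cn, "./modification"), xml2::xml_text,
                     character(1))
      spec <- new("MolecularSpecification", moleculeType = mt,
                  isoform = .xmlChildText(cn, "./isoform"),
                  modifications = sort(unique(mods)))
    }
    new("EntityCore", coreId = .orEmpty(.xmlChildText(cn, "./id")),
        coreType = .orEmpty(.xmlChildText(cn, "./coreType")), spec = spec)
  })
  an <- xml2::xml_find_first(entityNode, "./anatomicalContext")
  anatomy <- if (inherits(an, "xml_missing")) new("AnatomicalContext") else
    new("AnatomicalContext",
        organ = .xmlChildText(an, "./organ"),
        tissue = .xmlChildText(an, "./tissue"),
        cell = .xmlChildText(an, "./cell"))
  new("Entity", cores = cores, anatomy = anatomy)
}

.parseKu <- function(kuNode) {
  ctxs <- lapply(xml2::xml_find_all(kuNode, "./environmentalContext"),
                 function(cn) new("EnvironmentalContext",
                                  contextType = .orEmpty(.xmlChildText(cn, "./contextType")),
                                  contextId = .orEmpty(.xmlChildText(cn, "./contextId"))))
  if (length(ctxs)) {
    ek <- vapply(ctxs, canonicalKey, character(1))
    ctxs <- ctxs[order(ek)][!duplicated(sort(ek))]
  }
  refs <- lapply(xml2::xml_find_all(kuNode, "./reference"), function(rn)
    new("Reference",
        referenceType = .orEmpty(.xmlChildText(rn, "./referenceType")),
        name = .orEmpty(.xmlChildText(rn, "./name")),
        description = .xmlChildText(rn, "./description"),
        recordId = .xmlChildText(rn, "./recordId"),
        version = .xmlChildText(rn, "./version"),
        acquisitionDate = .xmlChildText(rn, "./acquisitionDate")))
  es <- xml2::xml_find_first(kuNode, "./evidenceScore")
  score <- numeric(0); etype <- character(0)
  if (!inherits(es, "xml_missing")) {
    score <- as.numeric(xml2::xml_text(es))
    etype <- xml2::xml_attr(es, "type")
    if (is.na(etype)) etype <- character(0)
  }
  new("KnowledgeUnit",
      subject = .parseEntity(xml2::xml_find_first(kuNode, "./subject")),
      predicate = .orEmpty(.xmlChildText(kuNode, "./predicate")),
      object = .parseEntity(xml2::xml_find_first(kuNode, "./object")),
      predicateInReference = .xmlChildText(kuNode, "./predicateInReference"),
      environmentalContexts = ctxs,
      species = .orEmpty(.xmlChildText(kuNode, "./species")),
      references = refs, evidenceScore = score, evidenceType = etype)
}

#' Parse a CODA-ML XML document
#'
#' Reads XML text or a file path, checks it against the shipped XSD (so
#' unknown elements, missing required elements and wrong ordering are
#' caught), builds the data model, and validates it. In strict mode (the
#' default) schema failures and error-severity model issues abort with a
#' message listing the issues; in lenient mode they are reported as
#' warnings and the document is returned for inspection with
#' \code{\link{validateDocument}}.
#'
#' @param x XML text (starting with "<") or a file path.
#' @param strict logical; abort on errors (TRUE) or downgrade to warnings.
#' @return a \linkS4class{CodamlDocument}.
#' @export
parseDocument <- function(x, strict = TRUE) {
  xml <- xml2::read_xml(x)
  if (is.null(.codamlr$schema))
    .codamlr$schema <- xml2::read_xml(codamlSchema())
  ok <- xml2::xml_validate(xml, .codamlr$schema)
  if (!ok) {
    msg <- paste(attr(ok, "errors"), collapse = "; ")
    if (strict) stop("schema violation: ", msg, call. = FALSE)
    warning("schema violation: ", msg, call. = FALSE)
  }
  if (xml2::xml_name(xml) != "codaml")
    stop("parse error: root element must be <codaml>", call. = FALSE)
  fv <- xml2::xml_attr(xml, "formatVersion")
  cd <- xml2::xml_attr(xml, "creationDate")
  doc <- new("CodamlDocument",
             knowledgeUnits = lapply(xml2::xml_find_all(xml, "./ku"), .parseKu),
             formatVersion = if (is.na(fv)) "1.0" else fv,
             creationDate = if (is.na(cd)) character(0) else cd)
  issues <- validateDocument(doc, strict = strict)
  if (strict) {
    .stopOnIssues(issues, "document violates model invariants")
  } else if (any(issues$severity == "error")) {
    warning("document has ", sum(issues$severity == "error"),
            " error-severity validation issue(s); see validateDocument()",
            call. = FALSE)
  }
  doc
}
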