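# Structural validator. Every model invariant maps to exactly one rule id;
# identifier-pattern mismatches are errors in strict mode and warnings in
# lenient mode, placeholder ("unverified:") identifiers and anatomical
# hierarchy gaps are always warnings.

.issue <- function(severity, ku, path, rule, message)
  data.frame(severity = severity, ku = ku, path = path, rule = rule,
             message = message, stringsAsFactors = FALSE)

.noIssues <- function()
  data.frame(severity = character(0), ku = integer(0), path = character(0),
             rule = character(0), message = character(0),
             stringsAsFactors = FALSE)

.stopOnIssues <- function(issues, what) {
  bad <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(bad))
    stop(what, ":\n", paste0("  [", bad$rule, "] ", bad$path, ": ",
                             bad$message, collapse = "\n"), call. = FALSE)
  invisible(issues)
}

.checkIdentifier <- function(id, role, i, path, strict) {
  if (role %in% c("user_defined", "siRNA_treatment")) return(.noIssues())
  if (grepl("^unverified:", id))
    return(.issue("warning", i, path, "identifier.unverified",
                  paste0("placeholder identifier ", id,
                         " is syntactic only, not a verified accession")))
  if (!.idFitsRole(id, role))
    return(.issue(if (strict) "error" else "warning", i, path,
                  "identifier.pattern",
                  paste0("identifier ", id, " does not match any namespace ",
                         "pattern for role '", role, "'")))
  .noIssues()
}

.validateEntity <- function(entity, i, side, strict) {
  out <- .noIssues()
  base <- paste0("ku[", i, "]/", side, "/entity")
  if (!length(entity@cores))
    return(.issue("error", i, base, "entity.empty_cores",
                  "entity has no entity cores"))
  for (j in seq_along(entity@cores)) {
    core <- entity@cores[[j]]
    p <- paste0(base, "/entityCore[", j, "]")
    if (!nzchar(core@coreId) || is.na(core@coreId))
      out <- rbind(out, .issue("error", i, p, "core.id_empty",
                               "core identifier is empty"))
    if (!core@coreType %in% .CORE_TYPES) {
      out <- rbind(out, .issue("error", i, p, "core.type",
                               paste0("unknown core type '", core@coreType, "'")))
    } else if (nzchar(core@coreId) && core@coreType != "user_defined") {
      out <- rbind(out, .checkIdentifier(core@coreId, core@coreType, i,
                                         paste0(p, "/id"), strict))
    }
    if (!is.null(core@spec)) {
      if (core@coreType != "gene" && core@coreType %in% .CORE_TYPES)
        out <- rbind(out, .issue("error", i, p, "core.spec_on_non_gene",
                                 paste0("molecular specification on a '",
                                        core@coreType, "' core")))
      if (!core@spec@moleculeType %in% .MOLECULE_TYPES)
        out <- rbind(out, .issue("error", i, p, "spec.molecule_type",
                                 paste0("unknown molecule type '",
                                        core@spec@moleculeType, "'")))
      if (length(core@spec@isoform)) {
        if (!core@spec@moleculeType %in% c("RNA", "protein"))
          out <- rbind(out, .issue("error", i, p, "spec.isoform_molecule_type",
                                   paste0("isoform given for molecule type '",
                                          core@spec@moleculeType, "'")))
        else
          out <- rbind(out, .checkIdentifier(core@spec@isoform, "isoform", i,
                                             paste0(p, "/isoform"), strict))
      }
      if (anyDuplicated(core@spec@modifications))
        out <- rbind(out, .issue("error", i, p, "spec.modifications_duplicate",
                                 "duplicate modification labels"))
    }
  }
  a <- entity@anatomy
  ap <- paste0(base, "/anatomicalContext")
  if (!length(a@organ) && (length(a@tissue) || length(a@cell)))
    out <- rbind(out, .issue("warning", i, ap, "anatomy.hierarchy_gap",
                             "narrower anatomical slot present without organ"))
  for (s in c("organ", "tissue", "cell")) {
    v <- slot(a, s)
    if (length(v))
      out <- rbind(out, .checkIdentifier(v, "anatomy", i,
                                         paste0(ap, "/", s), strict))
  }
  out
}

.validateKu <- function(ku, i, strict) {
  out <- .noIssues()
  p <- paste0("ku[", i, "]")
  if (!ku@predicate %in% predicateTerms())
    out <- rbind(out, .issue("error", i, paste0(p, "/predicate"),
                             "predicate.controlled",
                             paste0("'", ku@predicate, "' is not one of the 11 ",
                                    "controlled terms; raw text belongs in ",
                                    "predicateInReference")))
  out <- rbind(out, .validateEntity(ku@subject, i, "subject", strict))
  out <- rbind(out, .validateEntity(ku@object, i, "object", strict))
  for (j in seq_along(ku@environmentalContexts)) {
    ctx <- ku@environmentalContexts[[j]]
    cp <- paste0(p, "/environmentalContext[", j, "]")
    if (!ctx@contextType %in% .ENV_CONTEXT_TYPES)
      out <- rbind(out, .issue("error", i, cp, "context.type",
                               paste0("unknown context type '",
                                      ctx@contextType, "'")))
    if (!nzchar(ctx@contextId) || is.na(ctx@contextId))
      out <- rbind(out, .issue("error", i, cp, "context.id_empty",
                               "context identifier is empty"))
    else if (ctx@contextType %in% .ENV_CONTEXT_TYPES)
      out <- rbind(out, .checkIdentifier(ctx@contextId, ctx@contextType, i,
                                         paste0(cp, "/contextId"), strict))
  }
  if (is.na(ku@species) || !nzchar(ku@species))
    out <- rbind(out, .issue("error", i, paste0(p, "/species"),
                             "species.empty", "species is required"))
  if (!length(ku@references))
    out <- rbind(out, .issue("error", i, paste0(p, "/reference"),
                             "reference.missing",
                             "at least one reference is required"))
  for (j in seq_along(ku@references)) {
    r <- ku@references[[j]]
    rp <- paste0(p, "/reference[", j, "]")
    if (!r@referenceType %in% .REFERENCE_TYPES)
      out <- rbind(out, .issue("error", i, rp, "reference.type",
                               paste0("unknown reference type '",
                                      r@referenceType, "'")))
    if (is.na(r@name) || !nzchar(r@name))
      out <- rbind(out, .issue("error", i, rp, "reference.name_empty",
                               "reference name is required"))
  }
  if (length(ku@evidenceScore) &&
      (!length(ku@evidenceType) || !ku@evidenceType %in% .EVIDENCE_TYPES))
    out <- rbind(out, .issue("error", i, paste0(p, "/evidenceScore"),
                             "evidence.type_tag",
                             "evidence score must be tagged discrete or continuous"))
  out
}

#' Validate a document against the model invariants
#'
#' Checks every knowledge unit against the structural invariants of the
#' data model (controlled predicate, non-empty cores, specification only on
#' gene cores, isoform/molecule-type compatibility, required references,
#' evidence type tags, context types) and the syntactic identifier
#' namespaces. Each violated invariant yields one issue with a stable rule
#' id. Anatomical hierarchy gaps (a tissue or cell without an organ) and
#' placeholder identifiers are warnings; identifier-pattern mismatches are
#' errors in strict mode and warnings otherwise.
#'
#' @param doc a \linkS4class{CodamlDocument}.
#' @param strict logical; controls the severity of identifier-pattern
#'   failures.
#' @return data.frame with columns severity, ku, path, rule, message; zero
#'   rows for a fully clean document.
#' @export
validateDocument <- function(doc, strict = TRUE) {
  stopifnot(is(doc, "CodamlDocument"))
  out <- .noIssues()
  for (i in seq_along(doc@knowledgeUnits))
    out <- rbind(out, .validateKu(doc@knowledgeUnits[[i]], i, strict))
  rownames(out) <- NULL
  out
}
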