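# Controlled predicate vocabulary and identifier namespaces. The tables
# live in editable YAML config files (see inst/extdata) and are cached on
# first use; every function takes an optional `config`/`namespaces` path so
# users can substitute corrected or extended tables.

.vocabConfig <- function(config = NULL) {
  if (is.null(config)) {
    if (is.null(.codamlr$vocab)) {
      path <- system.file("extdata", "predicate_vocab.yaml",
                          package = "codamlr", mustWork = TRUE)
      .codamlr$vocab <- .loadVocab(path)
    }
    return(.codamlr$vocab)
  }
  .loadVocab(config)
}

.loadVocab <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(is.character(cfg$terms), length(cfg$terms) == 11L)
  cfg$hierarchy <- unlist(cfg$hierarchy)
  cfg$signs <- unlist(cfg$signs)
  cfg$raw_map <- unlist(cfg$raw_map)
  names(cfg$raw_map) <- tolower(names(cfg$raw_map))
  cfg$modification_normalization <- unlist(cfg$modification_normalization)
  cfg
}

.namespaceConfig <- function(namespaces = NULL) {
  if (is.null(namespaces)) {
    if (is.null(.codamlr$namespaces)) {
      path <- system.file("extdata", "identifier_namespaces.yaml",
                          package = "codamlr", mustWork = TRUE)
      .codamlr$namespaces <- yaml::read_yaml(path)
    }
    return(.codamlr$namespaces)
  }
  yaml::read_yaml(namespaces)
}

.assertTerm <- function(t, cfg) {
  if (length(t) != 1L || is.na(t) || !(t %in% cfg$terms))
    stop("unknown predicate term: ", deparse(t), call. = FALSE)
  t
}

#' The 11 controlled predicate terms
#'
#' The closed predicate vocabulary, stratified by the resolution of
#' direction and sign, in stable order: directed link, induction, reduction,
#' activation/inhibition by increase/decrease, undirected link,
#' positive/negative correlation, and missing interaction.
#'
#' @param config optional path to an alternative vocabulary YAML.
#' @return character vector of length 11.
#' @examples
#' predicateTerms()
#' @export
predicateTerms <- function(config = NULL) .vocabConfig(config)$terms

#' Parent of a predicate term in the generalization hierarchy
#'
#' Lower-level terms generalize to higher-level ones: the sign-resolved
#' leaves sit under induction/reduction (causal family, rooted at
#' "directed link") or under "undirected link" (non-causal family). Roots
#' return NULL.
#'
#' @param term a controlled predicate term.
#' @param config optional path to an alternative vocabulary YAML.
#' @return character(1) parent term, or NULL for a root.
#' @examples
#' parentOf("activation by increase")
#' @export
parentOf <- function(term, config = NULL) {
  cfg <- .vocabConfig(config)
  .assertTerm(term, cfg)
  p <- cfg$hierarchy[term]
  if (is.na(p)) NULL else unname(p)
}

# term and all its ancestors, self first
.ancestorsOf <- function(term, cfg) {
  out <- term
  while (!is.na(p <- cfg$hierarchy[term])) {
    term <- unname(p)
    out <- c(out, term)
  }
  out
}

#' Least common ancestor of two predicate terms
#'
#' The deepest term that generalizes both arguments, or NULL when they lie
#' in different root families (causal vs non-causal).
#'
#' @param a,b controlled predicate terms.
#' @param config optional path to an alternative vocabulary YAML.
#' @return character(1) term or NULL.
#' @examples
#' leastCommonAncestor("activation by increase", "inhibition by increase")
#' @export
leastCommonAncestor <- function(a, b, config = NULL) {
  cfg <- .vocabConfig(config)
  .assertTerm(a, cfg); .assertTerm(b, cfg)
  aa <- .ancestorsOf(a, cfg)
  bb <- .ancestorsOf(b, cfg)
  common <- aa[aa %in% bb]
  if (length(common)) common[1L] else NULL
}

#' Sign of a predicate term
#'
#' "positive" for the induction family and positive correlation, "negative"
#' for the reduction family and negative correlation, "unsigned" for
#' directed link, undirected link and missing interaction (causality or
#' association known, sign unresolved or inapplicable).
#'
#' @param term a controlled predicate term.
#' @param config optional path to an alternative vocabulary YAML.
#' @return "positive", "negative" or "unsigned".
#' @examples
#' signOf("induction")
#' signOf("directed link")
#' @export
signOf <- function(term, config = NULL) {
  cfg <- .vocabConfig(config)
  .assertTerm(term, cfg)
  unname(cfg$signs[term])
}

#' Family of a predicate term
#'
#' The coarse family used by integration and interchange: "induction" or
#' "reduction" for the signed causal terms, "directed link" for the bare
#' causal root, "undirected link" for the whole non-causal family, and
#' "missing interaction" for itself.
#'
#' @param term a controlled predicate term.
#' @param config optional path to an alternative vocabulary YAML.
#' @return character(1) family label.
#' @export
predicateFamily <- function(term, config = NULL) {
  cfg <- .vocabConfig(config)
  .assertTerm(term, cfg)
  chain <- .ancestorsOf(term, cfg)
  root <- chain[length(chain)]
  if (root == "undirected link") return("undirected link")
  if (term %in% c("directed link", "missing interaction")) return(term)
  # causal side: the child-of-root ancestor (induction or reduction)
  if (length(chain) == 1L) return(term)
  chain[length(chain) - 1L]
}

#' Are two predicate terms contradictory?
#'
#' True when both terms are signed with opposite signs, or when exactly one
#' of them is "missing interaction" and the other asserts a signed or
#' directed (causal) event. Unsigned terms are compatible with signed ones,
#' and "missing interaction" does not contradict itself.
#'
#' @param a,b controlled predicate terms.
#' @param config optional path to an alternative vocabulary YAML.
#' @return logical(1).
#' @examples
#' isContradictory("induction", "reduction")
#' isContradictory("induction", "directed link")
#' @export
isContradictory <- function(a, b, config = NULL) {
  cfg <- .vocabConfig(config)
  .assertTerm(a, cfg); .assertTerm(b, cfg)
  mi <- c(a, b) == "missing interaction"
  if (xor(mi[1], mi[2])) {
    other <- if (mi[1]) b else a
    return(signOf(other, config) != "unsigned" || other == "directed link")
  }
  if (any(mi)) return(FALSE)
  sa <- unname(cfg$signs[a]); sb <- unname(cfg$signs[b])
  sa != "unsigned" && sb != "unsigned" && sa != sb
}

#' Normalize raw relation text to a controlled predicate term
#'
#' Case-insensitive lookup in the shipped raw-term map (e.g. "activate",
#' "express", "positively regulate", "up-regulate" all mean activation by
#' increase). Unmapped text returns NULL; callers keep such text only as
#' the predicate-in-reference.
#'
#' @param raw relation text as found in a source model.
#' @param config optional path to an alternative vocabulary YAML.
#' @return character(1) controlled term or NULL.
#' @examples
#' normalizeRawPredicate("express")
#' @export
normalizeRawPredicate <- function(raw, config = NULL) {
  cfg <- .vocabConfig(config)
  hit <- cfg$raw_map[tolower(trimws(raw))]
  if (is.na(hit)) NULL else unname(hit)
}

# normalize modification labels via the shipped table; lowercase, map
# noun forms to participles, sort, deduplicate
.normalizeModifications <- function(mods, config = NULL) {
  if (!length(mods)) return(character(0))
  cfg <- .vocabConfig(config)
  mods <- tolower(trimws(mods))
  mapped <- cfg$modification_normalization[mods]
  mods <- ifelse(is.na(mapped), mods, unname(mapped))
  sort(unique(mods))
}

#' Known identifier namespaces
#'
#' @param namespaces optional path to an alternative namespace YAML.
#' @return named list of namespace definitions (anchored pattern + roles).
#' @export
identifierNamespaces <- function(namespaces = NULL) .namespaceConfig(namespaces)

#' Syntactic identifier validation
#'
#' Anchored full-string pattern match of an identifier against a namespace
#' (Ensembl gene/transcript/protein, STITCH compound, GO, UMLS, MeSH, CLO,
#' or the "unverified" placeholder namespace). Purely syntactic; no
#' ontology services are consulted.
#'
#' @param ns namespace name, see \code{\link{identifierNamespaces}}.
#' @param id identifier text.
#' @param namespaces optional path to an alternative namespace YAML.
#' @return logical(1).
#' @examples
#' validateIdentifier("ensembl_gene", "ENSG00000012048")
#' validateIdentifier("umls", "D010053")
#' @export
validateIdentifier <- function(ns, id, namespaces = NULL) {
  tab <- .namespaceConfig(namespaces)
  if (!ns %in% names(tab))
    stop("unknown identifier namespace: ", deparse(ns), call. = FALSE)
  grepl(tab[[ns]]$pattern, id)
}

# namespaces acceptable for a given role
.namespacesForRole <- function(role, namespaces = NULL) {
  tab <- .namespaceConfig(namespaces)
  names(tab)[vapply(tab, function(x) role %in% x$roles || "any" %in% x$roles,
                    logical(1))]
}

# does id syntactically fit any namespace acceptable for role?
.idFitsRole <- function(id, role, namespaces = NULL) {
  nss <- .namespacesForRole(role, namespaces)
  any(vapply(nss, function(ns) validateIdentifier(ns, id, namespaces),
             logical(1)))
}
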