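# Independent oracles used by the property and equivalence tests. These
# deliberately avoid the package's bucketed/keyed code paths: entity
# comparison walks slots recursively, and conflict detection is a plain
# O(n^2) pairwise scan with its own inlined sign table.

# recursive slot-by-slot entity comparison (no canonical keys)
specEqualsOracle <- function(a, b) {
  if (is.null(a) || is.null(b)) return(is.null(a) && is.null(b))
  identical(a@moleculeType, b@moleculeType) &&
    identical(sort(a@isoform), sort(b@isoform)) &&
    identical(sort(a@modifications), sort(b@modifications))
}

coreEqualsOracle <- function(a, b)
  identical(a@coreId, b@coreId) && identical(a@coreType, b@coreType) &&
  specEqualsOracle(a@spec, b@spec)

entityEqualsOracle <- function(a, b) {
  if (length(a@cores) != length(b@cores)) return(FALSE)
  for (s in c("organ", "tissue", "cell"))
    if (!identical(slot(a@anatomy, s), slot(b@anatomy, s))) return(FALSE)
  # multiset match: greedy pairing
  unused <- rep(TRUE, length(b@cores))
  for (ca in a@cores) {
    hit <- FALSE
    for (j in seq_along(b@cores)) {
      if (unused[j] && coreEqualsOracle(ca, b@cores[[j]])) {
        unused[j] <- FALSE; hit <- TRUE; break
      }
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

# O(n^2) pairwise conflict scan with inlined semantics
.oracleSigns <- c(
  "directed link" = "unsigned", "induction" = "positive",
  "reduction" = "negative", "activation by increase" = "positive",
  "activation by decrease" = "positive", "inhibition by increase" = "negative",
  "inhibition by decrease" = "negative", "undirected link" = "unsigned",
  "positive correlation" = "positive", "negative correlation" = "negative",
  "missing interaction" = "unsigned")
.oracleUndirected <- c("undirected link", "positive correlation",
                       "negative correlation")

oracleContradictory <- function(a, b) {
  mi <- c(a, b) == "missing interaction"
  if (xor(mi[1], mi[2])) {
    other <- if (mi[1]) b else a
    return(.oracleSigns[other] != "unsigned" || other == "directed link")
  }
  if (any(mi)) return(FALSE)
  .oracleSigns[a] != "unsigned" && .oracleSigns[b] != "unsigned" &&
    .oracleSigns[a] != .oracleSigns[b]
}

oracleConflictPairs <- function(units) {
  n <- length(units)
  out <- matrix(character(0), ncol = 2)
  if (n < 2) return(out)
  sk <- vapply(units, function(u) canonicalKey(kuSubject(u)), character(1))
  ok <- vapply(units, function(u) canonicalKey(kuObject(u)), character(1))
  ek <- vapply(units, function(u)
    paste(sort(vapply(environmentalContexts(u), canonicalKey, character(1))),
          collapse = ";"), character(1))
  sp <- vapply(units, species, character(1))
  pr <- vapply(units, predicate, character(1))
  und <- pr %in% .oracleUndirected
  keys <- vapply(units, canonicalKey, character(1))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (sp[i] != sp[j] || ek[i] != ek[j]) next
      if (!oracleContradictory(pr[i], pr[j])) next
      same <- sk[i] == sk[j] && ok[i] == ok[j]
      swapped <- und[i] && und[j] && sk[i] == ok[j] && ok[i] == sk[j]
      if (same || swapped) out <- rbind(out, c(keys[i], keys[j]))
    }
  }
  out
}

# connected components over the oracle pairs, as a sorted set-of-sets
oracleConflictGroups <- function(units) {
  pairs <- oracleConflictPairs(units)
  if (!nrow(pairs)) return(character(0))
  verts <- unique(c(pairs))
  comp <- stats::setNames(seq_along(verts), verts)
  for (r in seq_len(nrow(pairs))) {
    a <- comp[pairs[r, 1]]; b <- comp[pairs[r, 2]]
    if (a != b) comp[comp == b] <- a
  }
  # duplicate keys in the input must appear with multiplicity
  keys <- vapply(units, canonicalKey, character(1))
  groups <- vapply(split(names(comp), comp), function(members) {
    expanded <- keys[keys %in% members]
    paste(sort(expanded), collapse = " / ")
  }, character(1))
  sort(unname(groups))
}

groupSetOf <- function(conflictGroups)
  sort(vapply(conflictGroups, function(g)
    paste(sort(g@memberKeys), collapse = " / "), character(1)))

# quick builders
mkGene <- function(id, mt = NULL, iso = NULL, mods = NULL) {
  if (is.null(mt) && is.null(iso) && is.null(mods))
    EntityCore(id, "gene")
  else
    EntityCore(id, "gene", moleculeType = mt %||% "unspecified",
               isoform = iso, modifications = mods)
}

mkKu <- function(subj, pred, obj, env = list(), anatS = AnatomicalContext(),
                 anatO = AnatomicalContext(), score = NULL, stype = NULL,
                 ref = Reference("database", "KEGG"), species = "Homo sapiens") {
  if (is(subj, "EntityCore")) subj <- Entity(subj, anatS)
  if (is(obj, "EntityCore")) obj <- Entity(obj, anatO)
  KnowledgeUnit(subj, pred, obj, environmentalContexts = env,
                species = species, references = ref,
                evidenceScore = score, evidenceType = stype)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# conflict-prone unit sampler: a deliberately small entity/context space so
# that signature collisions (and hence genuine conflicts) are frequent
randomConflictUnits <- function(n, seed) {
  set.seed(seed)
  genes <- sprintf("ENSG%011d", 1:12)
  organs <- c("D010053", "D010902")
  ref <- Reference("database", "KEGG")
  terms <- predicateTerms()
  lapply(seq_len(n), function(i) {
    anatS <- if (runif(1) < 0.4)
      AnatomicalContext(organ = sample(organs, 1)) else AnatomicalContext()
    anatO <- if (runif(1) < 0.4)
      AnatomicalContext(organ = sample(organs, 1)) else AnatomicalContext()
    env <- if (runif(1) < 0.3)
      list(EnvironmentalContext("phenotype", "C0678222")) else list()
    mkKu(Entity(EntityCore(sample(genes, 1), "gene"), anatS),
         sample(terms, 1),
         Entity(EntityCore(sample(genes, 1), "gene"), anatO),
         env = env, ref = ref)
  })
}
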