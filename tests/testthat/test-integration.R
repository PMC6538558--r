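esr1ccnd1 <- function(ref, env = list())
  mkKu(mkGene("unverified:ESR1", "protein"), "activation by increase",
       mkGene("ENSG00000110092", "RNA"), env = env, ref = ref)

test_that("duplicates across sources merge with concatenated references", {
  a <- CodamlDocument(esr1ccnd1(Reference("database", "KEGG")))
  b <- CodamlDocument(esr1ccnd1(Reference("literature", "PubMed")))
  m <- integrateModels(list(kegg = a, lit = b))
  expect_length(knowledgeUnits(m), 1)
  expect_length(references(knowledgeUnits(m)[[1]]), 2)
  expect_setequal(names(m@provenance), c("kegg", "lit"))
  expect_length(m@conflicts, 0)

  # single-source integration is the identity
  one <- integrateModels(list(only = a))
  expect_length(knowledgeUnits(one), 1)
  expect_length(one@conflicts, 0)
})

test_that("context distinguishes events: no conflict across contexts", {
  # same triple, opposite signs, but one holds under breast cancer and the
  # other under the normal condition: two distinct units, no conflict
  cancer <- esr1ccnd1(Reference("database", "KEGG"),
                      env = list(EnvironmentalContext("phenotype",
                                                      "C0678222")))
  normalOpposite <- mkKu(mkGene("unverified:ESR1", "protein"),
                         "inhibition by increase",
                         mkGene("ENSG00000110092", "RNA"))
  m <- integrateModels(list(x = CodamlDocument(cancer),
                            y = CodamlDocument(normalOpposite)))
  expect_length(knowledgeUnits(m), 2)
  expect_length(m@conflicts, 0)

  # anatomy also distinguishes: lung vs liver
  lung <- mkKu(Entity(mkGene("unverified:A", "protein"),
                      AnatomicalContext(organ = "D008168")),
               "induction", mkGene("unverified:B", "protein"))
  liver <- mkKu(Entity(mkGene("unverified:A", "protein"),
                       AnatomicalContext(organ = "D008099")),
                "reduction", mkGene("unverified:B", "protein"))
  expect_length(findConflicts(list(lung, liver)), 0)

  # identical signature with opposite signs does conflict
  x <- mkKu(mkGene("unverified:A", "protein"), "activation by increase",
            mkGene("unverified:B", "protein"))
  y <- mkKu(mkGene("unverified:A", "protein"), "inhibition by increase",
            mkGene("unverified:B", "protein"))
  groups <- findConflicts(list(x, y))
  expect_length(groups, 1)
  expect_length(groups[[1]]@memberKeys, 2)

  # direction matters for causal predicates: A->B vs B->A is not a conflict
  yRev <- mkKu(mkGene("unverified:B", "protein"), "inhibition by increase",
               mkGene("unverified:A", "protein"))
  expect_length(findConflicts(list(x, yRev)), 0)
  # but undirected-family pairs match symmetrically
  pc <- mkKu(mkGene("unverified:A", "protein"), "positive correlation",
             mkGene("unverified:B", "protein"))
  ncRev <- mkKu(mkGene("unverified:B", "protein"), "negative correlation",
                mkGene("unverified:A", "protein"))
  expect_length(findConflicts(list(pc, ncRev)), 1)
})

test_that("conflict detection equals the O(n^2) brute-force scan", {
  nonTrivial <- 0
  for (seed in 1:8) {
    units <- randomConflictUnits(120, seed = 1000 + seed)
    got <- groupSetOf(findConflicts(units))
    expect_identical(got, oracleConflictGroups(units))
    nonTrivial <- nonTrivial + length(got)
  }
  expect_gt(nonTrivial, 0)  # the comparison must exercise real conflicts
  # sparse random documents are mostly conflict-free; agreement must hold too
  for (seed in 1:3) {
    units <- knowledgeUnits(randomDocument(nKU = 60, seed = 1000 + seed))
    expect_identical(groupSetOf(findConflicts(units)),
                     oracleConflictGroups(units))
  }
})

test_that("integration is idempotent and source-order invariant", {
  corpus <- generateCorpus(GeneratorConfig(nModels = 3, kusPerModel = 25,
                                           duplicateRate = 0.2,
                                           contradictions = 3, seed = 5))
  m <- integrateModels(corpus$documents)
  again <- integrateModels(list(unified = asDocument(m)))
  expect_setequal(again@keys, m@keys)
  expect_identical(groupSetOf(again@conflicts), groupSetOf(m@conflicts))

  perm <- integrateModels(rev(corpus$documents))
  expect_setequal(perm@keys, m@keys)
  expect_identical(groupSetOf(perm@conflicts), groupSetOf(m@conflicts))

  # reference conservation: nothing is lost in merging
  refCount <- function(docs) sum(vapply(docs, function(d)
    sum(vapply(knowledgeUnits(d), function(k) length(references(k)),
               integer(1))), integer(1)))
  expect_equal(sum(vapply(knowledgeUnits(m), function(k)
    length(references(k)), integer(1))),
    refCount(corpus$documents))
})

test_that("resolution strategies behave as declared", {
  hi <- mkKu(mkGene("unverified:A", "protein"), "induction",
             mkGene("unverified:B", "protein"), score = 0.9,
             stype = "continuous", ref = Reference("database", "KEGG"))
  lo <- mkKu(mkGene("unverified:A", "protein"), "reduction",
             mkGene("unverified:B", "protein"), score = 0.2,
             stype = "continuous", ref = Reference("database", "STRING"))
  m <- integrateModels(list(a = CodamlDocument(hi), b = CodamlDocument(lo)))
  expect_length(m@conflicts, 1)

  flagged <- resolveConflicts(m, "keep_all_flagged")
  expect_length(knowledgeUnits(flagged), 2)
  expect_equal(flagged@conflicts[[1]]@status, "resolved")

  pref <- resolveConflicts(m, "prefer_higher_evidence")
  kept <- knowledgeUnits(asDocument(pref))
  expect_length(kept, 1)
  expect_equal(predicate(kept[[1]]), "induction")

  # generalization to the least common ancestor
  abi <- mkKu(mkGene("unverified:A", "protein"), "activation by increase",
              mkGene("unverified:B", "protein"),
              ref = Reference("database", "KEGG"))
  ibi <- mkKu(mkGene("unverified:A", "protein"), "inhibition by increase",
              mkGene("unverified:B", "protein"),
              ref = Reference("database", "STRING"))
  m2 <- integrateModels(list(a = CodamlDocument(abi),
                             b = CodamlDocument(ibi)))
  gen <- resolveConflicts(m2, "generalize_to_lca")
  expect_length(knowledgeUnits(gen), 1)
  expect_equal(predicate(knowledgeUnits(gen)[[1]]), "directed link")
  expect_length(references(knowledgeUnits(gen)[[1]]), 2)

  # cross-family conflicts have no LCA and stay open
  mi <- mkKu(mkGene("unverified:A", "protein"), "missing interaction",
             mkGene("unverified:B", "protein"),
             ref = Reference("database", "KEGG"))
  pc <- mkKu(mkGene("unverified:A", "protein"), "positive correlation",
             mkGene("unverified:B", "protein"),
             ref = Reference("database", "STRING"))
  m3 <- integrateModels(list(a = CodamlDocument(mi),
                             b = CodamlDocument(pc)))
  expect_length(m3@conflicts, 1)
  expect_warning(gen3 <- resolveConflicts(m3, "generalize_to_lca"), "no LCA")
  expect_equal(gen3@conflicts[[1]]@status, "open")

  # mixed score types: prefer_higher_evidence keeps all and stays open
  disc <- mkKu(mkGene("unverified:A", "protein"), "reduction",
               mkGene("unverified:C", "protein"), score = 3,
               stype = "discrete", ref = Reference("database", "KEGG"))
  cont <- mkKu(mkGene("unverified:A", "protein"), "induction",
               mkGene("unverified:C", "protein"), score = 0.4,
               stype = "continuous", ref = Reference("database", "STRING"))
  m4 <- integrateModels(list(a = CodamlDocument(disc),
                             b = CodamlDocument(cont)))
  pref4 <- resolveConflicts(m4, "prefer_higher_evidence")
  expect_length(knowledgeUnits(asDocument(pref4)), 2)
  expect_equal(pref4@conflicts[[1]]@status, "open")
})

test_that("graph export has one node per (cores, anatomy) pair", {
  doc <- exampleModel("genistein")
  g <- toGraph(doc)
  expect_equal(igraph::vcount(g), 6)
  expect_equal(igraph::ecount(g), 5)
  expect_equal(sum(igraph::E(g)$undirected), 1)  # the binding step

  # brute-force node count on random documents
  for (seed in c(2, 9)) {
    d <- randomDocument(nKU = 30, seed = seed)
    ents <- unlist(lapply(knowledgeUnits(d), function(k)
      list(kuSubject(k), kuObject(k))), recursive = FALSE)
    want <- length(unique(vapply(ents, canonicalKey, character(1))))
    expect_equal(igraph::vcount(toGraph(d)), want)
    expect_equal(igraph::ecount(toGraph(d)), 30)
  }

  expect_equal(igraph::vcount(toGraph(CodamlDocument())), 0)

  # complex-as-node vs exploded per-core view
  complexDoc <- CodamlDocument(mkKu(
    Entity(list(mkGene("ENSG00000110092", "protein"),
                mkGene("ENSG00000135446", "protein"))),
    "directed link", mkGene("unverified:RB1", "protein")))
  expect_equal(igraph::vcount(toGraph(complexDoc)), 2)
  expect_equal(igraph::vcount(toGraph(complexDoc, explodeComplexes = TRUE)), 3)
  expect_equal(igraph::ecount(toGraph(complexDoc, explodeComplexes = TRUE)), 2)
})
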