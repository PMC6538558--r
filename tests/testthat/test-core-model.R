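test_that("knowledge units are validated at construction", {
  brca1 <- mkGene("ENSG00000012048", "protein", "ENSP00000312236")
  bap1 <- mkGene("unverified:BAP1", "protein")
  ku <- KnowledgeUnit(brca1, "undirected link", bap1,
                      references = Reference("database", "BioGrid"))
  expect_s4_class(ku, "KnowledgeUnit")
  # asymmetric specification detail is preserved
  expect_equal(isoform(cores(kuSubject(ku))[[1]]), "ENSP00000312236")
  expect_null(isoform(cores(kuObject(ku))[[1]]))

  # multi-core subject: a protein complex
  complexSubj <- Entity(list(mkGene("ENSG00000110092", "protein"),
                             mkGene("ENSG00000135446", "protein")))
  ku2 <- KnowledgeUnit(complexSubj, "directed link",
                       mkGene("unverified:RB1", "protein"),
                       references = Reference("database", "KEGG"))
  expect_length(cores(kuSubject(ku2)), 2)

  # raw text is not a controlled predicate
  expect_error(KnowledgeUnit(brca1, "upregulates", bap1,
                             references = Reference("database", "KEGG")),
               "vocabulary error")
  # references are mandatory
  expect_error(KnowledgeUnit(brca1, "undirected link", bap1),
               "reference")
  # an entity must have at least one core
  expect_error(Entity(list()), "at least one core")
  # molecular specification only on gene cores
  expect_error(EntityCore("CIDs00005870", "compound",
                          moleculeType = "protein"),
               "specification error")
  # isoforms are transcript/protein-level concepts
  expect_error(MolecularSpecification("DNA", isoform = "ENST00000354071"),
               "specification error")
  expect_error(MolecularSpecification("unspecified",
                                      isoform = "ENSP00000312236"),
               "specification error")
  # evidence scores must carry their type tag
  expect_error(KnowledgeUnit(brca1, "undirected link", bap1,
                             references = Reference("database", "KEGG"),
                             evidenceScore = 0.9),
               "discrete")
})

test_that("entity core equality is exact and modification-sensitive", {
  plain <- mkGene("ENSG00000012048", "protein", "ENSP00000312236")
  phos <- mkGene("ENSG00000012048", "protein", "ENSP00000312236",
                 "phosphorylated")
  expect_false(entityCoreEquals(plain, phos))
  expect_true(entityCoreEquals(plain,
                               mkGene("ENSG00000012048", "protein",
                                      "ENSP00000312236")))
  # asymmetric field presence under the exact-match rule
  noIso <- mkGene("ENSG00000012048", "protein")
  expect_false(entityCoreEquals(noIso, plain))
  # stated vs absent specification differ
  expect_false(entityCoreEquals(mkGene("ENSG00000012048"),
                                mkGene("ENSG00000012048", "protein")))
})

test_that("entity equality uses core multisets and slot-wise anatomy", {
  a <- mkGene("unverified:LH", "protein")
  ovaryOnly <- Entity(a, AnatomicalContext(organ = "D010053"))
  ovaryCell <- Entity(a, AnatomicalContext(organ = "D010053",
                                           cell = "D006107"))
  expect_false(entityEquals(ovaryOnly, ovaryCell))
  # subject located in the pituitary vs the same subject with no anatomy
  pituitary <- Entity(a, AnatomicalContext(organ = "D010902"))
  bare <- Entity(a)
  expect_false(entityEquals(pituitary, bare))
  expect_equal(entityEquals(pituitary, bare),
               entityEqualsOracle(pituitary, bare))
  # core order is irrelevant, the multiset decides
  c1 <- mkGene("ENSG00000110092", "protein")
  c2 <- mkGene("ENSG00000135446", "protein")
  expect_true(entityEquals(Entity(list(c1, c2)), Entity(list(c2, c1))))
  expect_false(entityEquals(Entity(list(c1, c1)), Entity(list(c1, c2))))
})

test_that("equality agrees with the slot-walking oracle on random entities", {
  set.seed(7)
  pool <- list()
  for (i in 1:40) {
    d <- randomDocument(1)
    pool[[2 * i - 1]] <- kuSubject(knowledgeUnits(d)[[1]])
    pool[[2 * i]] <- kuObject(knowledgeUnits(d)[[1]])
  }
  for (i in 1:150) {
    a <- pool[[sample.int(length(pool), 1)]]
    b <- pool[[sample.int(length(pool), 1)]]
    expect_identical(entityEquals(a, b), entityEqualsOracle(a, b))
  }
  # reflexivity, symmetry on the whole pool
  for (e in pool) expect_true(entityEquals(e, e))
})

test_that("canonical keys cover exactly the duplicate-relevant fields", {
  esr1 <- mkGene("unverified:ESR1", "protein")
  ccnd1 <- mkGene("ENSG00000110092", "RNA")
  base <- function(ref, env = list(), raw = NULL, score = NULL, st = NULL)
    KnowledgeUnit(esr1, "activation by increase", ccnd1,
                  predicateInReference = raw,
                  environmentalContexts = env, references = ref,
                  evidenceScore = score, evidenceType = st)
  kegg <- base(Reference("database", "KEGG"))
  pubmed <- base(Reference("literature", "PubMed"), raw = "express",
                 score = 0.7, st = "continuous")
  # provenance, raw predicate and evidence are not part of the key
  expect_identical(kuCanonicalKey(kegg), kuCanonicalKey(pubmed))
  expect_identical(kuCanonicalKey(kegg), kuCanonicalKey(kegg))
  # a disease context distinguishes the event from the normal condition
  cancer <- base(Reference("database", "KEGG"),
                 env = list(EnvironmentalContext("phenotype", "C0678222")))
  expect_false(kuCanonicalKey(kegg) == kuCanonicalKey(cancer))
  # species is part of the key
  mouse <- KnowledgeUnit(esr1, "activation by increase", ccnd1,
                         species = "mouse",
                         references = Reference("database", "KEGG"))
  expect_false(kuCanonicalKey(kegg) == kuCanonicalKey(mouse))
})

test_that("canonical keys match an exhaustive field-comparison oracle", {
  set.seed(11)
  kus <- list()
  for (i in 1:12) kus <- c(kus, knowledgeUnits(randomDocument(3)))
  kuEqualsOracle <- function(a, b)
    entityEqualsOracle(kuSubject(a), kuSubject(b)) &&
    entityEqualsOracle(kuObject(a), kuObject(b)) &&
    identical(predicate(a), predicate(b)) &&
    identical(species(a), species(b)) &&
    setequal(vapply(environmentalContexts(a), canonicalKey, character(1)),
             vapply(environmentalContexts(b), canonicalKey, character(1)))
  for (i in 1:200) {
    a <- kus[[sample.int(length(kus), 1)]]
    b <- kus[[sample.int(length(kus), 1)]]
    expect_identical(kuCanonicalKey(a) == kuCanonicalKey(b),
                     kuEqualsOracle(a, b))
  }
})

test_that("modification sets are canonical under input order and synonyms", {
  perms <- list(c("phosphorylated", "methylated"),
                c("methylated", "phosphorylated"),
                c("methylation", "phosphorylation"),
                c("Phosphorylated", "methylated", "phosphorylated"))
  keys <- vapply(perms, function(p)
    canonicalKey(mkGene("ENSG00000012048", "protein", mods = p)),
    character(1))
  expect_length(unique(keys), 1)
  expect_equal(modifications(mkGene("ENSG00000012048", "protein",
                                    mods = perms[[3]])),
               c("methylated", "phosphorylated"))
})
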