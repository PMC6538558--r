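test_that("signed causal units become Control interactions", {
  ku <- mkKu(mkGene("unverified:ESR1", "protein"), "activation by increase",
             mkGene("ENSG00000110092"))
  res <- toBiopax(CodamlDocument(ku))
  owl <- xml2::read_xml(res$owl)
  controls <- xml2::xml_find_all(owl, "//*[local-name()='Control']")
  expect_length(controls, 1)
  expect_equal(xml2::xml_text(xml2::xml_find_first(
    controls[[1]], "./*[local-name()='controlType']")), "ACTIVATION")
  # two physical entities, each with an entity reference
  expect_length(xml2::xml_find_all(owl, "//*[local-name()='Protein']"), 2)
  expect_equal(res$report$status[res$report$construct == "ku"], "converted")
})

test_that("missing interaction is declared lossy; empty documents convert", {
  mi <- mkKu(mkGene("unverified:A", "protein"), "missing interaction",
             mkGene("unverified:B", "protein"),
             env = list(EnvironmentalContext("phenotype", "C0678222")))
  res <- toBiopax(CodamlDocument(mi))
  owl <- xml2::read_xml(res$owl)
  expect_length(xml2::xml_find_all(
    owl, "//*[local-name()='Control' or local-name()='MolecularInteraction']"),
    0)
  kuRows <- res$report[res$report$construct == "ku", ]
  expect_equal(kuRows$status, "skipped")

  emptyRes <- toBiopax(CodamlDocument())
  expect_silent(xml2::read_xml(emptyRes$owl))
  expect_equal(nrow(emptyRes$report), 0)
})

test_that("inverse mapping restores predicates from controlType", {
  inh <- mkKu(mkGene("unverified:A", "protein"), "inhibition by decrease",
              mkGene("unverified:B", "protein"))
  back <- fromBiopax(toBiopax(CodamlDocument(inh))$owl)
  expect_equal(predicate(knowledgeUnits(back$document)[[1]]), "reduction")

  bare <- mkKu(mkGene("unverified:A", "protein"), "directed link",
               mkGene("unverified:B", "protein"))
  back2 <- fromBiopax(toBiopax(CodamlDocument(bare))$owl)
  expect_equal(predicate(knowledgeUnits(back2$document)[[1]]),
               "directed link")
})

test_that("a biochemical reaction imports as a multi-core directed link", {
  # hand-written reaction in the style Estrone + H + NADPH <=> Estradiol + NADP
  owl <- paste0(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" ',
    'xmlns:bp="http://www.biopax.org/release/biopax-level3.owl#">',
    paste0('<bp:SmallMolecule rdf:ID="PE', 1:5, '">',
           '<bp:displayName>', c("CIDs00005870", "CIDs00001038",
                                 "CIDs22833512", "CIDs00005757",
                                 "CIDs00005886"), '</bp:displayName>',
           '</bp:SmallMolecule>', collapse = ""),
    '<bp:BiochemicalReaction rdf:ID="RXN1">',
    '<bp:left rdf:resource="#PE1"/><bp:left rdf:resource="#PE2"/>',
    '<bp:left rdf:resource="#PE3"/>',
    '<bp:right rdf:resource="#PE4"/><bp:right rdf:resource="#PE5"/>',
    '</bp:BiochemicalReaction></rdf:RDF>')
  res <- fromBiopax(owl)
  kus <- knowledgeUnits(res$document)
  expect_length(kus, 1)
  expect_equal(predicate(kus[[1]]), "directed link")
  expect_setequal(vapply(cores(kuSubject(kus[[1]])), coreId, character(1)),
                  c("CIDs00005870", "CIDs00001038", "CIDs22833512"))
  expect_setequal(vapply(cores(kuObject(kus[[1]])), coreId, character(1)),
                  c("CIDs00005757", "CIDs00005886"))
  expect_true(all(vapply(cores(kuSubject(kus[[1]])), coreType,
                         character(1)) == "compound"))
})

test_that("round-trip preserves cores, types, predicate family, anatomy", {
  famSig <- function(doc) lapply(knowledgeUnits(doc), function(ku)
    list(s = canonicalKey(kuSubject(ku)),
         fam = predicateFamily(predicate(ku)),
         o = canonicalKey(kuObject(ku)),
         env = vapply(environmentalContexts(ku), canonicalKey, character(1)),
         sp = species(ku)))
  for (seed in 1:25) {
    d <- randomDocument(nKU = 5, seed = 3000 + seed, biopaxSafe = TRUE)
    res <- toBiopax(d)
    back <- fromBiopax(res$owl)
    expect_identical(famSig(back$document), famSig(d))
    # report accounting: every construct appears exactly once
    nKU <- length(knowledgeUnits(d))
    nRef <- sum(vapply(knowledgeUnits(d), function(k)
      length(references(k)), integer(1)))
    nEnv <- sum(vapply(knowledgeUnits(d), function(k)
      length(environmentalContexts(k)), integer(1)))
    nScore <- sum(vapply(knowledgeUnits(d), function(k)
      length(k@evidenceScore) > 0, logical(1)))
    expect_equal(nrow(res$report), nKU + nRef + nEnv + nScore)
    expect_equal(sum(res$report$construct == "ku"), nKU)
  }
})

test_that("constructs outside the subset are reported and skipped", {
  owl <- paste0(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" ',
    'xmlns:bp="http://www.biopax.org/release/biopax-level3.owl#">',
    '<bp:Pathway rdf:ID="P1"/>',
    '</rdf:RDF>')
  res <- fromBiopax(owl)
  expect_length(knowledgeUnits(res$document), 0)
  expect_equal(res$report$construct, "Pathway")
  expect_equal(res$report$status, "skipped")
})

test_that("SIF export emits one deterministic line per unit", {
  gen <- exampleModel("genistein")
  lines <- toSIF(gen)
  expect_length(lines, 5)
  expect_true(all(vapply(strsplit(lines, "\t"), length, integer(1)) == 3))
  expect_identical(toSIF(gen), lines)
  expect_length(toSIF(CodamlDocument()), 0)
  for (seed in c(4, 12)) {
    d <- randomDocument(nKU = 17, seed = seed)
    expect_length(toSIF(d), 17)
  }
})
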