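test_that("serialization is canonical and round-trips the data model", {
  # inter-anatomical worked example: asymmetric subject/object anatomy
  lh <- KnowledgeUnit(
    Entity(mkGene("unverified:LH", "protein"),
           AnatomicalContext(organ = "D010902")),
    "activation by increase",
    Entity(EntityCore("unverified:estrogen", "compound"),
           AnatomicalContext(organ = "D010053", cell = "D006107")),
    predicateInReference = "induce",
    references = Reference("literature", "PubMed"))
  doc <- CodamlDocument(lh, creationDate = "2020-01-01")
  xmlText <- writeDocument(doc)
  back <- parseDocument(xmlText)
  sub <- kuSubject(knowledgeUnits(back)[[1]])
  obj <- kuObject(knowledgeUnits(back)[[1]])
  expect_equal(anatomy(sub)@organ, "D010902")
  expect_equal(anatomy(obj)@organ, "D010053")
  expect_length(anatomy(obj)@tissue, 0)
  expect_equal(anatomy(obj)@cell, "D006107")
  expect_identical(back, doc)
  # determinism: same document serializes byte-identically
  expect_identical(writeDocument(doc), xmlText)
  expect_identical(writeDocument(back), xmlText)
})

test_that("empty documents and multi-reference units serialize correctly", {
  empty <- CodamlDocument()
  xmlText <- writeDocument(empty)
  expect_length(knowledgeUnits(parseDocument(xmlText)), 0)

  twoRefs <- mkKu(mkGene("unverified:ESR1", "protein"),
                  "activation by increase",
                  mkGene("ENSG00000110092", "RNA"),
                  ref = list(
                    Reference("database", "KEGG", "manually curated data",
                              "http://www.genome.jp/kegg-bin/show_pathway?hsa05224",
                              "2017", "2018"),
                    Reference("literature", "PubMed", "reported event")))
  xml2doc <- xml2::read_xml(writeDocument(CodamlDocument(twoRefs)))
  refNodes <- xml2::xml_find_all(xml2doc, "//reference")
  expect_length(refNodes, 2)
  # the database reference carries all six fields
  expect_length(xml2::xml_children(refNodes[[1]]), 6)
  expect_equal(xml2::xml_text(xml2::xml_find_first(refNodes[[1]], "./name")),
               "KEGG")
})

test_that("random documents round-trip structurally and byte-canonically", {
  for (seed in 1:40) {
    d <- randomDocument(nKU = 4, seed = seed)
    x <- writeDocument(d)
    back <- parseDocument(x)
    expect_identical(back, d)
    expect_identical(writeDocument(back), x)
  }
})

test_that("schema catches unknown elements; strictness controls severity", {
  good <- writeDocument(exampleModel("cisplatin_gemcitabine"))
  bad <- sub("<species>", "<wingspan>w</wingspan><species>", good)
  expect_error(parseDocument(bad, strict = TRUE), "schema violation")
  expect_warning(parseDocument(bad, strict = FALSE), "schema violation")

  # a raw predicate term is a validation issue, not a crash, in lenient mode
  raw <- sub("<predicate>activation by increase</predicate>",
             "<predicate>up-regulate</predicate>", good, fixed = TRUE)
  expect_warning(lenientDoc <- parseDocument(raw, strict = FALSE),
                 "error-severity")
  issues <- validateDocument(lenientDoc)
  expect_true("predicate.controlled" %in% issues$rule)
  expect_error(parseDocument(raw, strict = TRUE), "predicate.controlled")
})

test_that("every model invariant maps to exactly one rule id", {
  okRef <- list(new("Reference", referenceType = "database", name = "KEGG"))
  okCore <- function() new("EntityCore", coreId = "ENSG00000012048",
                           coreType = "gene", spec = NULL)
  okEnt <- function() new("Entity", cores = list(okCore()),
                          anatomy = new("AnatomicalContext"))
  mk <- function(tweak) {
    ku <- new("KnowledgeUnit", subject = okEnt(),
              predicate = "directed link", object = okEnt(),
              predicateInReference = character(0),
              environmentalContexts = list(), species = "Homo sapiens",
              references = okRef, evidenceScore = numeric(0),
              evidenceType = character(0))
    tweak(ku)
  }
  cases <- list(
    predicate.controlled = mk(function(k) { k@predicate <- "binds"; k }),
    entity.empty_cores = mk(function(k) { k@subject@cores <- list(); k }),
    core.id_empty = mk(function(k) { k@subject@cores[[1]]@coreId <- ""; k }),
    core.type = mk(function(k) { k@subject@cores[[1]]@coreType <- "organ"; k }),
    core.spec_on_non_gene = mk(function(k) {
      k@subject@cores[[1]]@coreId <- "CIDs00005870"
      k@subject@cores[[1]]@coreType <- "compound"
      k@subject@cores[[1]]@spec <- new("MolecularSpecification",
                                       moleculeType = "protein",
                                       isoform = character(0),
                                       modifications = character(0)); k }),
    spec.molecule_type = mk(function(k) {
      k@subject@cores[[1]]@spec <- new("MolecularSpecification",
                                       moleculeType = "peptide",
                                       isoform = character(0),
                                       modifications = character(0)); k }),
    spec.isoform_molecule_type = mk(function(k) {
      k@subject@cores[[1]]@spec <- new("MolecularSpecification",
                                       moleculeType = "DNA",
                                       isoform = "ENST00000354071",
                                       modifications = character(0)); k }),
    context.type = mk(function(k) {
      k@environmentalContexts <- list(new("EnvironmentalContext",
                                          contextType = "weather",
                                          contextId = "C0678222")); k }),
    context.id_empty = mk(function(k) {
      k@environmentalContexts <- list(new("EnvironmentalContext",
                                          contextType = "phenotype",
                                          contextId = "")); k }),
    species.empty = mk(function(k) { k@species <- ""; k }),
    reference.missing = mk(function(k) { k@references <- list(); k }),
    reference.type = mk(function(k) {
      k@references[[1]]@referenceType <- "hearsay"; k }),
    reference.name_empty = mk(function(k) { k@references[[1]]@name <- ""; k }),
    evidence.type_tag = mk(function(k) { k@evidenceScore <- 0.5; k }))
  for (rule in names(cases)) {
    issues <- validateDocument(new("CodamlDocument",
                                   knowledgeUnits = list(cases[[rule]]),
                                   formatVersion = "1.0",
                                   creationDate = character(0)),
                               strict = TRUE)
    errs <- issues[issues$severity == "error", ]
    expect_equal(nrow(errs), 1, info = rule)
    expect_equal(errs$rule, rule)
  }
})

test_that("lenient rules: context-free units pass, hierarchy gaps warn", {
  clean <- mkKu(mkGene("ENSG00000012048", "protein"), "undirected link",
                mkGene("ENSG00000110092", "protein"))
  expect_equal(nrow(validateDocument(CodamlDocument(clean))), 0)

  gap <- mkKu(Entity(mkGene("ENSG00000012048", "protein"),
                     AnatomicalContext(cell = "D006107")),
              "undirected link", mkGene("ENSG00000110092", "protein"))
  issues <- validateDocument(CodamlDocument(gap), strict = TRUE)
  expect_equal(issues$rule, "anatomy.hierarchy_gap")
  expect_equal(issues$severity, "warning")

  # identifier-pattern failures: error in strict mode, warning in lenient
  odd <- mkKu(mkGene("BRCA1", "protein"), "undirected link",
              mkGene("ENSG00000110092", "protein"))
  strictIssues <- validateDocument(CodamlDocument(odd), strict = TRUE)
  lenientIssues <- validateDocument(CodamlDocument(odd), strict = FALSE)
  expect_equal(strictIssues$rule, "identifier.pattern")
  expect_equal(strictIssues$severity, "error")
  expect_equal(lenientIssues$severity, "warning")
})
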