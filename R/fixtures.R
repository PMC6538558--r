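# Packaged example models. Identifiers printed in the source descriptions
# are used verbatim (ENSG00000012048, ENSP00000312236, D010902, D010053,
# D006107, C0678222, CLO0007606, CIDs000058xx...); entities known only by
# symbol carry "unverified:" placeholder identifiers, since inventing real
# accessions would be fabrication. All models validate with zero errors.

.keggRef <- function()
  Reference("database", "KEGG", "manually curated data",
            "http://www.genome.jp/kegg-bin/show_pathway?hsa05224",
            "2017", "2018")

.litRef <- function(desc = "reported biological event")
  Reference("literature", "PubMed", desc)

.gene <- function(id, mt = "protein", iso = NULL, mods = NULL)
  EntityCore(id, "gene", moleculeType = mt, isoform = iso,
             modifications = mods)

.methodWorkedExamples <- function() {
  kus <- list(
    # BRCA1 isoform-specified protein physically interacts with BAP1 protein
    # whose isoform is not specified: asymmetric specification detail
    KnowledgeUnit(
      .gene("ENSG00000012048", iso = "ENSP00000312236"), "undirected link",
      .gene("unverified:BAP1"),
      predicateInReference = "physically interact",
      references = .litRef("BRCA1-BAP1 physical interaction")),
    # intra-anatomical event: LHCGR relates to follicle growth, both in ovary
    KnowledgeUnit(
      Entity(.gene("unverified:LHCGR"),
             AnatomicalContext(organ = "D010053")),
      "undirected link",
      Entity(EntityCore("unverified:primary_follicle_growth",
                        "biological_process"),
             AnatomicalContext(organ = "D010053")),
      predicateInReference = "related to",
      references = .litRef("LHCGR and primary follicle growth in the ovary")),
    # inter-anatomical event: pituitary LH induces estrogen in ovarian
    # granulosa cells; subject and object carry different contexts
    KnowledgeUnit(
      Entity(.gene("unverified:LH"),
             AnatomicalContext(organ = "D010902")),
      "activation by increase",
      Entity(EntityCore("unverified:estrogen", "compound"),
             AnatomicalContext(organ = "D010053", cell = "D006107")),
      predicateInReference = "induce",
      references = .litRef("LH induces estrogen production")),
    # context-free protein-protein interaction
    KnowledgeUnit(
      .gene("unverified:ESR1"), "undirected link", .gene("ENSG00000012048"),
      predicateInReference = "physically interact",
      references = .litRef("ESR1-BRCA1 physical interaction")),
    # molecule-phenotype association without anatomical contexts
    KnowledgeUnit(
      .gene("unverified:ESR1"), "undirected link",
      EntityCore("C0678222", "phenotype"),
      predicateInReference = "marker or mechanism",
      references = .litRef("ESR1 as breast cancer marker")),
    # environmental context distinguishes the disease condition
    KnowledgeUnit(
      .gene("unverified:ESR1"), "activation by increase",
      .gene("ENSG00000110092", mt = "RNA"),
      predicateInReference = "increase expression",
      environmentalContexts = EnvironmentalContext("phenotype", "C0678222"),
      references = .keggRef()),
    # cell-line environmental context
    KnowledgeUnit(
      EntityCore("unverified:resveratrol", "compound"),
      "activation by increase",
      EntityCore("unverified:doxorubicin", "compound"),
      predicateInReference = "increase cellular accumulation",
      environmentalContexts = EnvironmentalContext("cell_line", "CLO0007606"),
      references = .litRef("resveratrol increases doxorubicin accumulation")),
    # multi-core subject: the CCND1:CDK4 complex phosphorylates RB1
    KnowledgeUnit(
      Entity(list(.gene("ENSG00000110092"), .gene("ENSG00000135446"))),
      "directed link",
      .gene("unverified:RB1", mods = "phosphorylated"),
      predicateInReference = "phosphorylate",
      references = .keggRef()),
    # metabolic reaction: multi-core subject and object sides
    KnowledgeUnit(
      Entity(list(EntityCore("CIDs00005870", "compound"),
                  EntityCore("CIDs00001038", "compound"),
                  EntityCore("CIDs22833512", "compound"))),
      "directed link",
      Entity(list(EntityCore("CIDs00005757", "compound"),
                  EntityCore("CIDs00005886", "compound"))),
      predicateInReference = "<=>",
      references = .litRef("testicular 17-beta-hydroxysteroid dehydrogenase")))
  CodamlDocument(kus, creationDate = "2019-01-01")
}

.rtkModel <- function() {
  ref <- .keggRef()
  abi <- function(s, o, raw = "activate")
    KnowledgeUnit(s, "activation by increase", o,
                  predicateInReference = raw, references = ref)
  kus <- list(
    abi(.gene("unverified:RTK"), .gene("unverified:RAS")),
    abi(.gene("unverified:RAS"), .gene("unverified:RAF")),
    abi(.gene("unverified:RAF"),
        .gene("unverified:MEK", mods = "phosphorylated"), "phosphorylate"),
    abi(.gene("unverified:MEK", mods = "phosphorylated"),
        .gene("unverified:ERK", mods = "phosphorylated"), "phosphorylate"),
    abi(.gene("unverified:ERK", mods = "phosphorylated"),
        .gene("ENSG00000110092")),
    KnowledgeUnit(
      Entity(list(.gene("ENSG00000110092"), .gene("ENSG00000135446"))),
      "directed link", .gene("unverified:RB1", mods = "phosphorylated"),
      predicateInReference = "phosphorylate", references = ref),
    abi(.gene("unverified:RTK"), .gene("unverified:PI3K")),
    abi(.gene("unverified:PI3K"),
        .gene("unverified:AKT", mods = "phosphorylated"), "phosphorylate"),
    abi(.gene("unverified:AKT", mods = "phosphorylated"),
        EntityCore("unverified:proteasomal_degradation",
                   "biological_process")),
    abi(Entity(list(.gene("ENSG00000110092"), .gene("ENSG00000135446"))),
        EntityCore("unverified:G1_S_transition", "biological_process")))
  CodamlDocument(kus, creationDate = "2019-01-01")
}

.cisplatinGemcitabineModel <- function() {
  casp9a <- .gene("unverified:CASP9", iso = "unverified:CASP9a")
  casp9b <- .gene("unverified:CASP9", iso = "unverified:CASP9b")
  apoptosis <- EntityCore("unverified:apoptosis", "biological_process")
  kus <- list(
    KnowledgeUnit(casp9a, "activation by increase", apoptosis,
                  predicateInReference = "induce", references = .litRef()),
    KnowledgeUnit(casp9b, "inhibition by increase", apoptosis,
                  predicateInReference = "inhibit", references = .litRef()),
    KnowledgeUnit(EntityCore("unverified:cisplatin", "compound"),
                  "activation by increase", casp9a,
                  predicateInReference = "increase amount",
                  references = .litRef()),
    KnowledgeUnit(EntityCore("unverified:gemcitabine", "compound"),
                  "inhibition by increase", casp9b,
                  predicateInReference = "decrease activity",
                  references = .litRef()))
  CodamlDocument(kus, creationDate = "2019-01-01")
}

.genisteinModel <- function() {
  skinFibro <- AnatomicalContext(organ = "unverified:skin",
                                 cell = "unverified:fibroblast")
  heartMuscle <- AnatomicalContext(organ = "unverified:heart",
                                   cell = "unverified:muscle_cell")
  ref <- Reference("database", "CODA", "computationally inferred mechanism")
  kus <- list(
    KnowledgeUnit(EntityCore("unverified:genistein", "compound"),
                  "undirected link",
                  Entity(.gene("unverified:FGF1"), skinFibro),
                  predicateInReference = "bind", references = ref),
    KnowledgeUnit(Entity(.gene("unverified:FGF1"), skinFibro),
                  "activation by increase",
                  Entity(.gene("unverified:FGFR1"), heartMuscle),
                  predicateInReference = "activate", references = ref),
    KnowledgeUnit(Entity(.gene("unverified:FGFR1"), heartMuscle),
                  "activation by increase",
                  Entity(.gene("unverified:UBC"), heartMuscle),
                  predicateInReference = "activate", references = ref),
    KnowledgeUnit(Entity(.gene("unverified:UBC"), heartMuscle),
                  "activation by increase",
                  Entity(.gene("unverified:CTGF"), heartMuscle),
                  predicateInReference = "activate", references = ref),
    KnowledgeUnit(Entity(.gene("unverified:CTGF"), heartMuscle),
                  "directed link",
                  EntityCore("unverified:hypertension", "phenotype"),
                  predicateInReference = "affect", references = ref))
  CodamlDocument(kus, creationDate = "2019-01-01")
}

#' Packaged example models
#'
#' Returns one of the worked-example documents shipped with the package:
#' \describe{
#'   \item{rtk}{A ten-unit fragment of receptor-tyrosine-kinase signaling
#'     (MAPK/ERK and PI3K/AKT branches) ending at proteasomal degradation
#'     and the G1/S transition, with phosphorylation modifications and the
#'     CCND1:CDK4 complex as a multi-core subject. Illustrative fragment,
#'     not a complete pathway.}
#'   \item{cisplatin_gemcitabine}{Isoform resolution: the CASP9a isoform
#'     induces apoptosis while CASP9b inhibits it; cisplatin increases
#'     CASP9a and gemcitabine decreases CASP9b activity.}
#'   \item{genistein}{A five-step inter-organ chain from genistein binding
#'     FGF1 in skin fibroblasts through FGFR1/UBC/CTGF in heart muscle
#'     cells to hypertension.}
#'   \item{method_worked_examples}{Nine single-unit worked examples
#'     covering asymmetric specification detail, intra- and inter-
#'     anatomical events, environmental contexts, multi-core complexes and
#'     a metabolic reaction with multi-core reaction sides.}
#' }
#'
#' @param name one of "rtk", "cisplatin_gemcitabine", "genistein",
#'   "method_worked_examples".
#' @return a validated \linkS4class{CodamlDocument}.
#' @examples
#' doc <- exampleModel("genistein")
#' length(knowledgeUnits(doc))
#' @export
exampleModel <- function(name = c("rtk", "cisplatin_gemcitabine", "genistein",
                                  "method_worked_examples")) {
  name <- match.arg(name)
  switch(name,
         rtk = .rtkModel(),
         cisplatin_gemcitabine = .cisplatinGemcitabineModel(),
         genistein = .genisteinModel(),
         method_worked_examples = .methodWorkedExamples())
}
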