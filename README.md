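# codamlr

Context-annotated biological knowledge representation in R: a typed data
model and XML dialect (CODA-ML, the context-oriented directed association
markup language) for *knowledge units*, plus the machinery to validate,
integrate and interconvert them.

## The problem

Systemic analysis of complex diseases — type 2 diabetes, hypertension,
cancers spanning organs — requires merging many pathway and association
models into one unified model. Merging fails quietly when the
representation cannot express what makes two superficially identical
statements different:

* **Molecular specification.** A phosphorylated BRCA1 protein isoform is
  not the same participant as the unmodified protein or the transcript.
  Most exchange formats collapse gene, transcript and protein onto one
  gene symbol.
* **Biological context.** ESR1 increases CCND1 expression under a breast
  cancer condition but not in the normal condition; an interaction
  observed in ovary granulosa cells need not hold in skin fibroblasts.
  Without context slots, model integration manufactures contradictions
  that are really context differences.

`codamlr` implements a representation in which each atomic event is a
**knowledge unit (KU)**: an RDF-style triple *(subject, predicate,
object)* plus additional information. Each subject/object is an entity
with one or more **entity cores** (gene-family molecule, compound,
biological process, molecular function, phenotype, or user-defined term),
where gene cores carry a molecular specification (molecule type ∈ {DNA,
RNA, protein, unspecified}, optional isoform accession, modification set)
and each entity carries a three-slot hierarchical **anatomical context**
(organ ⊇ tissue ⊇ cell) — so inter-organ events are expressed by giving
subject and object different contexts. The triple additionally carries a
set of **environmental contexts** (disease phenotype, cell line,
drug/siRNA/herb treatment; the empty set means the normal condition), the
raw predicate text from the source, a species, one or more provenance
references, and an optional evidence score tagged discrete or continuous.

The predicate is one of **11 controlled terms**, stratified by resolution
of direction and sign and arranged in a two-rooted generalization forest:

```
directed link ──┬── induction ──┬── activation by increase
                │               └── activation by decrease
                ├── reduction ──┬── inhibition by increase
                │               └── inhibition by decrease
                └── missing interaction
undirected link ─┬── positive correlation
                 └── negative correlation
```

Two predicates are *contradictory* when both are signed with opposite
signs, or when exactly one is "missing interaction" and the other asserts
a signed or directed event. Integration deduplicates KUs by a canonical
key over (subject, predicate, object, environmental contexts, species) —
merging provenance, never dropping references — and flags as conflicts
only *context-identical* signed opposites: the package's central design
point is that context distinguishes seemingly contradictory events.

## Worked example

```r
library(codamlr)

brca1 <- EntityCore("ENSG00000012048", "gene",
                    moleculeType = "protein", isoform = "ENSP00000312236")
bap1  <- EntityCore("unverified:BAP1", "gene", moleculeType = "protein")
ku <- KnowledgeUnit(brca1, "undirected link", bap1,
                    predicateInReference = "physically interact",
                    references = Reference("database", "BioGrid"))
ku
#> KnowledgeUnit
#>   subject:   ENSG00000012048, protein, ENSP00000312236
#>   predicate: undirected link
#>   object:    unverified:BAP1, protein
#>   species:   Homo sapiens (1 reference)
```

The two sides deliberately differ in specification detail: the subject
names a protein isoform, the object only the protein — and equality is
exact, so `entityCoreEquals(brca1, bap1)` and any modification or isoform
difference keep entities distinct. `writeDocument(CodamlDocument(ku))`
yields the canonical XML (fixed element order, 2-space indent, UTF-8/LF,
lexicographically ordered modification and context sets), which is
byte-stable: equal documents always serialize identically, and
`parseDocument()` validates against the shipped XSD and the model
invariants, returning rule-tagged issues.

Integration of a synthetic three-model corpus with planted structure:

```r
corpus  <- generateCorpus(GeneratorConfig(nModels = 3, kusPerModel = 50,
                                          duplicateRate = 0.1,
                                          contradictions = 7, seed = 42))
unified <- integrateModels(corpus$documents)
unified
#> UnifiedModel: 157 units from 3 source models
#>   conflict ledger: 7 groups (7 open)
```

172 input units (150 base + 15 planted duplicates + 7 planted
contradiction partners) collapse to 157: the 15 duplicates merge into
their originals with concatenated references, and exactly the 7 planted
context-identical signed opposites are flagged — recovery of the
generator's ground truth is exact. `resolveConflicts()` then applies a
declared strategy (`keep_all_flagged`, `prefer_higher_evidence`,
`generalize_to_lca`, `context_split`), and `toGraph()` /`writeSIF()` /
`writeGraphML()` export the network (one node per distinct entity-cores ×
anatomy pair). `toBiopax()` / `fromBiopax()` interconvert with a declared,
explicitly lossy BioPAX Level-3 subset, every construct accounted for in
a conversion report.

Four example models ship with the package via `exampleModel()`:
`"rtk"`, `"cisplatin_gemcitabine"`, `"genistein"`, and
`"method_worked_examples"`. A thin command-line wrapper with
`validate`/`canonicalize`/`convert`/`integrate`/`export`/`examples`/
`gen`/`vocab` verbs is installed at `inst/cli/codaml.R`.

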