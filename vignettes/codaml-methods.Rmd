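---
title: "Context-annotated knowledge units: model, semantics and design choices"
author: "codamlr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-annotated knowledge units: model, semantics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codamlr)
```

# The data model and its assumptions

A knowledge unit (KU) is one atomic biological event: a subject–predicate–
object triple plus additional information. The model's two load-bearing
assumptions are:

1. **Molecular specification matters.** A gene-type entity core is
   identified by its coding gene's accession and refined by a molecule
   type (DNA, RNA, protein, or unspecified), an optional isoform
   accession, and a set of modification labels. Equality is *exact*: a
   core with a stated isoform and one without are unequal, and a
   phosphorylated protein is distinct from its unmodified form. We chose
   exact matching (rather than subsumption, where "BRCA1 protein" would
   absorb "BRCA1 protein, isoform X") because the dialect routinely mixes
   granularities within one unit — one side isoform-resolved, the other
   not — and no cross-granularity matching rule can be applied silently
   without asserting biology the source did not state. Granularity-aware
   merging is therefore only ever an explicit integration strategy, never
   the default equality.
2. **Context distinguishes events.** Each entity carries a three-slot
   anatomical context (organ, tissue, cell; all optional; empty means
   unspecified), and each triple carries a set of environmental contexts
   (empty set = normal condition). Two units that differ in any context
   slot are different events. This is what lets integration avoid
   manufacturing contradictions out of context differences, and what
   makes inter-organ events expressible (subject and object with
   different anatomy).

Isoforms are accepted only for molecule types RNA and protein: an isoform
is a transcript- or protein-level concept, so a DNA or unspecified
molecule with an isoform is rejected at construction and reported by the
validator. Modifications form an open vocabulary normalized through a
shipped table (noun forms map to participles, e.g. "phosphorylation" →
"phosphorylated"), lowercased, deduplicated and stored sorted so that
serialization is invariant under input order. Species is a single value
per unit; an event observed in two species is two units. Evidence scores
are stored verbatim with a discrete/continuous tag and are never
normalized across sources, because score semantics belong to the source
model.

# The predicate vocabulary

Eleven controlled terms stratified by resolution of direction and sign,
arranged in a two-rooted forest (causal family under "directed link",
non-causal under "undirected link"). The exact parent edges are a
declared convention of this package, kept in one editable YAML file
(`inst/extdata/predicate_vocab.yaml`) so they can be corrected without
code changes. Two placements deserve comment:

* **"activation by decrease" sits under induction** (and "inhibition by
  increase" under reduction): the families group by the outcome on the
  *object* — activated vs inhibited — not by the direction of change of
  the subject.
* **"missing interaction" sits in the causal family**: it asserts that a
  causal event present in the normal condition disappears under a stated
  context, so it generalizes to "directed link", not to the non-causal
  root.

Signs follow the families: induction-family terms and positive
correlation are positive; reduction-family terms and negative correlation
are negative; the two roots and missing interaction are unsigned.
Contradiction is (i) opposite signs, or (ii) exactly one side "missing
interaction" with the other signed or directed — an unsigned "directed
link" is compatible with any sign (it merely under-specifies), but it is
contradicted by an asserted absence. "missing interaction" does not
contradict itself, and it only conflicts with units sharing its
environmental-context set, since it asserts absence *under that context*.

The raw-term normalization map ships with the canonical synonym sets
("activate", "express", "positively regulate", "increase", "up-regulate"
→ activation by increase; the obvious antonyms → inhibition by increase;
binding/interaction verbs → undirected link) and is extensible via the
same config file. Identifier validation is purely syntactic (anchored
regular expressions per namespace: ENSG/ENST/ENSP + 11 digits, CIDs + 8
digits, GO: + 7 digits, UMLS C + 7 digits, MeSH D/C + 6–9 alphanumerics,
CLO + 7 digits); no ontology service is consulted. One namespace quirk:
C-prefixed 7-digit identifiers match both the UMLS and the MeSH pattern;
we validate phenotype identifiers as UMLS. Entities known only by symbol
use the `unverified:` placeholder namespace, which every validator run
flags with a warning — inventing plausible-looking real accessions would
be worse than an honest placeholder.

# Serialization

The canonical writer is a deterministic string builder: fixed element
order, 2-space indent, UTF-8 with LF line endings, modification and
environmental-context sets in lexicographic order, and a fixed numeric
rendering for evidence scores. Equal documents therefore serialize to
byte-identical text, and `write(parse(write(d)))` equals `write(d)`
byte for byte. Parsing goes through `xml2` with validation against the
shipped XSD, which is generated from the same structural table that
drives the model validator; unknown elements are schema violations
(errors in strict mode, warnings in lenient mode). The document creation
date is document *data*, never stamped at write time, precisely to keep
serialization deterministic.

Validator severities encode deliberate choices: anatomical hierarchy
gaps — a tissue or cell given without an organ — are warnings, not
errors, because partial hierarchies are legitimate (several worked
examples fill only the organ slot, and one fills organ and cell but not
tissue); identifier-pattern failures are errors under strict validation
and warnings under lenient validation (the CLI validates strictly and
converts leniently); placeholder identifiers always warn.

# Integration semantics

The deduplication key covers subject, predicate, object, environmental
contexts and species — not references, raw predicate text, or evidence
scores, which are provenance. Merging concatenates reference lists (total
reference count is conserved; nothing is deduplicated away) and keeps the
maximum evidence score when all contributions share one score type; mixed
discrete/continuous scores are logged side by side and never compared.

The conflict signature is the deduplication key minus the predicate, with
direction: A→B and B→A are different signatures, except that pairs of
non-causal predicates match symmetrically. Conflict groups are connected
components of the pairwise-contradiction relation within one signature.
Conflicts are scoped within one species; whether cross-species
contradictions are meaningful is left to the curator (we believe they are
not, for the same reason context-differing events are not conflicts).

Resolution strategies are deliberately conservative. The default,
`keep_all_flagged`, changes nothing and marks the groups.
`prefer_higher_evidence` suppresses lower-scored members but refuses to
act (keeps all, leaves the group open) on missing scores, mixed score
types, or ties. `generalize_to_lca` replaces the members by one unit
whose predicate is the least common ancestor of theirs — typically
"directed link" for a signed causal disagreement, preserving "something
causal happens here" while withdrawing the sign — with the member
references pooled; groups spanning both root families have no LCA and
stay open with a warning. `context_split` only reports: a genuine
resolution would require recovering the missing context from the
sources, which is curator work, not arithmetic.

Graph export creates one node per distinct (entity-core multiset,
anatomical context) pair, so the same molecule in two organs is two
nodes — that is the point of the representation. Complexes are one node
by default (`explodeComplexes = TRUE` gives the per-core view), and
undirected-family units produce a single edge flagged `undirected`.

# BioPAX interchange

The BioPAX Level-3 subset is declared and explicitly lossy; the mapping
table is summarized in `?toBiopax`. Choices worth recording: the
reversible predicate mapping operates at the induction/reduction family
level because BioPAX `controlType` has no by-increase/by-decrease axis,
so sign-resolved leaves flatten to their family on export and return as
the family on import. Environmental contexts, species, core types and
molecular specifications are encoded as structured `bp:comment` strings
(`codaml:…=`), which round-trip through our own exports while remaining
visible to generic BioPAX tools; anatomical contexts become a
`CellularLocationVocabulary` whose terms are prefixed `organ:`/`tissue:`/
`cell:` with MeSH xrefs. "missing interaction" has no BioPAX
counterpart and is skipped with a report line, as are references and
evidence scores. Import additionally accepts `BiochemicalReaction`,
whose left/right participants become multi-core subject and object with
predicate "directed link". Every conversion emits a report in which
converted + encoded + skipped rows account for every input construct.
The published converter for this dialect is not described at mapping
level in the literature; this table is self-consistent and documented,
not claimed identical to any other implementation.

# The synthetic-corpus generator

`generateCorpus()` emulates the integration scenario the representation
is built for: several source models over a shared entity pool, with
duplicated events (same biology, different provenance) and planted
contradictions (signature-identical, opposite-signed). Defaults — three
models of fifty units, pools of 120 genes and 40 compounds, anatomy on
half the entities, an environmental context on 30 percent of units, a 10
percent duplicate rate — were chosen once as a realistic small multi-model
scenario. Base units are constructed on pairwise-distinct entity pairs,
so the only duplicates and contradictions present are the planted ones
and ground-truth recovery is exact *by construction*; this is a property
of the test harness, not a claim about real corpora. What the generator
does **not** emulate: correlated evidence between sources, near-duplicate
units differing in specification granularity, identifier synonymy across
namespaces, multi-species corpora, and scale-free topology of real
interaction networks. Passing the recovery tests therefore demonstrates
correctness of the deduplication and conflict machinery, not robustness
to noisy real-world curation.

Everything is seed-deterministic, including document creation dates
(fixed strings), so generated corpora serialize byte-identically across
runs.

# Numerical and degenerate-input choices

Evidence scores render via R's default 15-significant-digit character
conversion, exact for the score magnitudes in practice; document
round-trip tests exercise this. Ties in `prefer_higher_evidence` keep all
members. The LCA of a term with itself is the term. Empty documents
serialize, validate, convert and export as empty-but-valid artifacts.
Environmental-context sets are deduplicated and sorted at construction
and at parse, so set semantics hold regardless of input order. Canonical
keys percent-escape their delimiter characters, so adversarial
identifiers cannot collide two distinct units.

# Problem sizes in the shipped checks

The test suite and the acceptance script use: 1000 random documents for
serialization round-trips; 50 seeds of up to 200 units for the
conflict-scan/oracle equivalence (the oracle is an independent O(n²)
pairwise scan with its own inlined sign table); planted-structure
recovery at k ∈ {0, 1, 7, 25} contradictions in 3×50-unit corpora; all
121 predicate pairs for the lattice laws; and 200 documents for the
BioPAX round-trip. These sizes exercise every code path and collision
regime of the bucketed conflict scan while keeping the default test run
brief.

# Known limitations

* Gene sequences (and structure) are out of scope of the representation.
* Identifier validation is syntactic; a well-formed but nonexistent
  accession passes.
* The predicate hierarchy's parent edges are a declared convention,
  isolated in one config file.
* The BioPAX subset does not cover stoichiometry, pathway steps, or
  complex assembly; imported foreign BioPAX loses whatever our comment
  encoding did not author.
* One KU carries one species; cross-species reference models need one
  unit per species.
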