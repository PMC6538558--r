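# Controlled predicate vocabulary: 11 terms stratified by resolution of
# direction and sign, their generalization hierarchy (child -> parent; two
# roots: "directed link" for the causal family, "undirected link" for the
# non-causal family), the sign of each term, and the normalization map from
# raw relation text to controlled terms.
#
# The hierarchy edges are a declared convention of this package, isolated
# here so they can be corrected without code changes. Placement rationale:
# sign-resolved leaves sit under induction/reduction, which group by the
# outcome on the object (activated vs inhibited); "missing interaction"
# sits in the causal family because it asserts the disappearance of a
# causal event under a stated context.
terms:
  - directed link
  - induction
  - reduction
  - activation by increase
  - activation by decrease
  - inhibition by increase
  - inhibition by decrease
  - undirected link
  - positive correlation
  - negative correlation
  - missing interaction
hierarchy:
  induction: directed link
  reduction: directed link
  missing interaction: directed link
  activation by increase: induction
  activation by decrease: induction
  inhibition by increase: reduction
  inhibition by decrease: reduction
  positive correlation: undirected link
  negative correlation: undirected link
signs:
  directed link: unsigned
  induction: positive
  reduction: negative
  activation by increase: positive
  activation by decrease: positive
  inhibition by increase: negative
  inhibition by decrease: negative
  undirected link: unsigned
  positive correlation: positive
  negative correlation: negative
  missing interaction: unsigned
raw_map:
  activate: activation by increase
  express: activation by increase
  positively regulate: activation by increase
  increase: activation by increase
  up-regulate: activation by increase
  upregulate: activation by increase
  induce: activation by increase
  inhibit: inhibition by increase
  repress: inhibition by increase
  negatively regulate: inhibition by increase
  decrease: inhibition by increase
  down-regulate: inhibition by increase
  downregulate: inhibition by increase
  bind: undirected link
  binds: undirected link
  interact: undirected link
  physically interact: undirected link
modification_normalization:
  phosphorylation: phosphorylated
  phospho: phosphorylated
  methylation: methylated
  acetylation: acetylated
  ubiquitination: ubiquitinated
  ubiquitylation: ubiquitinated
  sumoylation: sumoylated
  glycosylation: glycosylated
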