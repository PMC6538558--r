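# Syntactic identifier namespaces. Patterns are anchored full-string
# regular expressions; validation is syntactic only (no service lookups).
# "roles" names the slots a namespace is acceptable for; the validator maps
# core types, anatomy slots and environmental-context types onto roles.
# The "unverified" namespace holds placeholder identifiers for entities
# known only by symbol; it is accepted syntactically everywhere but flagged
# with a warning by the document validator.
ensembl_gene:
  pattern: "^ENSG[0-9]{11}$"
  roles: [gene]
ensembl_transcript:
  pattern: "^ENST[0-9]{11}$"
  roles: [isoform]
ensembl_protein:
  pattern: "^ENSP[0-9]{11}$"
  roles: [isoform]
stitch:
  pattern: "^CIDs[0-9]{8}$"
  roles: [compound, drug_treatment, herb_treatment]
go:
  pattern: "^GO:[0-9]{7}$"
  roles: [biological_process, molecular_function]
umls:
  pattern: "^C[0-9]{7}$"
  roles: [phenotype]
mesh:
  pattern: "^[DC][A-Za-z0-9]{6,9}$"
  roles: [anatomy, species]
clo:
  pattern: "^CLO[0-9]{7}$"
  roles: [cell_line]
unverified:
  pattern: "^unverified:[A-Za-z0-9._-]+$"
  roles: [any]
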