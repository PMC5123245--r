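{
  "schema_version": "1.0",
  "flavor": "rCRS",
  "reference": "rCRS (GenBank J01415.2 / NC_012920.1), RefSeq-style gene map",
  "genome_length": 16569,
  "counts": {
    "trna_genes": 22,
    "rrna_genes": 2,
    "protein_coding_genes": 13,
    "trna_positions": 1508,
    "trna_positions_unique": 1504,
    "rrna_positions": 2513,
    "modification_types": 16,
    "modification_records": 116,
    "modified_residues": 110,
    "scored_rna_variants": 5
  },
  "notes": "modified_residues counts unique (position, tRNA) pairs; residues carrying two alternative modifications appear as two modification_records. Structure maps other than MT-TM are synthetic stand-ins (provenance column)."
}
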