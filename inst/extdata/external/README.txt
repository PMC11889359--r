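Optional full-scale benchmark inputs (not distributed; multi-GB raw data,
processed with an external search engine). Expected files:

  modified_peptides_trypsin.tsv   per-protease modified-peptide tables
  modified_peptides_pepsin.tsv    (combined modified-peptide dialect)
  annotation.tsv                  sample_id / condition / replicate / protease
  proteome.fasta                  the search database (SwissProt human)

With these present, the external acceptance test re-derives the published
per-site IC50s (e.g. EphA2;K646 and DDR1;K655).
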