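Place the canonical UniProt sequences used by the worked-example mapping
checks here as "worked_examples.fasta" (standard UniProt FASTA headers),
containing at least:

  P29317  EPHA2_HUMAN  (probe site K646)
  Q16288  NTRK3_HUMAN  (probe site K572)
  P12268  IMPD2_HUMAN  (probe site K450)

e.g. from https://rest.uniprot.org/uniprotkb/P29317.fasta etc. The file is
not distributed with the package; the corresponding acceptance test fails
until it is supplied.
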