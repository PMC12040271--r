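Reference sequences for the sequence-identity validation
=========================================================

The identity check of the human Na+,K+-ATPase beta1 ectodomain model
against its structural template compares two reference sequences that are
NOT redistributed with this package.  To enable it, place here:

  P05026.fasta      UniProt P05026 (human ATP1B1), e.g. from
                    https://rest.uniprot.org/uniprotkb/P05026.fasta
  3wgu_beta.fasta   the beta-subunit chain sequence of PDB entry 3WGU
                    (wild boar Na+,K+-ATPase), e.g. from
                    https://www.rcsb.org/fasta/entry/3WGU

With both files present, the corresponding acceptance test computes the
global-alignment percent identity with dimerscope::global_align_identity()
and compares it against the published 92.41%.
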