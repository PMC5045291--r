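Reference inputs for the structural recomputations (not redistributed):

- 5jbm.pdb         coordinates of the Cac1 winged-helix domain crystal structure
- 5ejo.pdb         coordinates of the molecular-replacement search model
- cac1_rlf2.fasta  full-length Cac1 (RLF2) database sequence

Place the files here to enable analysis/06_structure_metrics.R and the
corresponding acceptance tests; everything else in the package runs
without them.
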