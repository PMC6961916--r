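# External data

Place transcriptions of the study's supplementary per-gene tables here to
reproduce the published statistics with the `tables`-mode pipeline:

- `published_intensity.tsv` — the per-gene mean intensities (0-255 scale) for
  HPC, CX, CB and the subfields CA1, CA2, CA3, DG, in the package TSV dialect
  (header `gene<TAB>HPC<TAB>CX<TAB>CB<TAB>CA1<TAB>CA2<TAB>CA3<TAB>DG`, one
  row per gene, `NA` for unmeasured values).
- `published_groups.tsv` — the informative-gene group labels (header
  `gene<TAB>group`, values `A` for challenge, `B` for sufficiency).
- `published_fpkm.tsv` (optional) — subfield FPKM values
  (`gene<TAB>CA1<TAB>CA2<TAB>CA3<TAB>DG`).
- `published_effects.tsv` (optional) — coded ligand effects
  (`gene<TAB>group<TAB>ltp<TAB>neurogenesis`, codes -1/0/1/NA).

These tables are part of the study's supplementary appendix and are not
redistributed with the package.
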