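# Phenotype signatures for the articular chondrocyte model, encoded from the
# published attractor marker profiles. Signatures are configuration, not
# code: edit bands or marker sets freely.
- label: Healthy
  high: [SOX9, NKX3.2, COL-II]
  low: [RUNX2, COL-X, MMP13]
  band: 0.2
- label: Hypertrophic
  high: [RUNX2, COL-X, MMP13, IHH]
  low: [SOX9, COL-II]
  band: 0.2
- label: "None"
  high: []
  low: [SOX9, NKX3.2, COL-II, RUNX2, COL-X, MMP13, IHH]
  band: 0.2
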