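# Full benchmark run on the bundled synthetic default preset.
# Thresholds omitted here fall back to the study defaults and are logged
# in summary.json.
seed: 1
preset: default
outdir: naivebench_out
stages:
  te_de: {}
  concordance: {}
  te_gene: {}
  methylome: {}
  allelic: {}
  chimera: {}
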