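# Bundled data files

- `ese238_synthetic_hexamers.txt`, `ese54_synthetic_hexamers.txt`:
  deterministic SYNTHETIC stand-ins for the published 238-motif and
  54-motif exonic-splicing-enhancer hexamer catalogues (purine-rich
  6-mers; the 54 set is a subset of the 238 set). They exercise the
  scanning machinery; pass the real published lists to
  `motif_set(hexamers = ...)` to reproduce a published analysis.
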