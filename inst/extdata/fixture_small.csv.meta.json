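{
  "slide_col": "slide_id",
  "cell_col": "cell_id",
  "channels": ["vimentin", "cd3"],
  "scale_tag": "raw"
}
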