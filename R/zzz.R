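.datatable.aware <- TRUE

# silence R CMD check notes for data.table non-standard evaluation
utils::globalVariables(c(
  ".", ".N", ".SD", "amplicon_id", "ref", "read_pos", "depth", "in_primer",
  "altn", "alt", "n", "cov", "direction"))
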