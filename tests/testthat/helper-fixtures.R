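model_atoms_for_test <- function(m) {
  do.call(rbind, lapply(m$chains, function(ch) ch$atoms))
}
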