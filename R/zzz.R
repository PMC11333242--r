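.onLoad <- function(libname, pkgname) {
  register_annotation_backend(rule_en_backend)
  register_g2p_backend(rule_g2p_en_backend)
  invisible()
}
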