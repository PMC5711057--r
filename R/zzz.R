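.onLoad <- function(libname, pkgname) {
  assignInMyNamespace(".att_tables", .build_att_tables())
}
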