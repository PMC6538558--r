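.codamlr <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  .codamlr$vocab <- NULL
  .codamlr$namespaces <- NULL
}
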