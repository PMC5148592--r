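#' @useDynLib ehraql, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.onLoad <- function(libname, pkgname) {
  register_driver("memory", memory_driver)
  # Reserved factory slots: production document-store back-ends plug in here.
  register_driver("mongodb", function(config) {
    stop("driver not installed: mongodb support is a reserved factory slot")
  })
  register_driver("elasticsearch", function(config) {
    stop("driver not installed: elasticsearch support is a reserved factory slot")
  })
  invisible()
}
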