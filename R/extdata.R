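#' Path to the bundled synthetic Disease Ontology slice
#'
#' A small, hand-built OBO file mirroring the `is_a` topology of the
#' neurodegenerative-disease neighbourhood of the Disease Ontology
#' (motor neuron diseases, synucleinopathies, tauopathies, demyelinating
#' diseases, dementias) around the eight default disease terms. It is a
#' synthetic stand-in so that the disease-level similarity machinery can
#' run without downloading a DO release; similarities computed on it
#' approximate, but do not equal, values from a real release, which are
#' in any case version-sensitive. Pass a real DO OBO file wherever exact
#' published values matter.
#'
#' @return file path of the OBO text
#' @export
synthetic_do_path <- function() {
  system.file("extdata", "synthetic_do_slice.obo", package = "comorbsim",
              mustWork = TRUE)
}
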