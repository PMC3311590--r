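#' @rdname PeptideLibrary-class
#' @param x,object An object.
#' @export
setGeneric("peptideIds", function(x) standardGeneric("peptideIds"))

#' @rdname PeptideLibrary-class
#' @export
setGeneric("peptideSequences", function(x) standardGeneric("peptideSequences"))

#' @rdname PeptideLibrary-class
#' @export
setGeneric("peptideLength", function(x) standardGeneric("peptideLength"))

#' @rdname AAWS-classes
#' @export
setGeneric("aawsWeights", function(x) standardGeneric("aawsWeights"))

#' @rdname AntibodyMixture-class
#' @export
setGeneric("bindingSites", function(x) standardGeneric("bindingSites"))

#' @rdname AntibodyMixture-class
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname BindingProfile-class
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname BindingProfile-class
#' @export
setGeneric("profileStage", function(x) standardGeneric("profileStage"))

#' @rdname CvResult-class
#' @export
setGeneric("q2", function(x) standardGeneric("q2"))
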