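#' @rdname CodonCombinationSet-class
#' @param x,object a `CodonCombinationSet`, `DesignTemplate` or `PrimerSet`.
#' @export
setGeneric("dnaSequences", function(x) standardGeneric("dnaSequences"))

#' @rdname CodonCombinationSet-class
#' @export
setGeneric("codonIndices", function(x) standardGeneric("codonIndices"))

#' @rdname CodonCombinationSet-class
#' @export
setGeneric("segmentLabel", function(x) standardGeneric("segmentLabel"))

#' @rdname DesignTemplate-class
#' @export
setGeneric("dnaSequence", function(x) standardGeneric("dnaSequence"))

#' @rdname DesignTemplate-class
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname DesignTemplate-class
#' @export
setGeneric("identityReport", function(x) standardGeneric("identityReport"))

#' @rdname PrimerSet-class
#' @export
setGeneric("primers", function(x) standardGeneric("primers"))

#' @rdname PrimerSet-class
#' @export
setGeneric("overlaps", function(x) standardGeneric("overlaps"))

#' @rdname PrimerSet-class
#' @export
setGeneric("crossMatrix", function(x) standardGeneric("crossMatrix"))
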