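#' @include sRNAkit-package.R
NULL

#' @export
setGeneric("tagSequences", function(x) standardGeneric("tagSequences"))

#' @export
setGeneric("tagCounts", function(x) standardGeneric("tagCounts"))

#' @export
setGeneric("cleaningCounts", function(x) standardGeneric("cleaningCounts"))

#' @export
setGeneric("cleaningPercentages",
           function(x) standardGeneric("cleaningPercentages"))

#' @export
setGeneric("dotBracket", function(x) standardGeneric("dotBracket"))

#' @export
setGeneric("structurePairs", function(x) standardGeneric("structurePairs"))

#' @export
setGeneric("foldEnergy", function(x) standardGeneric("foldEnergy"))

#' @export
setGeneric("duplexStatus", function(x) standardGeneric("duplexStatus"))

#' @export
setGeneric("duplexTotal", function(x) standardGeneric("duplexTotal"))
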