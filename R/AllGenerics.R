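#' @export
setGeneric("consensusA", function(x) standardGeneric("consensusA"))

#' @export
setGeneric("consensusB", function(x) standardGeneric("consensusB"))

#' @export
setGeneric("pairInfo", function(x) standardGeneric("pairInfo"))

#' @export
setGeneric("foldChanges", function(x) standardGeneric("foldChanges"))

#' @export
setGeneric("deClass", function(x) standardGeneric("deClass"))

#' @export
setGeneric("deSummary", function(x) standardGeneric("deSummary"))

#' @export
setGeneric("roundTotals", function(x) standardGeneric("roundTotals"))
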