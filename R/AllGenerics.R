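#' @rdname SnpPanel-class
#' @param x A \linkS4class{SnpPanel} or \linkS4class{GenotypeSet}.
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname SnpPanel-class
#' @export
setGeneric("rsids", function(x) standardGeneric("rsids"))

#' @rdname SnpPanel-class
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname SnpPanel-class
#' @export
setGeneric("panelWeights", function(x) standardGeneric("panelWeights"))

#' @rdname SnpPanel-class
#' @param value Replacement value.
#' @export
setGeneric("panelWeights<-", function(x, value) standardGeneric("panelWeights<-"))

#' @rdname GenotypeSet-class
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname ConcordanceTable-class
#' @param x A \linkS4class{ConcordanceTable}.
#' @export
setGeneric("concordanceRecords", function(x) standardGeneric("concordanceRecords"))
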