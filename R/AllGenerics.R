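#' @rdname ConnectomeSet-accessors
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname ConnectomeSet-accessors
#' @export
setGeneric("regionInfo", function(x) standardGeneric("regionInfo"))

#' @rdname ConnectomeSet-accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname ConnectomeSet-accessors
#' @export
setGeneric("cohort", function(x) standardGeneric("cohort"))

#' @rdname ConnectomeSet-accessors
#' @export
setGeneric("scMatrix", function(x, subject) standardGeneric("scMatrix"))

#' @rdname ConnectomeSet-accessors
#' @export
setGeneric("distMatrix", function(x, subject) standardGeneric("distMatrix"))

#' @rdname PLSModel-accessors
#' @export
setGeneric("singularValues", function(object) standardGeneric("singularValues"))

#' @rdname PLSModel-accessors
#' @export
setGeneric("saliences", function(object, side = c("brain", "behavior"))
  standardGeneric("saliences"))

#' @rdname PLSModel-accessors
#' @export
setGeneric("permPValues", function(object) standardGeneric("permPValues"))

#' @rdname PLSModel-accessors
#' @export
setGeneric("bootstrapRatios", function(object) standardGeneric("bootstrapRatios"))

#' @rdname PLSModel-accessors
#' @export
setGeneric("splitHalfZ", function(object) standardGeneric("splitHalfZ"))

#' @rdname QCReport-accessors
#' @export
setGeneric("exclusions", function(object) standardGeneric("exclusions"))

#' @rdname QCReport-accessors
#' @export
setGeneric("consistencyRetained", function(object)
  standardGeneric("consistencyRetained"))

#' @rdname QCReport-accessors
#' @export
setGeneric("subjectDensity", function(object) standardGeneric("subjectDensity"))
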