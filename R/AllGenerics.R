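#' @name methrisk-generics
#' @title Accessor generics for MethylCohort objects
#' @param x a [MethylCohort-class] object.
#' @keywords internal
NULL

#' @rdname methrisk-generics
#' @export
setGeneric("betas", function(x) standardGeneric("betas"))

#' @rdname methrisk-generics
#' @export
setGeneric("cohortData", function(x) standardGeneric("cohortData"))

#' @rdname methrisk-generics
#' @export
setGeneric("deficits", function(x) standardGeneric("deficits"))

#' @rdname methrisk-generics
#' @export
setGeneric("designType", function(x) standardGeneric("designType"))

#' @rdname methrisk-generics
#' @export
setGeneric("trueParams", function(x) standardGeneric("trueParams"))
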