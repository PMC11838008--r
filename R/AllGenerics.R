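#' @import methods
NULL

#' @rdname KineticTrajectory-class
#' @param object,x an object.
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname KineticTrajectory-class
#' @export
setGeneric("stateMatrix", function(x) standardGeneric("stateMatrix"))

#' @rdname KineticTrajectory-class
#' @export
setGeneric("derivativeMatrix", function(x) standardGeneric("derivativeMatrix"))

#' @rdname KineticTrajectory-class
#' @export
setGeneric("kineticParams", function(x) standardGeneric("kineticParams"))

#' @rdname KineticParameters-class
#' @export
setGeneric("parameterValues", function(x) standardGeneric("parameterValues"))

#' @rdname KineticParameters-class
#' @export
setGeneric("productVariants", function(x) standardGeneric("productVariants"))

#' @rdname KineticParameters-class
#' @export
setGeneric("estimableParameters",
           function(x) standardGeneric("estimableParameters"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("stoichMatrix", function(x) standardGeneric("stoichMatrix"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("fluxBounds", function(x) standardGeneric("fluxBounds"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("networkRoles", function(x) standardGeneric("networkRoles"))

#' @rdname FluxTrajectory-class
#' @export
setGeneric("fluxMatrix", function(x) standardGeneric("fluxMatrix"))

#' @rdname FluxTrajectory-class
#' @export
setGeneric("lpStatus", function(x) standardGeneric("lpStatus"))

#' @rdname FluxTrajectory-class
#' @export
setGeneric("biomassSeries", function(x) standardGeneric("biomassSeries"))

#' @rdname FluxScoreTable-class
#' @export
setGeneric("fsMatrix", function(x) standardGeneric("fsMatrix"))

#' @rdname FluxScoreTable-class
#' @export
setGeneric("nfsMatrix", function(x) standardGeneric("nfsMatrix"))

#' @rdname PhaseSchedule-class
#' @export
setGeneric("phaseTable", function(x) standardGeneric("phaseTable"))
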