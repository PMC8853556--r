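#' @include AllClasses.R
NULL

#' @rdname MetabolicModel-class
#' @export
setGeneric("reactionIds", function(object, ...) standardGeneric("reactionIds"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("speciesIds", function(object, ...) standardGeneric("speciesIds"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("geneIds", function(object, ...) standardGeneric("geneIds"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("stoichiometricMatrix",
           function(object, ...) standardGeneric("stoichiometricMatrix"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("reactionBounds", function(object, ...) standardGeneric("reactionBounds"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("reactionBounds<-",
           function(object, ..., value) standardGeneric("reactionBounds<-"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("gprRules", function(object, ...) standardGeneric("gprRules"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("extraConstraints",
           function(object, ...) standardGeneric("extraConstraints"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("extraConstraints<-",
           function(object, ..., value) standardGeneric("extraConstraints<-"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("exchangeReactions",
           function(object, ...) standardGeneric("exchangeReactions"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("reverseMap", function(object, ...) standardGeneric("reverseMap"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("isIrreversible", function(object, ...) standardGeneric("isIrreversible"))

#' @rdname ScoreTable-class
#' @export
setGeneric("scoreType", function(object, ...) standardGeneric("scoreType"))

#' @rdname ScoreTable-class
#' @export
setGeneric("scoreGroups", function(object, ...) standardGeneric("scoreGroups"))

#' @rdname ScoreTable-class
#' @export
setGeneric("groupMeans", function(object, ...) standardGeneric("groupMeans"))

#' @rdname normalizeRAS
#' @export
setGeneric("normalizedScores",
           function(object, ...) standardGeneric("normalizedScores"))

#' @rdname FluxSampleSet-class
#' @export
setGeneric("fluxes", function(object, ...) standardGeneric("fluxes"))

#' @rdname FluxSampleSet-class
#' @export
setGeneric("sampleBatches", function(object, ...) standardGeneric("sampleBatches"))

#' @rdname netFlux
#' @export
setGeneric("netFlux", function(object, reaction, ...) standardGeneric("netFlux"))

#' @rdname SignMatrix-class
#' @export
setGeneric("signValues", function(object, ...) standardGeneric("signValues"))

#' @rdname SignMatrix-class
#' @export
setGeneric("groupPairs", function(object, ...) standardGeneric("groupPairs"))
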