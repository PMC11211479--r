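#' @name accessors
#' @title Accessors for ehrfm S4 containers
#' @description Extract the component tables and metadata of the package's
#'   S4 containers without touching slots directly.
#' @param object an ehrfm S4 object.
NULL

#' @rdname accessors
#' @export
setGeneric("persons", function(object) standardGeneric("persons"))
#' @rdname accessors
#' @export
setGeneric("events", function(object) standardGeneric("events"))
#' @rdname accessors
#' @export
setGeneric("admissions", function(object) standardGeneric("admissions"))
#' @rdname accessors
#' @export
setGeneric("vocabCodes", function(object) standardGeneric("vocabCodes"))
#' @rdname accessors
#' @export
setGeneric("vocabCounts", function(object) standardGeneric("vocabCounts"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("fmVocabulary", function(object) standardGeneric("fmVocabulary"))
#' @rdname accessors
#' @export
setGeneric("meanDiff", function(object) standardGeneric("meanDiff"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("confInt", function(object) standardGeneric("confInt"))
#' @rdname accessors
#' @export
setGeneric("perTaskDiff", function(object) standardGeneric("perTaskDiff"))

#' @rdname accessors
#' @export
setMethod("persons", "TimelineSet", function(object) object@persons)
#' @rdname accessors
#' @export
setMethod("events", "TimelineSet", function(object) object@events)
#' @rdname accessors
#' @export
setMethod("admissions", "TimelineSet", function(object) object@admissions)
#' @rdname accessors
#' @export
setMethod("vocabCodes", "Vocabulary", function(object) object@codes)
#' @rdname accessors
#' @export
setMethod("vocabCounts", "Vocabulary", function(object) object@counts)
#' @rdname accessors
#' @export
setMethod("provenance", "FMCheckpoint", function(object) object@provenance)
#' @rdname accessors
#' @export
setMethod("fmVocabulary", "FMCheckpoint", function(object) object@vocabulary)
#' @rdname accessors
#' @export
setMethod("meanDiff", "ComparisonResult", function(object) object@meanDiff)
#' @rdname accessors
#' @export
setMethod("pValue", "ComparisonResult", function(object) object@pValue)
#' @rdname accessors
#' @export
setMethod("confInt", "ComparisonResult", function(object) object@ci)
#' @rdname accessors
#' @export
setMethod("perTaskDiff", "ComparisonResult", function(object) object@perTaskDiff)
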