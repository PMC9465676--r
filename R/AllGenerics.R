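#' Accessor generics for recording objects
#'
#' `subjectInfo()` returns the [SubjectInfo-class] attached to a recording,
#' `channelNames()` the names of the channels present, `samplingRate()` the
#' sampling frequency (Hz) of a channel, `channelData()` the raw sample
#' vector, `activities()` the activity-interval annotation and `duration()`
#' the recording length in seconds.
#'
#' @param x a [Recording-class] (or, for `samplingRate`/`channelData`, a
#'   [Channel-class])
#' @param ... further arguments for methods (e.g. `which` naming a channel)
#' @return see the individual method descriptions
#' @name recording-accessors
NULL

#' @rdname recording-accessors
#' @export
setGeneric("subjectInfo", function(x, ...) standardGeneric("subjectInfo"))

#' @rdname recording-accessors
#' @export
setGeneric("channelNames", function(x, ...) standardGeneric("channelNames"))

#' @rdname recording-accessors
#' @export
setGeneric("samplingRate", function(x, ...) standardGeneric("samplingRate"))

#' @rdname recording-accessors
#' @export
setGeneric("channelData", function(x, ...) standardGeneric("channelData"))

#' @rdname recording-accessors
#' @export
setGeneric("activities", function(x, ...) standardGeneric("activities"))

#' @rdname recording-accessors
#' @export
setGeneric("duration", function(x, ...) standardGeneric("duration"))
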