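#' @rdname accessors
#' @export
setGeneric("materials", function(x) standardGeneric("materials"))

#' @rdname accessors
#' @export
setGeneric("speciesOf", function(x) standardGeneric("speciesOf"))

#' @rdname accessors
#' @export
setGeneric("chromIds", function(x) standardGeneric("chromIds"))

#' @rdname accessors
#' @export
setGeneric("markerSites", function(x) standardGeneric("markerSites"))

#' @rdname accessors
#' @export
setGeneric("centromerePos", function(x) standardGeneric("centromerePos"))

#' @rdname accessors
#' @export
setGeneric("probeOrder", function(x) standardGeneric("probeOrder"))

#' @rdname accessors
#' @export
setGeneric("centromereSlot", function(x) standardGeneric("centromereSlot"))

#' @rdname accessors
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))

#' @rdname accessors
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @rdname accessors
#' @export
setGeneric("letterCodes", function(x) standardGeneric("letterCodes"))

#' @rdname accessors
#' @export
setGeneric("primedFlags", function(x) standardGeneric("primedFlags"))

#' @rdname accessors
#' @export
setGeneric("permSequence", function(x) standardGeneric("permSequence"))

#' @rdname accessors
#' @export
setGeneric("foreignRuns", function(x) standardGeneric("foreignRuns"))

#' @rdname accessors
#' @export
setGeneric("missingProbes", function(x) standardGeneric("missingProbes"))

#' @rdname accessors
#' @export
setGeneric("extraSites", function(x) standardGeneric("extraSites"))

#' @rdname accessors
#' @export
setGeneric("eventType", function(x) standardGeneric("eventType"))

#' @rdname accessors
#' @export
setGeneric("eventLabel", function(x) standardGeneric("eventLabel"))

#' @rdname accessors
#' @export
setGeneric("eventChroms", function(x) standardGeneric("eventChroms"))

#' @rdname accessors
#' @export
setGeneric("refInterval", function(x) standardGeneric("refInterval"))
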