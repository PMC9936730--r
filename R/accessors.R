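#' Accessors for karyoCR objects
#'
#' Small accessor functions exposing the slots of the package's S4
#' containers; user code should use these rather than \code{@}.
#'
#' @param x A karyoCR object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
setMethod("materials", "Karyotype", function(x) x@materialId)
#' @rdname accessors
setMethod("materials", "EventMatrix", function(x) x@materials)
#' @rdname accessors
setMethod("materials", "PatternMatrix", function(x) x@materials)

#' @rdname accessors
setMethod("speciesOf", "Karyotype", function(x) x@species)
#' @rdname accessors
setMethod("speciesOf", "EventMatrix",
          function(x) structure(x@species, names = x@materials))
#' @rdname accessors
setMethod("speciesOf", "PatternMatrix",
          function(x) structure(x@species, names = x@materials))

#' @rdname accessors
setMethod("chromIds", "Karyotype", function(x) names(x@chromosomes))
#' @rdname accessors
setMethod("chromIds", "PatternMatrix", function(x) x@chromosomes)
#' @rdname accessors
setMethod("chromIds", "ChromosomeMap", function(x) x@chromId)
#' @rdname accessors
setMethod("chromIds", "Permutation", function(x) x@chromId)

#' @rdname accessors
setMethod("markerSites", "ChromosomeMap", function(x) x@sites)

#' @rdname accessors
setMethod("centromerePos", "ChromosomeMap", function(x) x@centromere)

#' @rdname accessors
setMethod("probeOrder", "ReferenceOrder", function(x) x@probes)
#' @rdname accessors
setMethod("centromereSlot", "ReferenceOrder", function(x) x@centromereSlot)

#' @rdname accessors
setMethod("presence", "EventMatrix",
          function(x) structure(x@presence,
                                dimnames = list(NULL, x@materials)))
#' @rdname accessors
setMethod("eventTable", "EventMatrix", function(x) x@events)

#' @rdname accessors
setMethod("letterCodes", "PatternMatrix",
          function(x) structure(x@letters,
                                dimnames = list(x@materials, x@chromosomes)))
#' @rdname accessors
setMethod("primedFlags", "PatternMatrix",
          function(x) structure(x@primed,
                                dimnames = list(x@materials, x@chromosomes)))

#' @rdname accessors
setMethod("permSequence", "Permutation", function(x) x@sequence)
#' @rdname accessors
setMethod("centromereSlot", "Permutation", function(x) x@centromereRank)
#' @rdname accessors
setMethod("foreignRuns", "Permutation", function(x) x@foreignRuns)
#' @rdname accessors
setMethod("missingProbes", "Permutation", function(x) x@missing)
#' @rdname accessors
setMethod("extraSites", "Permutation", function(x) x@extras)

#' @rdname accessors
setMethod("eventType", "CREvent", function(x) x@type)
#' @rdname accessors
setMethod("eventLabel", "CREvent", function(x) x@label)
#' @rdname accessors
setMethod("eventChroms", "CREvent", function(x) x@chroms)
#' @rdname accessors
setMethod("refInterval", "CREvent", function(x) c(x@refStart, x@refEnd))

#' Extract one chromosome map from a karyotype
#'
#' @param x A [Karyotype-class].
#' @param chromId Chromosome id, e.g. \code{"4H"}.
#' @return A [ChromosomeMap-class].
#' @export
getChromosome <- function(x, chromId) {
  stopifnot(is(x, "Karyotype"))
  if (!chromId %in% names(x@chromosomes))
    stop("karyotype ", x@materialId, " has no chromosome ", chromId)
  x@chromosomes[[chromId]]
}

setMethod("show", "ReferenceOrder", function(object) {
  p <- object@probes
  s <- object@centromereSlot
  cat("ReferenceOrder group ", object@group, ": ",
      paste(append(p, "|", after = s), collapse = " "), "\n", sep = "")
})

setMethod("show", "ChromosomeMap", function(object) {
  cat("ChromosomeMap ", object@chromId, " (", nrow(object@sites),
      " sites, centromere at ", format(object@centromere), ")\n", sep = "")
  cat("  ", formatIdiogram(object), "\n", sep = "")
})

setMethod("show", "Karyotype", function(object) {
  cat("Karyotype ", object@materialId, " [", object@species, "], ",
      length(object@chromosomes), " chromosomes\n", sep = "")
  for (cm in object@chromosomes)
    cat("  ", format(cm@chromId, width = 4), formatIdiogram(cm), "\n")
})

setMethod("show", "EventMatrix", function(object) {
  cat("EventMatrix: ", nrow(object@events), " events x ",
      length(object@materials), " materials (",
      paste(unique(object@species), collapse = ", "), ")\n", sep = "")
})

setMethod("show", "PatternMatrix", function(object) {
  cat("PatternMatrix: ", length(object@materials), " materials x ",
      length(object@chromosomes), " chromosomes\n", sep = "")
})

setMethod("show", "Permutation", function(object) {
  cat("Permutation ", object@chromId, ": ",
      paste(append(as.character(object@sequence), "|",
                   after = object@centromereRank), collapse = " "),
      sep = "")
  if (nrow(object@foreignRuns))
    cat("  [", nrow(object@foreignRuns), " foreign run(s)]", sep = "")
  if (length(object@missing))
    cat("  [missing: ", paste(object@missing, collapse = ","), "]", sep = "")
  cat("\n")
})

setMethod("show", "CREvent", function(object) {
  iv <- if (is.na(object@refStart)) "" else
    paste0(" [", object@refStart, ",", object@refEnd, ")")
  cat("CREvent ", object@type, " ", object@label, " on ",
      paste(object@chroms, collapse = "/"), iv, "\n", sep = "")
})
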