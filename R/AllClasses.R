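#' @import methods
NULL

## Controlled vocabularies shared across the package.
.SUBGENOMES <- c("St", "H", "Y")
.SPECIES <- c("H_bogdanii", "E_sibiricus", "E_nutans")
.EVENT_TYPES <- c("PeI", "PaI", "RT", "T", "Du", "De")

## Expected subgenome composition per species (Triticeae x = 7).
.SPECIES_GENOMES <- list(
  H_bogdanii  = "H",
  E_sibiricus = c("St", "H"),
  E_nutans    = c("St", "H", "Y")
)

#' Parse a chromosome identifier
#'
#' Chromosome identifiers combine the homoeologous group (1-7) with the
#' subgenome symbol, e.g. \code{"4H"}, \code{"2St"}, \code{"5Y"}.
#'
#' @param chromId Character vector of chromosome identifiers.
#' @return A data.frame with columns \code{group} (integer) and
#'   \code{subgenome} (character).
#' @examples
#' parseChromId(c("4H", "2St"))
#' @export
parseChromId <- function(chromId) {
  m <- regmatches(chromId, regexec("^([1-7])(St|H|Y)$", chromId))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed chromosome id(s): ", paste(chromId[bad], collapse = ", "))
  }
  data.frame(
    group = as.integer(vapply(m, `[`, "", 2L)),
    subgenome = vapply(m, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
}

#' ReferenceOrder: the collinearity standard for one homoeologous group
#'
#' Holds the reference marker order (the rearrangement-free D-genome standard)
#' for one homoeologous group, together with the centromere slot: an index in
#' \code{0..length(probes)} naming the gap between two adjacent probes (0 =
#' before the first probe) where the centromere sits.
#'
#' @slot group Integer homoeologous group, 1-7.
#' @slot probes Character vector of probe ids, ordered from the short-arm
#'   telomere.
#' @slot centromereSlot Integer in \code{[0, length(probes)]}.
#' @export
setClass("ReferenceOrder",
  representation(group = "integer", probes = "character",
                 centromereSlot = "integer"))

setValidity("ReferenceOrder", function(object) {
  msg <- character()
  if (length(object@group) != 1L || is.na(object@group) ||
      object@group < 1L || object@group > 7L)
    msg <- c(msg, "group must be a single integer in 1..7")
  if (anyDuplicated(object@probes))
    msg <- c(msg, "duplicate probe ids in reference order")
  if (length(object@centromereSlot) != 1L ||
      object@centromereSlot < 0L ||
      object@centromereSlot > length(object@probes))
    msg <- c(msg, "centromereSlot outside [0, number of probes]")
  if (length(msg)) msg else TRUE
})

#' Construct a ReferenceOrder
#'
#' @param group Homoeologous group (1-7).
#' @param probes Ordered probe ids, short-arm telomere first.
#' @param centromereSlot Gap index of the centromere, in
#'   \code{[0, length(probes)]}.
#' @return A [ReferenceOrder-class] object.
#' @examples
#' ReferenceOrder(4L, c("4H055", "4H138", "4H289"), 2L)
#' @export
ReferenceOrder <- function(group, probes, centromereSlot) {
  new("ReferenceOrder", group = as.integer(group),
      probes = as.character(probes),
      centromereSlot = as.integer(centromereSlot))
}

#' ChromosomeMap: one observed chromosome
#'
#' An ordered single-gene FISH map of one mitotic chromosome. Marker
#' positions are fractions of chromosome length in \code{[0, 1]} measured
#' from the short-arm telomere; only their order (and their side of the
#' centromere) carries information, never distances.
#'
#' @slot chromId Chromosome id, e.g. \code{"4H"}.
#' @slot subgenome One of \code{"St"}, \code{"H"}, \code{"Y"}.
#' @slot group Integer homoeologous group 1-7.
#' @slot centromere Centromere position as a fraction in (0, 1).
#' @slot sites data.frame with columns \code{probe}, \code{position},
#'   \code{arm} (\code{"S"}/\code{"L"}), \code{copy} (integer >= 1), sorted by
#'   strictly increasing position.
#' @export
setClass("ChromosomeMap",
  representation(chromId = "character", subgenome = "character",
                 group = "integer", centromere = "numeric",
                 sites = "data.frame"))

setValidity("ChromosomeMap", function(object) {
  msg <- character()
  p <- tryCatch(parseChromId(object@chromId), error = function(e) NULL)
  if (is.null(p)) {
    msg <- c(msg, "chromId does not parse to (group, subgenome)")
  } else if (p$group != object@group || p$subgenome != object@subgenome) {
    msg <- c(msg, "chromId inconsistent with group/subgenome slots")
  }
  if (object@centromere <= 0 || object@centromere >= 1)
    msg <- c(msg, "centromere must lie strictly inside (0, 1)")
  s <- object@sites
  need <- c("probe", "position", "arm", "copy")
  if (!all(need %in% names(s))) {
    msg <- c(msg, "sites must have columns probe, position, arm, copy")
  } else if (nrow(s)) {
    if (any(diff(s$position) <= 0))
      msg <- c(msg, "site positions must be strictly increasing")
    if (any(s$position < 0 | s$position > 1))
      msg <- c(msg, "site positions outside [0, 1]")
    wantArm <- ifelse(s$position < object@centromere, "S", "L")
    if (!identical(as.character(s$arm), wantArm))
      msg <- c(msg, "arm must be S exactly when position < centromere")
    if (anyDuplicated(s[, c("probe", "copy")]))
      msg <- c(msg, "duplicate (probe, copy) pair among sites")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ChromosomeMap
#'
#' @param chromId Chromosome id such as \code{"4H"}.
#' @param centromere Centromere position, fraction in (0, 1).
#' @param sites data.frame with columns \code{probe}, \code{position} and
#'   optionally \code{copy} (default 1). The \code{arm} column is derived
#'   from position versus centromere.
#' @return A [ChromosomeMap-class] object.
#' @examples
#' ChromosomeMap("7H", 0.45,
#'   data.frame(probe = c("7H081", "7H244"), position = c(0.1, 0.3)))
#' @export
ChromosomeMap <- function(chromId, centromere, sites) {
  p <- parseChromId(chromId)
  if (is.null(sites$copy)) sites$copy <- 1L
  sites <- sites[order(sites$position), , drop = FALSE]
  sites$arm <- ifelse(sites$position < centromere, "S", "L")
  sites <- data.frame(probe = as.character(sites$probe),
                      position = as.numeric(sites$position),
                      arm = sites$arm, copy = as.integer(sites$copy),
                      stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  new("ChromosomeMap", chromId = chromId, subgenome = p$subgenome,
      group = p$group, centromere = as.numeric(centromere), sites = sites)
}

#' Karyotype: all observed chromosomes of one material
#'
#' @slot materialId Material identifier, e.g. \code{"DY"}.
#' @slot species One of \code{"H_bogdanii"}, \code{"E_sibiricus"},
#'   \code{"E_nutans"}.
#' @slot chromosomes Named list of [ChromosomeMap-class], keyed by chromId.
#' @export
setClass("Karyotype",
  representation(materialId = "character", species = "character",
                 chromosomes = "list"))

setValidity("Karyotype", function(object) {
  msg <- character()
  if (!object@species %in% .SPECIES)
    msg <- c(msg, paste("unknown species:", object@species))
  ok <- vapply(object@chromosomes, is, TRUE, "ChromosomeMap")
  if (!all(ok)) msg <- c(msg, "chromosomes must all be ChromosomeMap objects")
  ids <- vapply(object@chromosomes, function(x) x@chromId, "")
  if (!identical(unname(names(object@chromosomes)), unname(ids)))
    msg <- c(msg, "chromosome list names must equal chromIds")
  if (all(ok) && object@species %in% names(.SPECIES_GENOMES)) {
    subs <- vapply(object@chromosomes, function(x) x@subgenome, "")
    allowed <- .SPECIES_GENOMES[[object@species]]
    if (!all(subs %in% allowed))
      msg <- c(msg, paste0("species ", object@species,
                           " cannot carry subgenome(s): ",
                           paste(setdiff(subs, allowed), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Karyotype
#'
#' @param materialId Material identifier.
#' @param species Species code (\code{"H_bogdanii"}, \code{"E_sibiricus"} or
#'   \code{"E_nutans"}).
#' @param chromosomes List of [ChromosomeMap-class] objects.
#' @return A [Karyotype-class] object.
#' @export
Karyotype <- function(materialId, species, chromosomes) {
  names(chromosomes) <- vapply(chromosomes, function(x) x@chromId, "")
  new("Karyotype", materialId = materialId, species = species,
      chromosomes = chromosomes)
}

#' CREvent: one typed chromosomal rearrangement
#'
#' @slot type One of PeI, PaI, RT, T, Du, De.
#' @slot chroms Involved chromosome id(s): one for inversions/Du/De, an
#'   ordered pair for RT and T (source first for T).
#' @slot probes Involved probe ids (may be empty).
#' @slot label Free-text series label, e.g. \code{"PeI II"} or
#'   \code{"RT (4H/6H)"}.
#' @slot refStart,refEnd Half-open reference-slot interval of the event on
#'   its (first) chromosome's reference order; \code{NA} when not applicable.
#' @export
setClass("CREvent",
  representation(type = "character", chroms = "character",
                 probes = "character", label = "character",
                 refStart = "integer", refEnd = "integer"))

setValidity("CREvent", function(object) {
  msg <- character()
  if (!object@type %in% .EVENT_TYPES)
    msg <- c(msg, paste("unknown event type:", object@type))
  n <- length(object@chroms)
  if (object@type %in% c("RT", "T") && n != 2L)
    msg <- c(msg, "RT/T events need exactly two chromosomes")
  if (object@type %in% c("PeI", "PaI", "Du", "De") && n != 1L)
    msg <- c(msg, "inversion/Du/De events involve exactly one chromosome")
  if (length(msg)) msg else TRUE
})

#' Construct a CREvent
#'
#' @param type Event type (PeI, PaI, RT, T, Du, De).
#' @param chroms Involved chromosome id(s).
#' @param label Series label; defaults to the type.
#' @param probes Involved probe ids.
#' @param refStart,refEnd Half-open reference-slot interval (0-based), or NA.
#' @return A [CREvent-class] object.
#' @examples
#' CREvent("RT", c("4H", "6H"), label = "RT (4H/6H)")
#' @export
CREvent <- function(type, chroms, label = type, probes = character(),
                    refStart = NA_integer_, refEnd = NA_integer_) {
  new("CREvent", type = type, chroms = as.character(chroms),
      probes = as.character(probes), label = label,
      refStart = as.integer(refStart), refEnd = as.integer(refEnd))
}

#' EventMatrix: rearrangement events by materials presence grid
#'
#' Rows are events keyed by (chromosome, label); columns are materials with
#' species tags. \code{presence} holds the +/- grid; \code{annotation} keeps
#' the printed superscripts (\code{"'"} species-specific, \code{"''"}
#' possibly ancestral, \code{"0"} subgenome absent) for cross-checking only —
#' no computation consumes it.
#'
#' @slot events data.frame with columns \code{chrom}, \code{label},
#'   \code{type}.
#' @slot materials Character vector of material ids.
#' @slot species Character vector of species codes, parallel to materials.
#' @slot presence Logical matrix, events x materials.
#' @slot annotation Character matrix, events x materials.
#' @export
setClass("EventMatrix",
  representation(events = "data.frame", materials = "character",
                 species = "character", presence = "matrix",
                 annotation = "matrix"))

setValidity("EventMatrix", function(object) {
  msg <- character()
  if (!all(c("chrom", "label", "type") %in% names(object@events)))
    msg <- c(msg, "events needs columns chrom, label, type")
  if (length(object@materials) != length(object@species))
    msg <- c(msg, "materials and species lengths differ")
  if (!all(object@species %in% .SPECIES))
    msg <- c(msg, "unknown species tag")
  if (!identical(dim(object@presence),
                 c(nrow(object@events), length(object@materials))))
    msg <- c(msg, "presence grid dimensions do not match events x materials")
  if (!identical(dim(object@annotation), dim(object@presence)))
    msg <- c(msg, "annotation grid dimensions differ from presence")
  if (anyDuplicated(paste(object@events$chrom, object@events$label)))
    msg <- c(msg, "duplicate (chrom, label) event rows")
  if (length(msg)) msg else TRUE
})

#' PatternMatrix: repeat-FISH pattern codes, materials x chromosomes
#'
#' Each cell is a single letter code (identical letters = identical
#' repeat-FISH pattern within a chromosome column) with an optional prime
#' flag marking a variant that carries additional polymorphic rearrangements.
#'
#' @slot materials Character vector of material ids.
#' @slot species Character vector of species codes, parallel to materials.
#' @slot chromosomes Character vector of chromosome ids (columns).
#' @slot letters Character matrix of single letters a-z, \code{NA} where the
#'   subgenome is absent.
#' @slot primed Logical matrix parallel to \code{letters}.
#' @export
setClass("PatternMatrix",
  representation(materials = "character", species = "character",
                 chromosomes = "character", letters = "matrix",
                 primed = "matrix"))

setValidity("PatternMatrix", function(object) {
  msg <- character()
  if (length(object@materials) != length(object@species))
    msg <- c(msg, "materials and species lengths differ")
  if (!all(object@species %in% .SPECIES))
    msg <- c(msg, "unknown species tag")
  d <- c(length(object@materials), length(object@chromosomes))
  if (!identical(dim(object@letters), d))
    msg <- c(msg, "letters grid dimensions do not match")
  if (!identical(dim(object@primed), dim(object@letters)))
    msg <- c(msg, "primed grid dimensions differ from letters")
  lt <- object@letters[!is.na(object@letters)]
  if (length(lt) && !all(lt %in% letters))
    msg <- c(msg, "letter codes must be single letters a-z")
  if (any(is.na(object@primed) != is.na(object@letters)))
    msg <- c(msg, "primed must be NA exactly where letters is NA")
  if (length(msg)) msg else TRUE
})

#' Permutation: an observed chromosome as a permutation of its reference
#'
#' The own-group, single-copy marker sites of a chromosome expressed as
#' 0-based dense ranks over the (possibly shrunken) reference order, plus the
#' observed centromere rank, with foreign-group runs, missing reference
#' probes and extra copies separated out.
#'
#' @slot chromId Chromosome id.
#' @slot sequence Integer vector: observed order of dense reference ranks,
#'   a permutation of \code{0..n-1}.
#' @slot centromereRank Number of sequence entries observed on the short-arm
#'   side, i.e. the 0-based rank of the centromere token.
#' @slot rankProbes Character vector of probe ids such that
#'   \code{rankProbes[r + 1]} is the probe with dense rank \code{r}.
#' @slot refSlots Integer vector mapping dense ranks back to original
#'   reference indices (before shrinking for missing probes).
#' @slot refCentromereSlot Integer: the reference centromere slot expressed
#'   in dense ranks (number of present markers on the reference short arm).
#' @slot foreignRuns data.frame with columns \code{sourceGroup},
#'   \code{sourceArm}, \code{terminal}, \code{probes} (comma-separated),
#'   \code{positionStart}, \code{positionEnd}.
#' @slot missing Character vector of reference probes absent from the map.
#' @slot extras data.frame with columns \code{probe}, \code{position}
#'   (additional copies of probes already placed).
#' @export
setClass("Permutation",
  representation(chromId = "character", sequence = "integer",
                 centromereRank = "integer", rankProbes = "character",
                 refSlots = "integer", refCentromereSlot = "integer",
                 foreignRuns = "data.frame",
                 missing = "character", extras = "data.frame"))

setValidity("Permutation", function(object) {
  msg <- character()
  n <- length(object@sequence)
  if (n && !setequal(object@sequence, 0:(n - 1L)))
    msg <- c(msg, "sequence is not a permutation of 0..n-1")
  if (object@centromereRank < 0L || object@centromereRank > n)
    msg <- c(msg, "centromereRank outside [0, n]")
  if (length(object@rankProbes) != n)
    msg <- c(msg, "rankProbes length must equal sequence length")
  if (length(object@refSlots) != n)
    msg <- c(msg, "refSlots length must equal sequence length")
  if (length(msg)) msg else TRUE
})
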