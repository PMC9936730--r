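## Cross-material accounting. Two deliberately different counting units:
## species-specific counts use COMPLEXES (a chromosome's whole inversion
## series is one rearrangement; reciprocal-translocation partner rows merge),
## while polymorphic-type counts use raw event types (chromosome + label),
## which is how the survey tables enumerate them.

.isInversion <- function(type) type %in% c("PeI", "PaI")

#' Build per-material rearrangement complexes from an event matrix
#'
#' For each material: all inversion events on one chromosome collapse into a
#' single inversion-series complex; reciprocal-translocation rows sharing an
#' "(A/B)" label merge into one translocation complex; each duplication or
#' deletion row is its own complex. An RT label appearing on a single
#' chromosome row raises a warning and is treated as a one-way
#' translocation.
#'
#' @param x An [EventMatrix-class].
#' @return Named list (by material) of data.frames with columns \code{kind}
#'   and \code{signature}.
#' @export
buildComplexes <- function(x) {
  stopifnot(is(x, "EventMatrix"))
  ev <- x@events
  rt <- ev$type == "RT"
  if (any(rt)) {
    nChrom <- tapply(ev$chrom[rt], ev$label[rt],
                     function(ch) length(unique(ch)))
    lone <- names(nChrom)[nChrom < 2L]
    if (length(lone))
      warning("RT label(s) on a single chromosome row, treated as T: ",
              paste(lone, collapse = ", "))
  }
  out <- list()
  for (j in seq_along(x@materials)) {
    present <- which(x@presence[, j])
    rows <- ev[present, , drop = FALSE]
    kinds <- character()
    sigs <- character()
    inv <- rows[.isInversion(rows$type), , drop = FALSE]
    for (ch in unique(inv$chrom)) {
      kinds <- c(kinds, "inversion_series")
      sigs <- c(sigs, paste0(ch, ":",
                             paste(sort(inv$label[inv$chrom == ch]),
                                   collapse = "+")))
    }
    tra <- rows[rows$type %in% c("RT", "T"), , drop = FALSE]
    for (lb in unique(tra$label)) {
      kinds <- c(kinds, "translocation")
      sigs <- c(sigs, lb)
    }
    cn <- rows[rows$type %in% c("Du", "De"), , drop = FALSE]
    if (nrow(cn)) {
      kinds <- c(kinds, rep("copy_number", nrow(cn)))
      sigs <- c(sigs, paste(cn$chrom, cn$label))
    }
    out[[x@materials[j]]] <- data.frame(kind = kinds, signature = sigs,
                                        stringsAsFactors = FALSE)
  }
  out
}

#' Classify complexes as species-specific, polymorphic or uniformly shared
#'
#' The diploid H-genome outgroup (H. bogdanii) is excluded from the
#' comparison. A complex signature is species-specific for species X iff it
#' occurs identically in every material of X and is not identical-and-
#' uniform across every material of the other Elymus species; polymorphic
#' for X iff present in at least one but not all materials of X; uniformly
#' shared iff uniform in both species.
#'
#' @param complexes Result of [buildComplexes()].
#' @param species Named character vector mapping material id to species
#'   code (e.g. from \code{speciesOf(eventMatrix)}).
#' @return data.frame with columns \code{signature}, \code{kind},
#'   \code{species}, \code{call}.
#' @export
classifySpecificity <- function(complexes, species) {
  species <- species[names(complexes)]
  elymus <- names(species)[species != "H_bogdanii"]
  spp <- unique(species[elymus])
  has <- function(m, sig) sig %in% complexes[[m]]$signature
  allSigs <- unique(do.call(rbind, complexes[elymus]))
  out <- NULL
  for (sp in spp) {
    mine <- elymus[species[elymus] == sp]
    others <- elymus[species[elymus] != sp]
    for (i in seq_len(nrow(allSigs))) {
      sig <- allSigs$signature[i]
      nIn <- sum(vapply(mine, has, TRUE, sig = sig))
      if (nIn == 0L) next
      uniformHere <- nIn == length(mine)
      uniformThere <- length(others) > 0L &&
        all(vapply(others, has, TRUE, sig = sig))
      call <- if (uniformHere && !uniformThere) "species_specific"
      else if (uniformHere && uniformThere) "uniform_shared"
      else "polymorphic"
      out <- rbind(out, data.frame(signature = sig,
                                   kind = allSigs$kind[i],
                                   species = sp, call = call,
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(signature = character(), kind = character(),
                      species = character(), call = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Count species-specific rearrangement complexes
#'
#' @param calls Result of [classifySpecificity()].
#' @param species Species code.
#' @return Integer count of distinct species-specific complex signatures.
#' @export
countSpeciesSpecific <- function(calls, species) {
  length(unique(calls$signature[calls$species == species &
                                  calls$call == "species_specific"]))
}

## Raw event-type keys with reciprocal/one-way translocation partner rows
## deduplicated by label.
.typeKeys <- function(x) {
  ev <- x@events
  ifelse(ev$type %in% c("RT", "T"), ev$label, paste(ev$chrom, ev$label))
}

.typePresence <- function(x, cols) {
  keys <- .typeKeys(x)
  pres <- x@presence[, cols, drop = FALSE]
  uk <- unique(keys)
  out <- matrix(FALSE, length(uk), length(cols), dimnames = list(uk, NULL))
  for (i in seq_along(uk))
    out[i, ] <- apply(pres[keys == uk[i], , drop = FALSE], 2L, any)
  out
}

#' Count polymorphic rearrangement types for a species
#'
#' Counts distinct raw event types (chromosome + label, translocation
#' partner rows merged) present in at least one but not all materials of the
#' species.
#'
#' @param x An [EventMatrix-class].
#' @param species Species code.
#' @return Integer count of polymorphic types.
#' @export
countPolymorphicTypes <- function(x, species) {
  cols <- which(x@species == species)
  tp <- .typePresence(x, cols)
  n <- rowSums(tp)
  sum(n >= 1L & n < length(cols))
}

#' Count polymorphic types shared by exactly k materials
#'
#' @param x An [EventMatrix-class].
#' @param species Species code.
#' @param k Number of materials.
#' @return Integer count of polymorphic types present in exactly \code{k}
#'   materials of the species.
#' @export
countBySharing <- function(x, species, k) {
  cols <- which(x@species == species)
  tp <- .typePresence(x, cols)
  n <- rowSums(tp)
  sum(n == k & n < length(cols))
}

.locusLabel <- function(ref, slot, side = c("left", "right")) {
  side <- match.arg(side)
  p <- ref@probes
  n <- length(p)
  left <- if (slot == 0L) "TEL" else p[slot]
  right <- if (slot == n) "TEL" else p[slot + 1L]
  if (slot == ref@centromereSlot && slot > 0L && slot < n) {
    ## the centromere splits this gap into two loci; a left interval
    ## endpoint cuts on the centromere's right flank and vice versa
    if (side == "left") paste0("CEN|", right) else paste0(left, "|CEN")
  } else {
    paste0(left, "|", right)
  }
}

#' Tally breakpoint reuse across materials and species
#'
#' A breakpoint locus is the open interval between two reference-adjacent
#' probes (or probe-to-telomere/centromere). Its usage count is the number
#' of distinct rearrangement complexes — identical complexes shared within a
#' species deduplicate to one; like-for-like complexes in different species
#' count separately as independent origins — with an interval endpoint in
#' that locus. Loci with usage >= 2 are flagged as reused.
#'
#' @param events data.frame with columns \code{species}, \code{chrom},
#'   \code{label}, \code{ref_start}, \code{ref_end} (half-open reference
#'   marker slots on the chromosome's group reference). Rows with missing
#'   intervals are ignored.
#' @param reference Named list of [ReferenceOrder-class] by group.
#' @return data.frame with columns \code{group}, \code{locus}, \code{count},
#'   \code{reused}, \code{complexes}, sorted by decreasing count.
#' @export
breakpointReuse <- function(events, reference) {
  ev <- events[!is.na(events$ref_start) & !is.na(events$ref_end), ,
               drop = FALSE]
  key <- paste(ev$species, ev$chrom, ev$label, ev$ref_start, ev$ref_end)
  ev <- ev[!duplicated(key), , drop = FALSE]
  if (!nrow(ev))
    return(data.frame(group = integer(), locus = character(),
                      count = integer(), reused = logical(),
                      complexes = character(), stringsAsFactors = FALSE))
  grp <- parseChromId(ev$chrom)$group
  hits <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i) {
    ref <- reference[[as.character(grp[i])]]
    if (is.null(ref)) stop("no reference order for group ", grp[i])
    cx <- paste0(ev$species[i], ":", ev$chrom[i], " ", ev$label[i])
    data.frame(group = grp[i],
               locus = c(.locusLabel(ref, ev$ref_start[i], "left"),
                         .locusLabel(ref, ev$ref_end[i], "right")),
               complex = cx, stringsAsFactors = FALSE)
  }))
  agg <- split(hits, paste(hits$group, hits$locus, sep = "\r"))
  out <- do.call(rbind, lapply(agg, function(h) {
    data.frame(group = h$group[1L], locus = h$locus[1L],
               count = length(unique(h$complex)),
               reused = length(unique(h$complex)) >= 2L,
               complexes = paste(unique(h$complex), collapse = "; "),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$count, out$group, out$locus), , drop = FALSE]
  rownames(out) <- NULL
  out
}
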