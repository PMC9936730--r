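## Marker ORDER drives everything here: fractional positions are consumed
## only to sort sites and place the centromere token. The model is unsigned
## (FISH reports a probe's position, never its orientation).

#' Build the permutation of a chromosome over its reference order
#'
#' Separates the observed marker sites of a chromosome into (i) own-group,
#' single-copy sites, expressed as an unsigned permutation of dense reference
#' ranks with the centromere token placed at its observed rank; (ii) maximal
#' runs of foreign-group sites (translocation/duplication candidates);
#' (iii) reference probes missing from the map; and (iv) extra copies of
#' probes already placed on this chromosome. Missing probes shrink the
#' reference index set, which is re-ranked densely so the sequence is always
#' a permutation of \code{0..n-1}.
#'
#' @param chrom A [ChromosomeMap-class].
#' @param ref The [ReferenceOrder-class] of the chromosome's group.
#' @param manifest Probe manifest data.frame (see [readProbeManifest()]).
#' @return A [Permutation-class].
#' @examples
#' ref <- ReferenceOrder(7L, paste0("7H", 1:4), 2L)
#' man <- data.frame(probe_id = paste0("7H", 1:4), home_group = 7L,
#'                   home_arm = c("S", "S", "L", "L"),
#'                   reference_index = 0:3, multi_site = FALSE)
#' cm <- ChromosomeMap("7H", 0.5, data.frame(probe = paste0("7H", 1:4),
#'                                           position = c(.1, .3, .6, .9)))
#' buildPermutation(cm, ref, man)
#' @export
buildPermutation <- function(chrom, ref, manifest) {
  stopifnot(is(chrom, "ChromosomeMap"), is(ref, "ReferenceOrder"))
  if (chrom@group != ref@group)
    stop("chromosome group ", chrom@group,
         " does not match reference group ", ref@group)
  s <- chrom@sites
  idx <- match(s$probe, manifest$probe_id)
  if (anyNA(idx))
    stop("unknown probe(s) not in manifest: ",
         paste(unique(s$probe[is.na(idx)]), collapse = ", "))
  homeGroup <- manifest$home_group[idx]
  homeArm <- manifest$home_arm[idx]
  own <- homeGroup == chrom@group

  ## Foreign runs: maximal runs of position-consecutive foreign sites of one
  ## source group. Terminal = touching either chromosome end.
  fr <- data.frame(sourceGroup = integer(), sourceArm = character(),
                   terminal = logical(), probes = character(),
                   positionStart = numeric(), positionEnd = numeric(),
                   stringsAsFactors = FALSE)
  if (any(!own)) {
    runId <- cumsum(c(TRUE, diff(which(!own)) > 1L))
    for (r in split(which(!own), runId)) {
      for (g in unique(homeGroup[r])) {
        rg <- r[homeGroup[r] == g]
        fr <- rbind(fr, data.frame(
          sourceGroup = g,
          sourceArm = homeArm[rg[1L]],
          terminal = min(r) == 1L || max(r) == nrow(s),
          probes = paste(s$probe[rg], collapse = ","),
          positionStart = s$position[rg[1L]],
          positionEnd = s$position[rg[length(rg)]],
          stringsAsFactors = FALSE))
      }
    }
  }

  ## Own-group sites: first occurrence of a probe (lowest copy) is placed;
  ## later occurrences are extra copies (duplication candidates).
  ownIdx <- which(own)
  ownIdx <- ownIdx[order(s$position[ownIdx])]
  firstOcc <- ownIdx[!duplicated(s$probe[ownIdx])]
  extraOcc <- setdiff(ownIdx, firstOcc)
  extras <- data.frame(probe = s$probe[extraOcc],
                       position = s$position[extraOcc],
                       stringsAsFactors = FALSE)

  refIdx <- match(s$probe[firstOcc], ref@probes)
  if (anyNA(refIdx))
    stop("own-group probe(s) absent from reference order: ",
         paste(s$probe[firstOcc][is.na(refIdx)], collapse = ", "))
  presentSlots <- sort(unique(refIdx))         # 1-based slots into ref@probes
  dense <- match(refIdx, presentSlots) - 1L    # dense 0-based ranks
  missing <- setdiff(ref@probes, s$probe[firstOcc])
  cenRank <- sum(s$position[firstOcc] < chrom@centromere)

  new("Permutation", chromId = chrom@chromId,
      sequence = as.integer(dense),
      centromereRank = as.integer(cenRank),
      rankProbes = ref@probes[presentSlots],
      refSlots = as.integer(presentSlots - 1L),
      refCentromereSlot = sum(presentSlots - 1L < ref@centromereSlot),
      foreignRuns = fr, missing = missing, extras = extras)
}

## Unsigned breakpoint count of an integer sequence (0-based dense ranks),
## framed by telomere sentinels -1 and n. The centromere token never takes
## part in adjacency testing.
.breakpointCount <- function(s) {
  framed <- c(-1L, s, length(s))
  sum(abs(diff(framed)) != 1L)
}

#' Count unsigned breakpoints of a permutation
#'
#' Reference adjacencies (including the two telomere sentinels) that are not
#' adjacent in the observed sequence. The centromere token is ignored: its
#' position is an observation about arm membership, not an adjacency.
#'
#' @param perm A [Permutation-class] or a bare integer sequence of dense
#'   ranks \code{0..n-1}.
#' @return Integer breakpoint count in \code{[0, n + 1]}.
#' @examples
#' countBreakpoints(c(0L, 2L, 1L, 3L))  # 2
#' @export
countBreakpoints <- function(perm) {
  s <- if (is(perm, "Permutation")) perm@sequence else as.integer(perm)
  if (!length(s)) stop("empty sequence")
  .breakpointCount(s)
}
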