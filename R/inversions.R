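## Minimal inversion scenarios by exhaustive search over unsigned reversals
## of the token-inclusive sequence. The centromere token (coded -1 in the
## internal vectors) takes part in reversal intervals — moving it is exactly
## what makes an inversion pericentric — but never in breakpoint counting.

.TOKEN <- -1L

#' Construct a bare Permutation
#'
#' Convenience constructor for a [Permutation-class] not derived from an
#' observed chromosome map (simulation, testing).
#'
#' @param sequence Integer permutation of \code{0..n-1} (observed order of
#'   dense reference ranks).
#' @param centromereRank Observed 0-based rank of the centromere token.
#' @param refCentromereSlot Reference centromere slot in dense ranks;
#'   defaults to \code{centromereRank}.
#' @param chromId Chromosome id, cosmetic.
#' @param rankProbes Probe ids by dense rank; defaults to \code{m<rank>}.
#' @return A [Permutation-class].
#' @export
newPermutation <- function(sequence, centromereRank,
                           refCentromereSlot = centromereRank,
                           chromId = "sim",
                           rankProbes = paste0("m", seq_along(sequence))) {
  n <- length(sequence)
  new("Permutation", chromId = chromId, sequence = as.integer(sequence),
      centromereRank = as.integer(centromereRank),
      rankProbes = rankProbes, refSlots = seq_len(n) - 1L,
      refCentromereSlot = as.integer(refCentromereSlot),
      foreignRuns = data.frame(), missing = character(),
      extras = data.frame())
}

#' Token-inclusive reference and observed sequences of a permutation
#'
#' @param perm A [Permutation-class].
#' @return Integer vector of dense ranks with the centromere token coded as
#'   \code{-1}.
#' @export
referenceSeq <- function(perm) {
  n <- length(perm@sequence)
  append(if (n) 0:(n - 1L) else integer(), .TOKEN,
         after = perm@refCentromereSlot)
}

#' @rdname referenceSeq
#' @export
observedSeq <- function(perm) {
  append(perm@sequence, .TOKEN, after = perm@centromereRank)
}

#' Apply one reversal to a token-inclusive sequence
#'
#' @param state Integer vector (markers plus the \code{-1} centromere token).
#' @param start,end Half-open 0-based interval over \code{state}.
#' @return The reversed state.
#' @export
applyReversal <- function(state, start, end) {
  stopifnot(start >= 0, end <= length(state), end - start >= 2)
  i <- start + 1L
  state[i:end] <- state[end:i]
  state
}

#' Apply a scenario (ordered reversal list) to a state
#'
#' @param state Token-inclusive integer vector, or a [Permutation-class]
#'   (whose reference sequence is then the starting state).
#' @param scenario data.frame with columns \code{start}, \code{end}
#'   (half-open, 0-based) and \code{classification}.
#' @return The transformed token-inclusive state.
#' @export
applyScenario <- function(state, scenario) {
  if (is(state, "Permutation")) state <- referenceSeq(state)
  for (k in seq_len(nrow(scenario)))
    state <- applyReversal(state, scenario$start[k], scenario$end[k])
  state
}

#' Classify an inversion step as pericentric or paracentric
#'
#' Pericentric (PeI) iff the reversal interval contains the centromere token
#' at the moment the step is applied; paracentric (PaI) otherwise.
#'
#' @param interval Half-open 0-based interval \code{c(start, end)}.
#' @param tokenPos 0-based position of the centromere token in the current
#'   sequence.
#' @return \code{"PeI"} or \code{"PaI"}.
#' @examples
#' classifyInversion(c(1, 4), 2)  # "PeI"
#' classifyInversion(c(3, 5), 0)  # "PaI"
#' @export
classifyInversion <- function(interval, tokenPos) {
  if (interval[1] <= tokenPos && tokenPos < interval[2]) "PeI" else "PaI"
}

.markerBreakpoints <- function(state) {
  .breakpointCount(state[state != .TOKEN])
}

## Depth-limited enumeration of ALL reversal paths of exactly `depth` steps
## from `state` to `target`. Prunes on the provable bound d >= ceil(b/2)
## (each reversal heals at most two marker breakpoints) and solves the last
## step constructively: with distinct elements the reversal turning one
## state into another is unique when it exists.
.searchAll <- function(state, target, depth, lastI = 0L, lastJ = 0L) {
  if (depth == 0L)
    return(if (identical(state, target)) list(list()) else list())
  if (depth == 1L) {
    d <- which(state != target)
    if (!length(d)) return(list())
    i <- d[1L]
    j <- d[length(d)]
    if (j - i < 1L || (i == lastI && j == lastJ)) return(list())
    if (!identical(state[j:i], target[i:j])) return(list())
    cls <- if (any(state[i:j] == .TOKEN)) "PeI" else "PaI"
    return(list(list(list(i = i, j = j, cls = cls))))
  }
  m <- length(state)
  out <- list()
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      if (i == lastI && j == lastJ) next
      ns <- state
      ns[i:j] <- state[j:i]
      ## callers relabel so that target's markers are the identity: marker
      ## breakpoints of ns are then breakpoints relative to target
      b <- .markerBreakpoints(ns)
      if ((b + 1L) %/% 2L > depth - 1L) next
      cls <- if (any(state[i:j] == .TOKEN)) "PeI" else "PaI"
      step <- list(i = i, j = j, cls = cls)
      for (p in .searchAll(ns, target, depth - 1L, i, j))
        out[[length(out) + 1L]] <- c(list(step), p)
    }
  }
  out
}

## Relabel `state` so that `target`'s marker order becomes the identity;
## breakpoints of the relabeled state are then breakpoints relative to
## target. Token entries stay tokens.
.relDiff <- function(state, target) {
  tm <- target[target != .TOKEN]
  rank <- integer(length(tm))
  rank[tm + 1L] <- seq_along(tm) - 1L
  out <- state
  mk <- state != .TOKEN
  out[mk] <- rank[state[mk] + 1L]
  out
}

.stepsToFrame <- function(steps) {
  if (!length(steps))
    return(data.frame(start = integer(), end = integer(),
                      classification = character(),
                      stringsAsFactors = FALSE))
  data.frame(start = vapply(steps, function(s) s$i - 1L, 1L),
             end = vapply(steps, function(s) s$j, 1L),
             classification = vapply(steps, function(s) s$cls, ""),
             stringsAsFactors = FALSE)
}

.scenarioKey <- function(sc) {
  paste(sprintf("%03d,%03d", sc$start, sc$end), collapse = ";")
}

#' Enumerate all minimal inversion scenarios for a permutation
#'
#' Exhaustive search over reversals of contiguous intervals (length >= 2
#' elements of the token-inclusive sequence) transforming the reference
#' order into the observed order. Returns the minimal number of reversals
#' and every scenario of that length, each step classified pericentric or
#' paracentric, sorted canonically (lexicographically by interval list).
#'
#' @param perm A [Permutation-class] with no foreign runs (excise them
#'   first; see [inferEvents()]).
#' @param maxDepth Maximum scenario length searched (default 4). If the true
#'   distance exceeds it, \code{dMin} is \code{Inf} and no scenarios are
#'   returned.
#' @return List with elements \code{dMin} (integer or \code{Inf}) and
#'   \code{scenarios} (list of data.frames with columns \code{start},
#'   \code{end}, \code{classification}).
#' @examples
#' p <- newPermutation(c(0L, 2L, 1L, 3L), 4L)
#' minInversionScenarios(p)
#' @export
minInversionScenarios <- function(perm, maxDepth = 4L) {
  stopifnot(is(perm, "Permutation"))
  if (nrow(perm@foreignRuns))
    stop("permutation still carries foreign runs; excise them first")
  n <- length(perm@sequence)
  if (n > 12L)
    stop("sequence longer than 12 markers; exhaustive search not supported")
  start0 <- referenceSeq(perm)
  target0 <- observedSeq(perm)
  if (identical(start0, target0))
    return(list(dMin = 0L, scenarios = list(.stepsToFrame(list()))))
  ## relabel so the observed marker order becomes the identity; reversal
  ## intervals are positional and unaffected by relabelling
  start <- .relDiff(start0, target0)
  target <- .relDiff(target0, target0)
  b <- .markerBreakpoints(start)
  lb <- max(1L, (b + 1L) %/% 2L)
  if (lb > maxDepth) return(list(dMin = Inf, scenarios = list()))
  for (d in lb:maxDepth) {
    found <- .searchAll(start, target, d)
    if (length(found)) {
      scen <- lapply(found, .stepsToFrame)
      scen <- scen[order(vapply(scen, .scenarioKey, ""))]
      return(list(dMin = d, scenarios = scen))
    }
  }
  list(dMin = Inf, scenarios = list())
}
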