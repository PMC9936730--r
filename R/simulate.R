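## Karyotype simulator with known ground truth. Chromosomes start as
## identity copies of the reference order; rearrangements are applied as
## operations on the token-inclusive probe sequence ("CEN" = centromere),
## then positions are re-spaced uniformly within each arm. Marker order,
## not spacing, is what the inference stages consume, so uniform re-spacing
## loses nothing.

#' Build a synthetic reference order set
#'
#' @param groups Homoeologous groups to cover.
#' @param markersPerGroup Markers per group (7-10 in practice).
#' @param centromereSlot Centromere slot per group; default places ~40% of
#'   markers on the short arm.
#' @return Named list of [ReferenceOrder-class] by group.
#' @export
simReference <- function(groups = 1:7, markersPerGroup = 8L,
                         centromereSlot = max(1L,
                                              round(markersPerGroup * 0.4))) {
  out <- lapply(groups, function(g)
    ReferenceOrder(g, sprintf("g%dm%02d", g, seq_len(markersPerGroup)),
                   centromereSlot))
  names(out) <- as.character(groups)
  out
}

#' Derive a probe manifest from a reference order set
#'
#' @param reference Named list of [ReferenceOrder-class].
#' @return Manifest data.frame as produced by [readProbeManifest()].
#' @export
manifestFromReference <- function(reference) {
  do.call(rbind, lapply(reference, function(r) {
    n <- length(r@probes)
    data.frame(probe_id = r@probes, home_group = r@group,
               home_arm = ifelse(seq_len(n) - 1L < r@centromereSlot,
                                 "S", "L"),
               reference_index = seq_len(n) - 1L,
               multi_site = FALSE, stringsAsFactors = FALSE)
  }))
}

## One token-inclusive probe sequence per chromosome; "CEN" is the token.
.identitySeqs <- function(reference, species) {
  subs <- .SPECIES_GENOMES[[species]]
  seqs <- list()
  for (sub in subs) {
    for (g in names(reference)) {
      r <- reference[[g]]
      seqs[[paste0(r@group, sub)]] <-
        append(r@probes, "CEN", after = r@centromereSlot)
    }
  }
  seqs
}

.seqCheck <- function(seqs, chrom) {
  if (is.null(seqs[[chrom]]))
    stop("simulation spec error: no chromosome ", chrom)
  seqs[[chrom]]
}

.applySimEvent <- function(seqs, ev) {
  type <- ev$type
  if (type %in% c("PeI", "PaI")) {
    s <- .seqCheck(seqs, ev$chrom)
    a <- ev$start; b <- ev$end
    if (a < 0L || b > length(s) || b - a < 2L)
      stop("simulation spec error: inversion interval [", a, ",", b,
           ") out of range on ", ev$chrom)
    spans <- "CEN" %in% s[(a + 1L):b]
    if ((type == "PeI") != spans)
      stop("simulation spec error: interval [", a, ",", b, ") on ",
           ev$chrom, " is ", if (spans) "pericentric" else "paracentric",
           " but declared ", type)
    seqs[[ev$chrom]] <- applyReversal(s, a, b)
  } else if (type == "RT") {
    a <- .seqCheck(seqs, ev$chroms[1L]); b <- .seqCheck(seqs, ev$chroms[2L])
    la <- ev$len[1L]; lb <- ev$len[2L]
    if (la < 1L || lb < 1L || "CEN" %in% a[1:la] || "CEN" %in% b[1:lb])
      stop("simulation spec error: RT runs must be >= 1 marker and stay ",
           "within the short arm")
    seqs[[ev$chroms[1L]]] <- c(b[1:lb], a[-(1:la)])
    seqs[[ev$chroms[2L]]] <- c(a[1:la], b[-(1:lb)])
  } else if (type == "T") {
    src <- .seqCheck(seqs, ev$from); dst <- .seqCheck(seqs, ev$to)
    len <- ev$len
    end <- if (is.null(ev$fromEnd)) "tail" else ev$fromEnd
    run <- if (end == "tail") src[(length(src) - len + 1L):length(src)]
           else src[1:len]
    if ("CEN" %in% run)
      stop("simulation spec error: T run crosses the centromere")
    seqs[[ev$from]] <- if (end == "tail") src[1:(length(src) - len)]
                       else src[-(1:len)]
    seqs[[ev$to]] <- c(run, dst)
  } else if (type == "Du") {
    s <- .seqCheck(seqs, ev$chrom)
    if (ev$at < 0L || ev$at > length(s))
      stop("simulation spec error: Du insertion slot out of range")
    seqs[[ev$chrom]] <- append(s, ev$probe, after = ev$at)
  } else if (type == "De") {
    s <- .seqCheck(seqs, ev$chrom)
    hit <- which(s == ev$probe)
    if (!length(hit))
      stop("simulation spec error: De probe ", ev$probe, " not on ",
           ev$chrom)
    seqs[[ev$chrom]] <- s[-hit[1L]]
  } else stop("simulation spec error: unknown event type ", type)
  seqs
}

.seqToChromosomeMap <- function(chrom, s, centromere = 0.45) {
  cen <- which(s == "CEN")
  sArm <- s[seq_len(cen - 1L)]
  lArm <- if (cen < length(s)) s[(cen + 1L):length(s)] else character()
  pos <- c(if (length(sArm)) centromere * seq_along(sArm) /
             (length(sArm) + 1L),
           if (length(lArm)) centromere + (1 - centromere) *
             seq_along(lArm) / (length(lArm) + 1L))
  probes <- c(sArm, lArm)
  copy <- stats::ave(seq_along(probes), probes, FUN = seq_along)
  ChromosomeMap(chrom, centromere,
                data.frame(probe = probes, position = pos,
                           copy = as.integer(copy),
                           stringsAsFactors = FALSE))
}

.truthEvent <- function(ev, seqs) {
  if (ev$type %in% c("PeI", "PaI")) {
    s <- seqs[[ev$chrom]]
    vals <- setdiff(s[(ev$start + 1L):ev$end], "CEN")
    CREvent(ev$type, ev$chrom, label = paste(ev$type, ev$chrom),
            probes = vals)
  } else if (ev$type == "RT") {
    chroms <- sort(ev$chroms)
    CREvent("RT", chroms,
            label = paste0("RT (", chroms[1L], "/", chroms[2L], ")"))
  } else if (ev$type == "T") {
    CREvent("T", c(ev$from, ev$to),
            label = paste0("T (", ev$from, "->", ev$to, ")"))
  } else if (ev$type == "Du") {
    CREvent("Du", ev$chrom, label = paste0("Du (", ev$probe, ")"),
            probes = ev$probe)
  } else {
    CREvent("De", ev$chrom, label = paste0("De (", ev$probe, ")"),
            probes = ev$probe)
  }
}

#' Simulate a karyotype with known ground-truth rearrangements
#'
#' Starts from identity chromosomes over the reference and applies the
#' given events in order. Fully deterministic: identical inputs give
#' identical outputs.
#'
#' @param reference Named list of [ReferenceOrder-class] by group.
#' @param species Species code (fixes the subgenome complement).
#' @param materialId Material id for the simulated karyotype.
#' @param events List of event specifications:
#'   \code{list(type = "PeI"/"PaI", chrom, start, end)} with a half-open
#'   0-based interval over the token-inclusive sequence;
#'   \code{list(type = "RT", chroms = c(A, B), len = c(lenA, lenB))}
#'   swapping distal short-arm runs;
#'   \code{list(type = "T", from, to, len, fromEnd = "tail"/"head")};
#'   \code{list(type = "Du", probe, chrom, at)};
#'   \code{list(type = "De", chrom, probe)}.
#' @param centromere Centromere fraction used for re-spacing (default 0.45,
#'   a typical submetacentric arm ratio).
#' @return List with \code{karyotype} ([Karyotype-class]) and \code{truth}
#'   (list of [CREvent-class] ground-truth events).
#' @export
simulateKaryotype <- function(reference, species = "E_sibiricus",
                              materialId = "sim", events = list(),
                              centromere = 0.45) {
  seqs <- .identitySeqs(reference, species)
  truth <- list()
  for (ev in events) {
    truth[[length(truth) + 1L]] <- .truthEvent(ev, seqs)
    seqs <- .applySimEvent(seqs, ev)
  }
  chroms <- lapply(names(seqs), function(cid)
    .seqToChromosomeMap(cid, seqs[[cid]], centromere))
  list(karyotype = Karyotype(materialId, species, chroms), truth = truth)
}

#' Sample breakpoint-disjoint inversion events for one chromosome
#'
#' Samples \code{k} inversions with >= \code{minLen} markers each, pairwise
#' separated marker intervals (so every reversal contributes two fresh
#' breakpoints and the true minimal scenario length is exactly \code{k}).
#' Intervals strictly spanning the centromere slot include the token and
#' are pericentric; all others are paracentric.
#'
#' @param ref A [ReferenceOrder-class].
#' @param chrom Chromosome id the events apply to.
#' @param k Number of inversions.
#' @param minLen Minimum markers per inversion (>= 2).
#' @param maxTries Rejection-sampling cap.
#' @return List of inversion event specifications (see
#'   [simulateKaryotype()]), sorted by start, or NULL if none found.
#' @export
sampleDisjointInversions <- function(ref, chrom, k, minLen = 2L,
                                     maxTries = 200L) {
  n <- length(ref@probes)
  cen <- ref@centromereSlot
  for (try in seq_len(maxTries)) {
    ## marker-slot intervals [a, b), b - a >= minLen, separated by >= 1
    starts <- sort(sample(0:(n - minLen), k))
    ends <- integer(k)
    ok <- TRUE
    for (i in seq_len(k)) {
      lo <- starts[i] + minLen
      hi <- if (i < k) starts[i + 1L] - 1L else n
      if (lo > hi) { ok <- FALSE; break }
      choices <- lo:hi
      ends[i] <- choices[sample.int(length(choices), 1L)]
    }
    if (!ok) next
    evs <- lapply(seq_len(k), function(i) {
      ## convert marker-slot interval [a, b) to token-inclusive
      ## coordinates: marker m sits at position m (m < cen) or m + 1
      a <- starts[i]; b <- ends[i]
      if (a < cen && cen < b)
        list(type = "PeI", chrom = chrom, start = a, end = b + 1L)
      else if (a >= cen)
        list(type = "PaI", chrom = chrom, start = a + 1L, end = b + 1L)
      else
        list(type = "PaI", chrom = chrom, start = a, end = b)
    })
    return(evs)
  }
  NULL
}

#' Simulate a repeat-FISH pattern matrix with known variant counts
#'
#' Starts from an all-\code{a} grid, assigns a fresh letter to
#' \code{nVariantCells} randomly chosen cells (each altered cell gets a
#' column-unique letter) and primes \code{nPrimed} of the altered cells.
#' The expected summary is computed from the construction itself, serving
#' as an independent oracle for [countVariants()].
#'
#' @param seed Integer seed.
#' @param materials Material ids (rows).
#' @param chromosomes Chromosome ids (columns).
#' @param nVariantCells Number of cells to alter.
#' @param nPrimed Number of altered cells to prime (<= nVariantCells).
#' @param species Species tag for all rows.
#' @return List with \code{matrix} ([PatternMatrix-class]) and
#'   \code{expected} (per-chromosome/genome/total variant and primed
#'   counts).
#' @export
simulatePatternMatrix <- function(seed, materials, chromosomes,
                                  nVariantCells, nPrimed = 0L,
                                  species = "E_sibiricus") {
  nr <- length(materials); nc <- length(chromosomes)
  if (nVariantCells > nr * nc)
    stop("spec error: more variant cells than grid cells")
  if (nPrimed > nVariantCells)
    stop("spec error: more primed cells than variant cells")
  if (nVariantCells > nc * 25L)
    stop("spec error: letter alphabet exhausted")
  set.seed(seed)
  lt <- matrix("a", nr, nc)
  pr <- matrix(FALSE, nr, nc)
  cells <- sample(nr * nc, nVariantCells)
  nextLetter <- rep(2L, nc)  # per-column cursor into letters
  for (cell in cells) {
    j <- (cell - 1L) %/% nr + 1L
    i <- (cell - 1L) %% nr + 1L
    if (nextLetter[j] > 26L) next  # cannot happen under the checks above
    lt[i, j] <- letters[nextLetter[j]]
    nextLetter[j] <- nextLetter[j] + 1L
  }
  primedCells <- if (nPrimed) sample(cells, nPrimed) else integer()
  pr[primedCells] <- TRUE
  altered <- tabulate((cells - 1L) %/% nr + 1L, nbins = nc)
  perChrom <- ifelse(altered < nr, 1L, 0L) + altered
  primedPer <- tabulate((primedCells - 1L) %/% nr + 1L, nbins = nc)
  names(perChrom) <- names(primedPer) <- chromosomes
  sub <- parseChromId(chromosomes)$subgenome
  expected <- list(
    perChromosome = perChrom,
    perGenome = vapply(split(perChrom, sub), sum, 1L),
    total = sum(perChrom),
    primedPerChromosome = primedPer,
    primedTotal = sum(primedPer))
  mat <- new("PatternMatrix", materials = materials,
             species = rep(species, nr), chromosomes = chromosomes,
             letters = lt, primed = pr)
  list(matrix = mat, expected = expected)
}
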