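## Event inference: foreign-run excision -> translocation calls ->
## copy-number calls -> minimal inversion scenarios on the residual
## own-group permutation. Mirrors the practice of reading inversions from
## own-group probe order and translocations from cross-group signals.

.buildAllPermutations <- function(karyotype, reference, manifest) {
  lapply(karyotype@chromosomes, function(cm) {
    ref <- reference[[as.character(cm@group)]]
    if (is.null(ref))
      stop("no reference order for group ", cm@group)
    buildPermutation(cm, ref, manifest)
  })
}

## A single-probe terminal foreign site is a translocation candidate only if
## the probe's home site is vacant; otherwise it is a duplication candidate.
.eligibleTerminalRuns <- function(karyotype, perms, manifest) {
  out <- list()
  for (cid in names(perms)) {
    fr <- perms[[cid]]@foreignRuns
    if (!nrow(fr)) next
    for (k in seq_len(nrow(fr))) {
      if (!fr$terminal[k]) next
      probes <- strsplit(fr$probes[k], ",", fixed = TRUE)[[1]]
      if (length(probes) == 1L) {
        sub <- parseChromId(cid)$subgenome
        home <- paste0(fr$sourceGroup[k], sub)
        if (home %in% names(karyotype@chromosomes)) {
          homeSites <- karyotype@chromosomes[[home]]@sites$probe
          if (probes %in% homeSites) next  # home occupied -> Du candidate
        }
      }
      out[[length(out) + 1L]] <- list(chrom = cid,
                                      sourceGroup = fr$sourceGroup[k],
                                      probes = probes)
    }
  }
  out
}

#' Detect reciprocal and one-way translocations
#'
#' Terminal foreign-group marker runs are paired across chromosomes: a run
#' on A sourced from B's group matched by a run on B sourced from A's group
#' yields one reciprocal translocation RT(A, B); an unpaired run yields a
#' one-way translocation from the same-subgenome chromosome of its source
#' group. Interstitial foreign probes are never translocations (they are
#' duplication candidates; see [detectCopyNumber()]).
#'
#' @param karyotype A [Karyotype-class].
#' @param reference Named list of [ReferenceOrder-class] by group.
#' @param manifest Probe manifest data.frame.
#' @param perms Optional precomputed permutations (named by chromId).
#' @return List of [CREvent-class] of types RT and T.
#' @export
detectTranslocations <- function(karyotype, reference, manifest,
                                 perms = NULL) {
  if (is.null(perms))
    perms <- .buildAllPermutations(karyotype, reference, manifest)
  runs <- .eligibleTerminalRuns(karyotype, perms, manifest)
  if (!length(runs)) return(list())
  used <- rep(FALSE, length(runs))
  groupOf <- function(cid) parseChromId(cid)$group
  subOf <- function(cid) parseChromId(cid)$subgenome
  events <- list()
  ord <- order(vapply(runs, `[[`, "", "chrom"))
  for (a in ord) {
    if (used[a]) next
    ra <- runs[[a]]
    ## reciprocal partner: a chromosome of the run's source group carrying a
    ## terminal run sourced from this chromosome's group
    cand <- which(!used & seq_along(runs) != a &
                    vapply(runs, function(r) groupOf(r$chrom), 1L) ==
                      ra$sourceGroup &
                    vapply(runs, `[[`, 1L, "sourceGroup") ==
                      groupOf(ra$chrom))
    if (length(cand)) {
      same <- cand[vapply(runs[cand], function(r) subOf(r$chrom), "") ==
                     subOf(ra$chrom)]
      b <- if (length(same)) same[1L] else cand[1L]
      rb <- runs[[b]]
      used[c(a, b)] <- TRUE
      chroms <- sort(c(ra$chrom, rb$chrom))
      events[[length(events) + 1L]] <-
        CREvent("RT", chroms,
                label = paste0("RT (", chroms[1L], "/", chroms[2L], ")"),
                probes = c(ra$probes, rb$probes))
    }
  }
  for (a in ord) {
    if (used[a]) next
    ra <- runs[[a]]
    used[a] <- TRUE
    src <- paste0(ra$sourceGroup, subOf(ra$chrom))
    events[[length(events) + 1L]] <-
      CREvent("T", c(src, ra$chrom),
              label = paste0("T (", src, "->", ra$chrom, ")"),
              probes = ra$probes)
  }
  events
}

#' Detect duplications and deletions from probe copy numbers
#'
#' A probe observed at more sites within a subgenome than its declared
#' complement (1, or 2 for multi-site probes) yields a duplication call at
#' each extra site; a probe absent from its home chromosome while both of
#' its nearest reference neighbours are present there yields a deletion call
#' (the neighbour requirement distinguishes deletion from a truncated map).
#'
#' @inheritParams detectTranslocations
#' @return List of [CREvent-class] of types Du and De.
#' @export
detectCopyNumber <- function(karyotype, reference, manifest, perms = NULL) {
  events <- list()
  chroms <- karyotype@chromosomes
  info <- do.call(rbind, lapply(names(chroms), function(cid) {
    s <- chroms[[cid]]@sites
    if (!nrow(s)) return(NULL)
    data.frame(chrom = cid, sub = chroms[[cid]]@subgenome,
               probe = s$probe, copy = s$copy, stringsAsFactors = FALSE)
  }))
  for (sub in unique(info$sub)) {
    di <- info[info$sub == sub, , drop = FALSE]
    for (p in unique(di$probe)) {
      mrow <- manifest[manifest$probe_id == p, , drop = FALSE]
      if (!nrow(mrow)) next
      complement <- if (mrow$multi_site[1L]) 2L else 1L
      dp <- di[di$probe == p, , drop = FALSE]
      home <- paste0(mrow$home_group[1L], sub)
      if (nrow(dp) > complement) {
        ## keep the first-copy home site (if any) as legitimate; every other
        ## site is an extra -> Du
        legit <- which(dp$chrom == home & dp$copy == 1L)[1L]
        if (is.na(legit)) legit <- 1L
        extraChroms <- unique(dp$chrom[-legit])
        for (ec in extraChroms)
          events[[length(events) + 1L]] <-
            CREvent("Du", ec, label = paste0("Du (", p, ")"), probes = p)
      }
    }
    ## deletions: own-group probes absent from their home chromosome AND
    ## from the whole subgenome (a probe sitting on another chromosome is
    ## translocated/duplicated, not deleted)
    for (cid in names(chroms)) {
      cm <- chroms[[cid]]
      if (cm@subgenome != sub) next
      ref <- reference[[as.character(cm@group)]]
      if (is.null(ref)) next
      present <- cm@sites$probe
      for (p in setdiff(ref@probes, present)) {
        if (p %in% di$probe) next
        at <- match(p, ref@probes)
        ix <- c(at - 1L, at + 1L, at - 2L, at + 2L)
        ix <- ix[ix >= 1L & ix <= length(ref@probes)]
        nb <- utils::head(ref@probes[ix], 2L)
        if (length(nb) >= 2L && all(nb %in% present))
          events[[length(events) + 1L]] <-
            CREvent("De", cid, label = paste0("De (", p, ")"), probes = p)
      }
    }
  }
  events
}

.roman <- function(i) as.character(utils::as.roman(i))

#' Infer all rearrangement events of a karyotype
#'
#' Composition of the inference stages: permutations are built per
#' chromosome, terminal foreign runs become translocation calls, copy-number
#' deviations become duplication/deletion calls, and the residual own-group
#' permutation of each chromosome is solved for its minimal inversion
#' scenarios. The canonical (lexicographically first) scenario names the
#' inversion events; the full minimal scenario set is returned alongside.
#'
#' @inheritParams detectTranslocations
#' @param maxDepth Maximum inversion-scenario length searched per
#'   chromosome.
#' @return List with \code{events} (list of [CREvent-class]) and
#'   \code{scenarios} (per-chromosome results of
#'   [minInversionScenarios()]).
#' @export
inferEvents <- function(karyotype, reference, manifest, maxDepth = 4L) {
  perms <- .buildAllPermutations(karyotype, reference, manifest)
  events <- detectTranslocations(karyotype, reference, manifest, perms)
  events <- c(events,
              detectCopyNumber(karyotype, reference, manifest, perms))
  scenarios <- list()
  for (cid in names(perms)) {
    perm <- perms[[cid]]
    perm@foreignRuns <- data.frame()  # excised: handled above
    res <- minInversionScenarios(perm, maxDepth = maxDepth)
    scenarios[[cid]] <- res
    if (!length(res$scenarios) || is.infinite(res$dMin) || res$dMin == 0L)
      next
    canon <- res$scenarios[[1L]]
    state <- referenceSeq(perm)
    counts <- c(PeI = 0L, PaI = 0L)
    for (k in seq_len(nrow(canon))) {
      vals <- state[(canon$start[k] + 1L):canon$end[k]]
      mk <- vals[vals != .TOKEN]
      cls <- canon$classification[k]
      counts[cls] <- counts[cls] + 1L
      events[[length(events) + 1L]] <-
        CREvent(cls, cid,
                label = paste(cls, .roman(counts[cls])),
                probes = perm@rankProbes[sort(mk) + 1L],
                refStart = min(perm@refSlots[mk + 1L]),
                refEnd = max(perm@refSlots[mk + 1L]) + 1L)
      state <- applyReversal(state, canon$start[k], canon$end[k])
    }
  }
  list(events = events, scenarios = scenarios)
}

#' Assemble an EventMatrix from per-material event calls
#'
#' @param calls Named list (by material id) of lists of [CREvent-class].
#' @param species Character vector of species codes, parallel to
#'   \code{names(calls)}.
#' @return An [EventMatrix-class] whose rows are the union of observed
#'   (chromosome, label, type) event keys.
#' @export
eventMatrixFromCalls <- function(calls, species) {
  mats <- names(calls)
  rows <- unique(do.call(rbind, lapply(calls, function(evs) {
    if (!length(evs)) return(NULL)
    data.frame(
      chrom = vapply(evs, function(e) e@chroms[1L], ""),
      label = vapply(evs, function(e) e@label, ""),
      type = vapply(evs, function(e) e@type, ""),
      stringsAsFactors = FALSE)
  })))
  if (is.null(rows))
    rows <- data.frame(chrom = character(), label = character(),
                       type = character(), stringsAsFactors = FALSE)
  rownames(rows) <- NULL
  pres <- matrix(FALSE, nrow(rows), length(mats))
  for (j in seq_along(mats)) {
    evs <- calls[[mats[j]]]
    keys <- vapply(evs, function(e)
      paste(e@chroms[1L], e@label), "")
    pres[, j] <- paste(rows$chrom, rows$label) %in% keys
  }
  new("EventMatrix", events = rows, materials = mats, species = species,
      presence = pres,
      annotation = matrix("", nrow(rows), length(mats)))
}
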