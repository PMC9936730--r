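## Candidate-gene filter for single-gene FISH probe development: keep genes
## that are single-copy in every subgenome, collinear across the reference
## genomes and long enough to give a clean hybridization signal, then space
## picks evenly (~100 Mb apart) along each chromosome.

#' Select probe candidate genes
#'
#' Filters a gene-candidate table to single-copy, collinear genes longer
#' than \code{minLengthBp}, then greedily picks genes left-to-right per
#' homoeologous group: the first eligible gene, then repeatedly the eligible
#' gene nearest to (last pick + \code{targetSpacingMb}), until the
#' chromosome end. Deterministic.
#'
#' @param genes data.frame with columns \code{gene_id}, \code{group},
#'   \code{position} (Mb on the reference pseudomolecule), \code{length}
#'   (bp), \code{copies} (maximum copy number over subgenomes) and
#'   \code{collinear} (logical).
#' @param minLengthBp Minimum gene length in bp (default 2000: genes above
#'   2 kb label efficiently).
#' @param targetSpacingMb Target spacing between picks in Mb (default 100).
#' @return Character vector of selected gene ids, in pick order.
#' @examples
#' g <- data.frame(gene_id = paste0("g", 1:6), group = 1L,
#'                 position = c(0, 40, 100, 160, 210, 300),
#'                 length = 2500L, copies = 1L, collinear = TRUE)
#' selectProbes(g)
#' @export
selectProbes <- function(genes, minLengthBp = 2000, targetSpacingMb = 100) {
  eligible <- genes[genes$copies == 1L & genes$collinear &
                      genes$length > minLengthBp, , drop = FALSE]
  if (!nrow(eligible)) {
    warning("no eligible candidate genes")
    return(character())
  }
  picks <- character()
  for (g in sort(unique(eligible$group))) {
    eg <- eligible[eligible$group == g, , drop = FALSE]
    eg <- eg[order(eg$position, eg$gene_id), , drop = FALSE]
    taken <- 1L
    picks <- c(picks, eg$gene_id[1L])
    last <- eg$position[1L]
    repeat {
      ahead <- which(eg$position > last & !seq_len(nrow(eg)) %in% taken)
      if (!length(ahead)) break
      want <- last + targetSpacingMb
      nxt <- ahead[which.min(abs(eg$position[ahead] - want))]
      taken <- c(taken, nxt)
      picks <- c(picks, eg$gene_id[nxt])
      last <- eg$position[nxt]
    }
  }
  picks
}

#' Simulate a gene-candidate table
#'
#' Random candidate genes over the seven homoeologous groups with
#' controllable rates of multi-copy and non-collinear genes, for exercising
#' [selectProbes()].
#'
#' @param nPerGroup Candidates per group.
#' @param chromLengthMb Chromosome length in Mb.
#' @param pMultiCopy,pNonCollinear Contamination rates.
#' @param seed Integer seed.
#' @return data.frame in the format [selectProbes()] consumes.
#' @export
simulateGeneCandidates <- function(nPerGroup = 50L, chromLengthMb = 500,
                                   pMultiCopy = 0.2, pNonCollinear = 0.1,
                                   seed = 1L) {
  set.seed(seed)
  do.call(rbind, lapply(1:7, function(g) {
    data.frame(
      gene_id = sprintf("g%d_%03d", g, seq_len(nPerGroup)),
      group = g,
      position = sort(round(stats::runif(nPerGroup, 0, chromLengthMb), 2)),
      length = sample(500:6000, nPerGroup, replace = TRUE),
      copies = 1L + stats::rbinom(nPerGroup, 2L, pMultiCopy / 2),
      collinear = stats::runif(nPerGroup) > pNonCollinear,
      stringsAsFactors = FALSE)
  }))
}
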