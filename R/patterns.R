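## Chromosome-variant accounting from repeat-FISH pattern letter grids.
## A primed letter is a distinct variant from its unprimed base: a and a'
## are two variants (the prime marks co-occurring polymorphic CRs).

.restrictPatterns <- function(x, species) {
  keep <- x@species == species
  if (!any(keep)) stop("no materials of species ", species)
  new("PatternMatrix", materials = x@materials[keep],
      species = x@species[keep], chromosomes = x@chromosomes,
      letters = x@letters[keep, , drop = FALSE],
      primed = x@primed[keep, , drop = FALSE])
}

.columnCounts <- function(letters, primed, primedOnly = FALSE) {
  vapply(seq_len(ncol(letters)), function(j) {
    lt <- letters[, j]
    pr <- primed[, j]
    ok <- !is.na(lt)
    if (primedOnly) ok <- ok & pr
    length(unique(paste0(lt[ok], ifelse(pr[ok], "'", ""))))
  }, 1L)
}

.genomeTotals <- function(counts, chromosomes) {
  sub <- parseChromId(chromosomes)$subgenome
  vapply(split(counts, sub), sum, 1L)
}

#' Count chromosome variants per chromosome, genome and in total
#'
#' The variant count of a chromosome column is the number of distinct
#' (letter, prime) codes among the species' materials; genome totals sum the
#' columns of each subgenome. Columns where the subgenome is absent count
#' zero.
#'
#' @param x A [PatternMatrix-class].
#' @param species Species code to restrict to.
#' @return List with \code{perChromosome} (named integer vector),
#'   \code{perGenome} (named by subgenome) and \code{total}.
#' @examples
#' # a 4H column reading a, a, b, a', c, a across six materials -> 4
#' @export
countVariants <- function(x, species) {
  m <- .restrictPatterns(x, species)
  counts <- .columnCounts(m@letters, m@primed)
  names(counts) <- m@chromosomes
  list(perChromosome = counts,
       perGenome = .genomeTotals(counts, m@chromosomes),
       total = sum(counts))
}

#' Count chromosome variants that carry the prime flag
#'
#' Distinct primed codes per chromosome column (variants verified as
#' carrying additional polymorphic rearrangements), with genome and grand
#' totals.
#'
#' @inheritParams countVariants
#' @return List with \code{perChromosome}, \code{perGenome} and
#'   \code{total}.
#' @export
countPrimedVariants <- function(x, species) {
  m <- .restrictPatterns(x, species)
  counts <- .columnCounts(m@letters, m@primed, primedOnly = TRUE)
  names(counts) <- m@chromosomes
  list(perChromosome = counts,
       perGenome = .genomeTotals(counts, m@chromosomes),
       total = sum(counts))
}
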