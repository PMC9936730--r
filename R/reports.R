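## Plain-text reporting: chromosomes rendered as ordered marker strings
## with "|" for the centromere — a text analogue of an idiogram.

#' Render a chromosome or permutation as a one-line text idiogram
#'
#' Markers appear in observed order with the centromere as \code{"|"};
#' foreign-group runs of a [Permutation-class] are shown in braces.
#'
#' @param x A [ChromosomeMap-class] or [Permutation-class].
#' @return A single character string.
#' @export
formatIdiogram <- function(x) {
  if (is(x, "ChromosomeMap")) {
    s <- x@sites
    items <- append(s$probe, "|", after = sum(s$position < x@centromere))
    return(paste(items, collapse = " "))
  }
  if (is(x, "Permutation")) {
    items <- append(x@rankProbes[x@sequence + 1L], "|",
                    after = x@centromereRank)
    fr <- x@foreignRuns
    if (nrow(fr))
      items <- c(items, paste0("{", fr$probes, "}"))
    return(paste(items, collapse = " "))
  }
  stop("formatIdiogram expects a ChromosomeMap or Permutation")
}

#' Write a specificity table
#'
#' @param calls Result of [classifySpecificity()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeSpecificityTable <- function(calls, path) {
  .writeTsv(calls, path)
}

#' Write a breakpoint-reuse table
#'
#' @param reuse Result of [breakpointReuse()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeReuseTable <- function(reuse, path) {
  .writeTsv(reuse, path)
}

#' Write a chromosome-variant summary
#'
#' Mirrors the printed summary rows of a pattern-variant table: one row of
#' per-chromosome variant counts, one of primed-variant counts, and genome
#' totals.
#'
#' @param x A [PatternMatrix-class].
#' @param species Species code.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeVariantSummary <- function(x, species, path) {
  v <- countVariants(x, species)
  p <- countPrimedVariants(x, species)
  df <- data.frame(chromosome = names(v$perChromosome),
                   variants = unname(v$perChromosome),
                   primed_variants = unname(p$perChromosome),
                   stringsAsFactors = FALSE)
  gen <- data.frame(chromosome = paste0("total_", names(v$perGenome)),
                    variants = unname(v$perGenome),
                    primed_variants = unname(p$perGenome[names(v$perGenome)]),
                    stringsAsFactors = FALSE)
  tot <- data.frame(chromosome = "total", variants = v$total,
                    primed_variants = p$total, stringsAsFactors = FALSE)
  .writeTsv(rbind(df, gen, tot), path,
            comments = paste("chromosome variant summary for", species))
}

#' Write per-chromosome scenario sets to a sidecar table
#'
#' @param scenarios The \code{scenarios} element of [inferEvents()] output.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeScenarioTable <- function(scenarios, path) {
  rows <- list()
  for (cid in names(scenarios)) {
    res <- scenarios[[cid]]
    if (!length(res$scenarios)) next
    for (r in seq_along(res$scenarios)) {
      sc <- res$scenarios[[r]]
      for (k in seq_len(nrow(sc))) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = cid, scenario = r, step = k,
          interval = paste0("[", sc$start[k], ",", sc$end[k], ")"),
          classification = sc$classification[k],
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), scenario = integer(), step = integer(),
               interval = character(), classification = character(),
               stringsAsFactors = FALSE)
  .writeTsv(df, path)
}
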