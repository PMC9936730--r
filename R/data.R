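#' Paths to packaged survey fixtures
#'
#' @param name File name under the package's \code{extdata}.
#' @return Absolute path to the file.
#' @export
crFixture <- function(name) {
  p <- system.file("extdata", name, package = "karyoCR", mustWork = TRUE)
  p
}

#' Packaged probe manifest (59 single-gene probes)
#'
#' @return Manifest data.frame; see [readProbeManifest()].
#' @export
crProbeManifest <- function() {
  readProbeManifest(crFixture("probe_manifest.tsv"))
}

#' Packaged reference collinearity orders (D-genome standard)
#'
#' @return Named list of [ReferenceOrder-class] by group.
#' @export
crReference <- function() {
  readReference(crFixture("reference_orders.tsv"))
}

#' Packaged rearrangement survey (events x 11 materials)
#'
#' @return An [EventMatrix-class].
#' @export
crEventSurvey <- function() {
  readEventMatrix(crFixture("elymus_cr_events.tsv"))
}

#' Packaged repeat-FISH pattern survey (10 materials x 21 chromosomes)
#'
#' @return A [PatternMatrix-class].
#' @export
crPatternSurvey <- function() {
  readPatternMatrix(crFixture("elymus_fish_patterns.tsv"))
}

#' Packaged group-4 breakpoint-reuse demonstration complexes
#'
#' @return data.frame consumed by [breakpointReuse()].
#' @export
crGroup4Demo <- function() {
  df <- .readTsv(crFixture("group4_reuse_demo.tsv"),
                 c("material", "species", "chrom", "label",
                   "ref_start", "ref_end"))
  df$ref_start <- as.integer(df$ref_start)
  df$ref_end <- as.integer(df$ref_end)
  attr(df, "lineNo") <- NULL
  df
}

#' Prose-derived demonstration karyotypes
#'
#' Builds a karyotype over the packaged reference carrying the major
#' rearrangements narrated for a material, with the simulator as the
#' construction engine. Exact supplementary marker orders were not
#' available, so these maps reproduce the narrated events, not
#' probe-by-probe layouts — they support demonstrations, not acceptance
#' checks.
#'
#' \code{"DY"}: an E. sibiricus karyotype with pericentric inversions on
#' 1H, 2H, 3H, 6H, 2St, 5St, a paracentric inversion on 4St, two successive
#' pericentric inversions on 4H and the reciprocal 4H/6H translocation of
#' distal short-arm segments. \code{"Hbog"}: the diploid H-genome outgroup
#' with a pericentric inversion on 1H, a pericentric plus paracentric
#' inversion on 2H, a one-way translocation of the distal 4H long arm onto
#' the 3H short arm, a pericentric inversion and distal long-arm deletion
#' on 4H, and two paracentric inversions on the 5H long arm.
#'
#' @param material \code{"DY"} or \code{"Hbog"}.
#' @return List with \code{karyotype} and ground-truth \code{truth} events
#'   (see [simulateKaryotype()]).
#' @export
demoKaryotype <- function(material = c("DY", "Hbog")) {
  material <- match.arg(material)
  ref <- crReference()
  ## token-inclusive coordinates; group sizes/cen slots: g1 9/4, g2 8/3,
  ## g3 8/3, g4 9/4, g5 9/3, g6 8/3, g7 8/3
  if (material == "DY") {
    events <- list(
      list(type = "PeI", chrom = "1H", start = 3L, end = 6L),
      list(type = "PeI", chrom = "2H", start = 2L, end = 5L),
      list(type = "PeI", chrom = "3H", start = 2L, end = 5L),
      list(type = "PeI", chrom = "6H", start = 2L, end = 5L),
      list(type = "PeI", chrom = "2St", start = 2L, end = 5L),
      list(type = "PeI", chrom = "5St", start = 2L, end = 5L),
      list(type = "PaI", chrom = "4St", start = 5L, end = 8L),
      list(type = "PeI", chrom = "4H", start = 3L, end = 6L),
      list(type = "PeI", chrom = "4H", start = 2L, end = 7L),
      list(type = "RT", chroms = c("4H", "6H"), len = c(1L, 1L)))
    simulateKaryotype(ref, "E_sibiricus", "DY", events)
  } else {
    events <- list(
      list(type = "PeI", chrom = "1H", start = 3L, end = 6L),
      list(type = "PeI", chrom = "2H", start = 2L, end = 5L),
      list(type = "PaI", chrom = "2H", start = 5L, end = 8L),
      list(type = "T", from = "4H", to = "3H", len = 1L,
           fromEnd = "tail"),
      list(type = "PeI", chrom = "4H", start = 3L, end = 6L),
      list(type = "De", chrom = "4H", probe = "4H527"),
      list(type = "PaI", chrom = "5H", start = 4L, end = 7L),
      list(type = "PaI", chrom = "5H", start = 7L, end = 10L))
    simulateKaryotype(ref, "H_bogdanii", "Hbog", events)
  }
}
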