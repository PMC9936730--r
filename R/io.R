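## All package files are UTF-8 tab-separated text; '#' lines are comments.
## Reading goes through .readTsv so that malformed rows can be reported with
## their original line numbers.

.readTsv <- function(path, requiredCols = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", raw)
  if (!any(keep)) stop("no records in ", path)
  lineNo <- which(keep)
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  header <- fields[[1]]
  body <- fields[-1]
  bodyLines <- lineNo[-1]
  if (!length(body)) stop("no records in ", path)
  bad <- vapply(body, length, 1L) != length(header)
  if (any(bad))
    stop("malformed row(s) in ", path, " at line(s) ",
         paste(bodyLines[bad], collapse = ", "),
         ": field count differs from header")
  df <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
  names(df) <- header
  missingCols <- setdiff(requiredCols, header)
  if (length(missingCols))
    stop("file ", path, " lacks column(s): ",
         paste(missingCols, collapse = ", "))
  attr(df, "lineNo") <- bodyLines
  df
}

.writeTsv <- function(df, path, comments = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    rows <- apply(df, 1L, function(r) paste(r, collapse = "\t"))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a probe manifest
#'
#' The manifest lists every single-gene probe with its homoeologous group,
#' home arm, rank within its group's reference order, and whether it
#' legitimately hybridizes at two sites per subgenome (multi-site probes).
#'
#' @param path Path to a tab-separated manifest with columns
#'   \code{probe_id}, \code{home_group}, \code{home_arm},
#'   \code{reference_index}, \code{multi_site} and optionally \code{origin}.
#' @return A data.frame with typed columns.
#' @export
readProbeManifest <- function(path) {
  df <- .readTsv(path, c("probe_id", "home_group", "home_arm",
                         "reference_index", "multi_site"))
  out <- data.frame(
    probe_id = df$probe_id,
    home_group = as.integer(df$home_group),
    home_arm = df$home_arm,
    reference_index = as.integer(df$reference_index),
    multi_site = toupper(df$multi_site) %in% c("TRUE", "T", "1", "YES"),
    stringsAsFactors = FALSE
  )
  if (!is.null(df$origin)) out$origin <- df$origin
  if (anyDuplicated(out$probe_id))
    stop("duplicate probe_id in manifest: ",
         paste(unique(out$probe_id[duplicated(out$probe_id)]), collapse = ", "))
  if (!all(out$home_arm %in% c("S", "L")))
    stop("home_arm must be S or L")
  if (!all(out$home_group %in% 1:7))
    stop("home_group must be in 1..7")
  single <- out[!out$multi_site, ]
  dupIdx <- duplicated(single[, c("home_group", "reference_index")])
  if (any(dupIdx))
    stop("reference_index duplicated within group for single-site probes")
  out
}

#' Read reference collinearity orders
#'
#' @param path Path to a tab-separated file with columns \code{group} and
#'   \code{item}; per group, rows list probe ids in reference order with one
#'   \code{CEN} token marking the centromere slot.
#' @return Named list of [ReferenceOrder-class], keyed by group.
#' @export
readReference <- function(path) {
  df <- .readTsv(path, c("group", "item"))
  out <- list()
  for (g in sort(unique(as.integer(df$group)))) {
    items <- df$item[as.integer(df$group) == g]
    cenAt <- which(items == "CEN")
    if (length(cenAt) != 1L)
      stop("group ", g, " must contain exactly one CEN token")
    probes <- items[items != "CEN"]
    out[[as.character(g)]] <- ReferenceOrder(g, probes, cenAt - 1L)
  }
  out
}

#' Write reference collinearity orders
#'
#' @param reference Named list of [ReferenceOrder-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeReference <- function(reference, path) {
  rows <- do.call(rbind, lapply(reference, function(r) {
    data.frame(group = r@group,
               item = append(r@probes, "CEN", after = r@centromereSlot),
               stringsAsFactors = FALSE)
  }))
  .writeTsv(rows, path)
}

#' Read karyotypes from a marker-map file
#'
#' @param path Path to a tab-separated file with columns \code{material},
#'   \code{species}, \code{chrom}, \code{centromere}, \code{probe},
#'   \code{position}, \code{copy}. Positions are fractions of chromosome
#'   length in \code{[0, 1]} from the short-arm telomere.
#' @return A named list of [Karyotype-class], one per material (a single
#'   [Karyotype-class] if the file holds one material).
#' @export
readKaryotype <- function(path) {
  df <- .readTsv(path, c("material", "species", "chrom", "centromere",
                         "probe", "position", "copy"))
  lineNo <- attr(df, "lineNo")
  pos <- suppressWarnings(as.numeric(df$position))
  bad <- is.na(pos) | pos < 0 | pos > 1
  if (any(bad))
    stop("position outside [0,1] (or unparseable) in ", path,
         " at line(s) ", paste(lineNo[bad], collapse = ", "))
  key <- paste(df$material, df$chrom, df$probe, df$copy)
  if (anyDuplicated(key))
    stop("duplicate (chrom, probe, copy) record(s) in ", path,
         " at line(s) ", paste(lineNo[duplicated(key)], collapse = ", "))
  out <- list()
  for (m in unique(df$material)) {
    dm <- df[df$material == m, , drop = FALSE]
    sp <- unique(dm$species)
    if (length(sp) != 1L)
      stop("material ", m, " carries conflicting species tags")
    chroms <- lapply(unique(dm$chrom), function(cid) {
      dc <- dm[dm$chrom == cid, , drop = FALSE]
      cen <- unique(as.numeric(dc$centromere))
      if (length(cen) != 1L)
        stop("chromosome ", cid, " of ", m,
             " carries conflicting centromere values")
      ChromosomeMap(cid, cen,
                    data.frame(probe = dc$probe,
                               position = as.numeric(dc$position),
                               copy = as.integer(dc$copy),
                               stringsAsFactors = FALSE))
    })
    out[[m]] <- Karyotype(m, sp, chroms)
  }
  if (length(out) == 1L) out[[1L]] else out
}

#' Write karyotypes to a marker-map file
#'
#' @param karyotypes A [Karyotype-class] or list of them.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeKaryotype <- function(karyotypes, path) {
  if (is(karyotypes, "Karyotype")) karyotypes <- list(karyotypes)
  rows <- do.call(rbind, lapply(karyotypes, function(k) {
    do.call(rbind, lapply(k@chromosomes, function(cm) {
      s <- cm@sites
      data.frame(material = k@materialId, species = k@species,
                 chrom = cm@chromId,
                 centromere = format(cm@centromere, digits = 10),
                 probe = s$probe,
                 position = format(s$position, digits = 10),
                 copy = s$copy, stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  .writeTsv(rows, path)
}

## Cell grammar of the event grid: "+", "-" or "0", with an optional prime
## annotation spelled as trailing ' or '' (ASCII) kept only for provenance.
.parseEventCell <- function(cell) {
  cell <- trimws(cell)
  base <- substr(cell, 1L, 1L)
  if (!base %in% c("+", "-", "0") || !grepl("^[+0-]'{0,2}$", cell))
    stop("bad event-grid cell: '", cell, "'")
  ann <- if (base == "0") "0" else substring(cell, 2L)
  list(present = base == "+", annotation = ann)
}

#' Read an events-by-materials presence matrix
#'
#' @param path Tab-separated file with columns \code{chrom}, \code{label},
#'   \code{type}, then one column per material. Material species tags are
#'   given on header comment lines of the form
#'   \code{#material <id> <species>}. Cells are \code{+} / \code{-} /
#'   \code{0} with optional trailing \code{'} or \code{''} annotations.
#' @return An [EventMatrix-class].
#' @export
readEventMatrix <- function(path) {
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  tagLines <- grep("^#material\\s", raw, value = TRUE)
  tags <- do.call(rbind, strsplit(sub("^#material\\s+", "", tagLines),
                                  "\\s+"))
  df <- .readTsv(path, c("chrom", "label", "type"))
  matCols <- setdiff(names(df), c("chrom", "label", "type"))
  if (!length(matCols)) stop("event matrix has no material columns")
  if (is.null(tags) || !all(matCols %in% tags[, 1L]))
    stop("species tag missing for material(s): ",
         paste(setdiff(matCols, tags[, 1L]), collapse = ", "))
  species <- tags[match(matCols, tags[, 1L]), 2L]
  parseChromId(df$chrom)  # validates chromosome ids
  pres <- matrix(FALSE, nrow(df), length(matCols))
  ann <- matrix("", nrow(df), length(matCols))
  for (j in seq_along(matCols)) {
    cells <- lapply(df[[matCols[j]]], .parseEventCell)
    pres[, j] <- vapply(cells, `[[`, TRUE, "present")
    ann[, j] <- vapply(cells, `[[`, "", "annotation")
  }
  new("EventMatrix",
      events = data.frame(chrom = df$chrom, label = df$label,
                          type = df$type, stringsAsFactors = FALSE),
      materials = matCols, species = species,
      presence = pres, annotation = ann)
}

#' Write an events-by-materials presence matrix
#'
#' @param x An [EventMatrix-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeEventMatrix <- function(x, path) {
  grid <- matrix("-", nrow(x@events), length(x@materials))
  grid[x@presence] <- "+"
  grid[x@annotation == "0"] <- "0"
  prime <- x@annotation %in% c("'", "''")
  grid[prime] <- paste0(grid[prime], x@annotation[prime])
  df <- cbind(x@events, as.data.frame(grid, stringsAsFactors = FALSE))
  names(df) <- c("chrom", "label", "type", x@materials)
  con <- file(path, open = "wt", encoding = "UTF-8")
  writeLines(paste("#material", x@materials, x@species), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(apply(df, 1L, paste, collapse = "\t"), con)
  close(con)
  invisible(path)
}

#' Write a list of rearrangement events
#'
#' @param events List of [CREvent-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeEvents <- function(events, path) {
  df <- eventsAsFrame(events)
  .writeTsv(df, path)
}

#' Read a list of rearrangement events written by [writeEvents()]
#'
#' @param path Input path.
#' @return List of [CREvent-class].
#' @export
readEvents <- function(path) {
  df <- .readTsv(path, c("type", "chroms", "label", "probes",
                         "ref_start", "ref_end"))
  lapply(seq_len(nrow(df)), function(i) {
    CREvent(df$type[i],
            strsplit(df$chroms[i], "/", fixed = TRUE)[[1]],
            label = df$label[i],
            probes = if (nzchar(df$probes[i]))
              strsplit(df$probes[i], ",", fixed = TRUE)[[1]] else character(),
            refStart = suppressWarnings(as.integer(df$ref_start[i])),
            refEnd = suppressWarnings(as.integer(df$ref_end[i])))
  })
}

#' Flatten a list of CREvents to a data.frame
#'
#' @param events List of [CREvent-class].
#' @return data.frame with one row per event.
#' @export
eventsAsFrame <- function(events) {
  if (!length(events))
    return(data.frame(type = character(), chroms = character(),
                      label = character(), probes = character(),
                      ref_start = character(), ref_end = character(),
                      stringsAsFactors = FALSE))
  data.frame(
    type = vapply(events, function(e) e@type, ""),
    chroms = vapply(events, function(e) paste(e@chroms, collapse = "/"), ""),
    label = vapply(events, function(e) e@label, ""),
    probes = vapply(events, function(e) paste(e@probes, collapse = ","), ""),
    ref_start = vapply(events, function(e) as.character(e@refStart), ""),
    ref_end = vapply(events, function(e) as.character(e@refEnd), ""),
    stringsAsFactors = FALSE
  )
}

## Pattern cells: one letter a-z, optional trailing ' (prime); "-" where the
## subgenome does not exist in the species.
.parsePatternCell <- function(cell) {
  cell <- trimws(cell)
  if (cell == "-") return(list(letter = NA_character_, primed = NA))
  primed <- grepl("'$", cell)
  letter <- sub("'+$", "", cell)
  if (!letter %in% letters)
    stop("bad pattern cell: '", cell, "'")
  list(letter = letter, primed = primed)
}

#' Read a repeat-FISH pattern matrix
#'
#' @param path Tab-separated file with columns \code{material},
#'   \code{species}, then one column per chromosome; cells are letter codes
#'   with an optional trailing \code{'} (prime) flag, or \code{-} where the
#'   subgenome is absent.
#' @return A [PatternMatrix-class].
#' @export
readPatternMatrix <- function(path) {
  df <- .readTsv(path, c("material", "species"))
  chromCols <- setdiff(names(df), c("material", "species"))
  if (!length(chromCols)) stop("pattern matrix has no chromosome columns")
  parseChromId(chromCols)
  lt <- matrix(NA_character_, nrow(df), length(chromCols))
  pr <- matrix(NA, nrow(df), length(chromCols))
  for (j in seq_along(chromCols)) {
    cells <- lapply(df[[chromCols[j]]], .parsePatternCell)
    lt[, j] <- vapply(cells, `[[`, "", "letter")
    pr[, j] <- vapply(cells, function(x) as.logical(x$primed), TRUE)
  }
  new("PatternMatrix", materials = df$material, species = df$species,
      chromosomes = chromCols, letters = lt, primed = pr)
}

#' Write a repeat-FISH pattern matrix
#'
#' @param x A [PatternMatrix-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writePatternMatrix <- function(x, path) {
  grid <- ifelse(is.na(x@letters), "-",
                 paste0(x@letters, ifelse(!is.na(x@primed) & x@primed,
                                          "'", "")))
  grid <- matrix(grid, nrow(x@letters), ncol(x@letters))
  df <- data.frame(material = x@materials, species = x@species,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(grid, stringsAsFactors = FALSE))
  names(df) <- c("material", "species", x@chromosomes)
  .writeTsv(df, path)
}
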