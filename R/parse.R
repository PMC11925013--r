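#' Parse a segmental-duplication annotation table
#'
#' Reads a tab-delimited table of pairwise alignments in the UCSC
#' genomicSuperDups dialect: each row gives two genomic intervals (the two
#' copies of a duplication, 0-based half-open coordinates) and the fraction
#' of matching bases between them.  Column positions are configurable so
#' that both the full UCSC table and reduced exports parse.
#'
#' Alignments shorter than `minLength` or below `minIdentity` are outside
#' the segmental-duplication definition (>= 1 kbp, > 90% identity) and are
#' dropped with a message when present.
#'
#' @param path path to the tab-delimited table.
#' @param dropSex drop rows where either interval lies on a sex chromosome
#'   (chrX/chrY/X/Y).  Default `TRUE`: the analysis is restricted to
#'   autosomes.
#' @param columns named integer vector giving the 1-based column indices of
#'   `chromA`, `startA`, `endA`, `chromB`, `startB`, `endB`, `identity`.
#'   The default matches the UCSC genomicSuperDups schema (with its leading
#'   `bin` column).
#' @param header does the file carry a header line?
#' @param minLength,minIdentity alignment filters; set to 0 to disable.
#' @return a `data.frame` of alignment records: `id` (assigned in input
#'   order), `chromA`, `startA`, `endA`, `chromB`, `startB`, `endB`,
#'   `identity`.  Coordinates are kept 0-based half-open, as in the input.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("chr1\t100\t2000\tchr2\t500\t2400\t0.95",
#'              "chr1\t1500\t3000\tchr3\t0\t1500\t0.97"), tf)
#' sd <- parseSdAnnotation(tf, columns = c(chromA = 1, startA = 2, endA = 3,
#'   chromB = 4, startB = 5, endB = 6, identity = 7))
#' nrow(sd)
#' @export
parseSdAnnotation <- function(path, dropSex = TRUE,
                              columns = c(chromA = 2, startA = 3, endA = 4,
                                          chromB = 8, startB = 9, endB = 10,
                                          identity = 27),
                              header = FALSE,
                              minLength = 1000, minIdentity = 0.9) {
  need <- c("chromA", "startA", "endA", "chromB", "startB", "endB", "identity")
  if (!all(need %in% names(columns)))
    stop("`columns` must name indices for: ", paste(need, collapse = ", "))
  raw <- utils::read.delim(path, header = header, stringsAsFactors = FALSE,
                           comment.char = "#", quote = "")
  if (max(columns) > ncol(raw))
    stop("table at ", path, " has ", ncol(raw),
         " columns but the column map needs ", max(columns))
  rec <- data.frame(
    id = paste0("A", seq_len(nrow(raw))),
    chromA = as.character(raw[[columns[["chromA"]]]]),
    startA = suppressWarnings(as.numeric(raw[[columns[["startA"]]]])),
    endA = suppressWarnings(as.numeric(raw[[columns[["endA"]]]])),
    chromB = as.character(raw[[columns[["chromB"]]]]),
    startB = suppressWarnings(as.numeric(raw[[columns[["startB"]]]])),
    endB = suppressWarnings(as.numeric(raw[[columns[["endB"]]]])),
    identity = suppressWarnings(as.numeric(raw[[columns[["identity"]]]])),
    stringsAsFactors = FALSE
  )
  bad <- which(!stats::complete.cases(rec))
  if (length(bad))
    stop("unparseable row(s) at line ", paste(bad[seq_len(min(5, length(bad)))],
         collapse = ", "), " of ", path)
  inv <- which(rec$endA <= rec$startA | rec$endB <= rec$startB |
               rec$startA < 0 | rec$startB < 0)
  if (length(inv))
    stop("negative or inverted interval at line ",
         paste(inv[seq_len(min(5, length(inv)))], collapse = ", "))
  if (any(rec$identity < 0 | rec$identity > 1))
    stop("identity outside [0, 1]")
  if (dropSex) {
    sex <- c("chrX", "chrY", "X", "Y")
    rec <- rec[!(rec$chromA %in% sex | rec$chromB %in% sex), , drop = FALSE]
  }
  if (minLength > 0 || minIdentity > 0) {
    keep <- (rec$endA - rec$startA) >= minLength &
            (rec$endB - rec$startB) >= minLength &
            rec$identity >= minIdentity
    if (any(!keep))
      message(sum(!keep), " alignment(s) below the length/identity ",
              "thresholds dropped")
    rec <- rec[keep, , drop = FALSE]
  }
  rownames(rec) <- NULL
  rec
}

#' Read BED-like interval and value tracks
#'
#' `readBed()` reads a BED3+ file into a `GRanges` (0-based half-open input
#' converted to the 1-based closed convention GRanges uses).  `readTrack()`
#' reads a bedGraph-style 4-column file (chrom, start, end, value) into a
#' `GRanges` with a `score` column.  `readChromSizes()` reads a two-column
#' chrom/size table into a named vector.
#'
#' @param path file path.
#' @return `readBed`/`readTrack`: a `GRanges`; `readChromSizes`: a named
#'   numeric vector.
#' @export
readBed <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(raw) < 3) stop("BED file needs at least 3 columns: ", path)
  GRanges(raw[[1]], IRanges(raw[[2]] + 1L, raw[[3]]))
}

#' @rdname readBed
#' @export
readTrack <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(raw) < 4) stop("value track needs 4 columns: ", path)
  gr <- GRanges(raw[[1]], IRanges(raw[[2]] + 1L, raw[[3]]))
  mcols(gr)$score <- as.numeric(raw[[4]])
  gr
}

#' @rdname readBed
#' @export
readChromSizes <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(raw[[2]]), as.character(raw[[1]]))
}

# internal: alignment record table -> GRanges of the 2n intervals
# (1-based closed), with record row index and side in mcols
.alignmentIntervals <- function(records) {
  gr <- GRanges(
    c(records$chromA, records$chromB),
    IRanges(c(records$startA, records$startB) + 1,
            c(records$endA, records$endB))
  )
  mcols(gr)$rec <- rep(seq_len(nrow(records)), 2L)
  mcols(gr)$side <- rep(c("A", "B"), each = nrow(records))
  gr
}
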