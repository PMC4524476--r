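#' Parse a RepeatMasker .out annotation table
#'
#' Reads the standard RepeatMasker output layout: three header lines
#' followed by whitespace-delimited annotation records.  Coordinates are
#' taken from the query-sequence columns (1-based, inclusive).  For simple
#' repeats the motif is extracted from the repeat name, e.g.
#' \code{"(CA)n"} gives motif \code{"CA"}.
#'
#' @param path Path to a RepeatMasker \code{.out} file.
#' @return data.frame with columns \code{scaffold_id}, \code{start},
#'   \code{end}, \code{repeat_name}, \code{repeat_class}, \code{motif}
#'   (NA unless extractable from the repeat name).
#' @export
parse_repeatmasker <- function(path) {
  lines <- readLines(path)
  if (length(lines) > 3L) body <- lines[-(1:3)] else body <- character(0)
  body <- body[nzchar(trimws(body))]
  empty <- data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), repeat_name = character(),
                      repeat_class = character(), motif = character(),
                      stringsAsFactors = FALSE)
  if (length(body) == 0L) return(empty)
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    stop("RepeatMasker parse error at line ", which(nf < 11L)[1L] + 3L,
         ": fewer than 11 fields")
  }
  pick <- function(k) vapply(fields, `[[`, "", k)
  start <- suppressWarnings(as.integer(pick(6L)))
  end <- suppressWarnings(as.integer(pick(7L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("RepeatMasker parse error at line ", bad[1L] + 3L,
         ": non-integer query coordinates")
  }
  rev_bad <- which(end < start)
  if (length(rev_bad)) {
    stop("RepeatMasker parse error at line ", rev_bad[1L] + 3L,
         ": end < start")
  }
  name <- pick(10L)
  motif <- ifelse(grepl("^\\(([ACGTacgt]+)\\)n$", name),
                  toupper(sub("^\\(([ACGTacgt]+)\\)n$", "\\1", name)),
                  NA_character_)
  data.frame(scaffold_id = pick(5L), start = start, end = end,
             repeat_name = name, repeat_class = pick(11L), motif = motif,
             stringsAsFactors = FALSE)
}

#' Fraction of a scaffold covered by annotated repeat intervals
#'
#' Computes, per repeat class and overall, the number of bases covered by
#' the union of annotation intervals (overlaps counted once) and the
#' corresponding fraction of the scaffold length.  A base annotated under
#' two classes counts once overall and once within each class.
#'
#' @param records Annotation data.frame (see [parse_repeatmasker()]) for
#'   one scaffold.
#' @param length_bp Scaffold length; all records must lie within it.
#' @param classes Optional character vector restricting the summary to
#'   these repeat classes.
#' @return data.frame with one row per class plus an \code{"overall"} row:
#'   \code{scaffold_id}, \code{repeat_class}, \code{covered_bp},
#'   \code{fraction}.
#' @export
coverage_fraction <- function(records, length_bp, classes = NULL) {
  if (!is.null(classes)) {
    records <- records[records$repeat_class %in% classes, , drop = FALSE]
  }
  scaffold <- if (nrow(records)) records$scaffold_id[1L] else NA_character_
  if (nrow(records)) {
    if (min(records$start) < 1L || max(records$end) > length_bp) {
      stop("consistency error: annotation interval outside [1, ",
           length_bp, "]")
    }
    if (length(unique(records$scaffold_id)) > 1L) {
      stop("coverage_fraction expects records for a single scaffold")
    }
  }
  union_bp <- function(df) {
    if (nrow(df) == 0L) return(0L)
    r <- IRanges::reduce(IRanges::IRanges(df$start, df$end))
    sum(IRanges::width(r))
  }
  cls <- sort(unique(records$repeat_class))
  per_class <- vapply(cls, function(cl)
    union_bp(records[records$repeat_class == cl, , drop = FALSE]),
    integer(1))
  overall <- union_bp(records)
  data.frame(scaffold_id = scaffold,
             repeat_class = c(cls, "overall"),
             covered_bp = c(per_class, overall),
             fraction = c(per_class, overall) / length_bp,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter simple-repeat annotations to microsatellites with enough units
#'
#' Keeps records whose span contains at least \code{min_units} whole copies
#' of the motif: \code{floor((end - start + 1) / nchar(motif)) >=
#' min_units}.  Partial copies do not count.
#'
#' @param records Annotation data.frame with a non-NA \code{motif} column
#'   for the records to consider.
#' @param min_units Minimum number of whole repeat units (default 15).
#' @return The filtered data.frame with an added \code{units} column.
#' @export
microsatellite_filter <- function(records, min_units = 15L) {
  if (nrow(records) == 0L) {
    records$units <- integer(0)
    return(records)
  }
  if (any(is.na(records$motif) | !nzchar(records$motif))) {
    stop("microsatellite_filter: empty motif")
  }
  units <- (records$end - records$start + 1L) %/% nchar(records$motif)
  out <- records[units >= min_units, , drop = FALSE]
  out$units <- units[units >= min_units]
  rownames(out) <- NULL
  out
}
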