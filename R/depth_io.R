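#' Read a per-position depth table
#'
#' Parses the three-column, headerless TSV dialect emitted by
#' \command{samtools depth}: scaffold identifier, 1-based position, read
#' depth.  Positions absent from the file are interpreted downstream as
#' depth 0, so the table only needs to list covered positions.
#'
#' @param path Path to a tab-separated text file (scaffold, position, depth).
#' @return A data.frame with columns \code{scaffold}, \code{pos},
#'   \code{depth}, in file order.
#' @details Lines may be grouped by scaffold in any scaffold order, but
#'   positions within one scaffold must be strictly increasing; a violation
#'   aborts with the offending line number, as does any non-integer position
#'   or depth.
#' @export
read_depth_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(scaffold = character(), pos = integer(),
                      depth = integer(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    stop("depth table parse error at line ", which(nf < 3L)[1L],
         ": fewer than 3 tab-separated fields")
  }
  scaffold <- vapply(parts, `[[`, "", 1L)
  pos_chr <- vapply(parts, `[[`, "", 2L)
  dep_chr <- vapply(parts, `[[`, "", 3L)
  pos <- suppressWarnings(as.integer(pos_chr))
  depth <- suppressWarnings(as.integer(dep_chr))
  bad <- which(is.na(pos) | pos_chr != as.character(pos) |
                 is.na(depth) | dep_chr != as.character(depth))
  if (length(bad)) {
    stop("depth table parse error at line ", bad[1L],
         ": non-integer position or depth")
  }
  if (any(pos < 1L)) {
    stop("depth table parse error at line ", which(pos < 1L)[1L],
         ": position must be >= 1")
  }
  if (any(depth < 0L)) {
    stop("depth table parse error at line ", which(depth < 0L)[1L],
         ": negative depth")
  }
  d <- diff(pos)
  same <- scaffold[-1L] == scaffold[-length(scaffold)]
  viol <- which(same & d <= 0L)
  if (length(viol)) {
    stop("depth table ordering error at line ", viol[1L] + 1L,
         ": positions within a scaffold must be strictly increasing")
  }
  data.frame(scaffold = scaffold, pos = pos, depth = depth,
             stringsAsFactors = FALSE)
}

#' Write a per-position depth table
#'
#' Inverse of [read_depth_table()]: emits the 3-column headerless TSV.
#'
#' @param depths data.frame with columns \code{scaffold}, \code{pos},
#'   \code{depth}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_depth_table <- function(depths, path) {
  utils::write.table(depths[, c("scaffold", "pos", "depth")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Scan a reference FASTA for scaffold lengths and ambiguous positions
#'
#' Reads an assembly FASTA and records, per scaffold, its length and the
#' 1-based positions whose base is not A, C, G or T (case-insensitive) —
#' i.e. N and any other IUPAC ambiguity code.  These positions are excluded
#' from average-depth computation.
#'
#' @param fasta Path to a FASTA file.
#' @param ambiguous One of \code{"non-ACGT"} (default: any character outside
#'   A/C/G/T counts as ambiguous) or \code{"N-only"} (only N/n).
#' @return A data.frame of class \code{scaffold_info} with columns
#'   \code{scaffold_id}, \code{length_bp} and a list-column
#'   \code{ambiguous} of integer position vectors.
#' @export
scan_reference <- function(fasta, ambiguous = c("non-ACGT", "N-only")) {
  ambiguous <- match.arg(ambiguous)
  seqs <- Biostrings::readBStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("reference format error: duplicate scaffold id '",
         ids[duplicated(ids)][1L], "'")
  }
  lens <- Biostrings::width(seqs)
  if (any(lens == 0L)) {
    stop("reference format error: empty sequence for scaffold '",
         ids[lens == 0L][1L], "'")
  }
  pattern <- if (ambiguous == "non-ACGT") "[^ACGTacgt]" else "[Nn]"
  # gregexpr returns -1 when there is no match; normalize to integer(0)
  amb <- lapply(seq_along(seqs), function(i) {
    m <- gregexpr(pattern, as.character(seqs[[i]]))[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m)
  })
  info <- data.frame(scaffold_id = ids, length_bp = lens,
                     stringsAsFactors = FALSE)
  info$ambiguous <- amb
  class(info) <- c("scaffold_info", class(info))
  info
}

#' Build scaffold info directly from lengths and ambiguous positions
#'
#' Constructor used by the simulator and by callers that already know
#' scaffold lengths without a FASTA on disk.
#'
#' @param scaffold_id Character vector of scaffold identifiers.
#' @param length_bp Integer vector of scaffold lengths (bp).
#' @param ambiguous List of integer vectors of 1-based ambiguous positions
#'   (default: none).
#' @return A \code{scaffold_info} data.frame as from [scan_reference()].
#' @export
scaffold_info <- function(scaffold_id, length_bp,
                          ambiguous = vector("list", length(scaffold_id))) {
  stopifnot(length(scaffold_id) == length(length_bp),
            length(ambiguous) == length(scaffold_id))
  length_bp <- as.integer(length_bp)
  if (any(length_bp < 1L)) stop("scaffold lengths must be positive")
  ambiguous <- lapply(ambiguous, function(p) {
    p <- as.integer(p)
    if (length(p) && (min(p) < 1L)) stop("ambiguous position < 1")
    sort(unique(p))
  })
  for (i in seq_along(scaffold_id)) {
    if (length(ambiguous[[i]]) && max(ambiguous[[i]]) > length_bp[i]) {
      stop("ambiguous position beyond scaffold length for '",
           scaffold_id[i], "'")
    }
  }
  info <- data.frame(scaffold_id = as.character(scaffold_id),
                     length_bp = length_bp, stringsAsFactors = FALSE)
  info$ambiguous <- ambiguous
  class(info) <- c("scaffold_info", class(info))
  info
}

#' Read totals of mapped reads per individual
#'
#' The normalization factor needs the total number of mapped reads
#' (mapping quality >= 20) in each individual's alignment.  These counts are
#' computed upstream (e.g. \command{samtools view -c -q 20}) and supplied
#' either directly or as a 2-line \code{key=value} file with keys
#' \code{female} and \code{male}.
#'
#' @param female,male Positive integer read counts.
#' @return A list with elements \code{female} and \code{male}.
#' @export
read_totals <- function(female, male) {
  female <- as.numeric(female)
  male <- as.numeric(male)
  if (is.na(female) || is.na(male) || female <= 0 || male <= 0) {
    stop("read totals must be positive")
  }
  list(female = female, male = male)
}

#' @rdname read_totals
#' @param path Path to a key=value file with lines \code{female=<int>} and
#'   \code{male=<int>}.
#' @export
read_totals_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, function(x) {
    if (length(x) < 2L) NA_character_ else x[[2L]]
  }, ""))))
  names(vals) <- keys
  if (!all(c("female", "male") %in% keys)) {
    stop("totals file must define 'female' and 'male'")
  }
  read_totals(vals[["female"]], vals[["male"]])
}
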