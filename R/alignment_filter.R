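#' Read an aligned FASTA into an alignment object
#'
#' @param path Path to an aligned (equal-width) FASTA file.
#' @return A list of class \code{msa_alignment}: \code{sequence_ids}
#'   (character), \code{rows} (character vector of equal-length strings),
#'   \code{length} (columns).
#' @export
read_alignment <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  new_alignment(sub("\\s.*$", "", names(seqs)),
                toupper(as.character(seqs)))
}

#' Construct an alignment from id and row vectors
#'
#' @param sequence_ids Character vector of row identifiers (>= 2 rows).
#' @param rows Character vector of equal-length aligned strings over
#'   A/C/G/T, IUPAC ambiguity codes and '-'.
#' @return An \code{msa_alignment} object.
#' @export
new_alignment <- function(sequence_ids, rows) {
  rows <- unname(toupper(rows))
  if (length(rows) < 2L) stop("alignment needs >= 2 rows")
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("alignment rows must have equal length")
  structure(list(sequence_ids = as.character(sequence_ids), rows = rows,
                 length = w),
            class = "msa_alignment")
}

#' Write an alignment as aligned FASTA
#'
#' @param aln An \code{msa_alignment} object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_alignment <- function(aln, path) {
  x <- Biostrings::BStringSet(aln$rows)
  names(x) <- aln$sequence_ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$rows, ""))
}

matrix_to_aln <- function(aln, mat) {
  rows <- if (ncol(mat) == 0L) rep("", nrow(mat)) else
    apply(mat, 1L, paste, collapse = "")
  new_alignment_allow_empty(aln$sequence_ids, rows)
}

# zero-column alignments are legal filter output (emitted with a warning)
new_alignment_allow_empty <- function(sequence_ids, rows) {
  structure(list(sequence_ids = as.character(sequence_ids),
                 rows = unname(rows), length = nchar(rows[1L])),
            class = "msa_alignment")
}

#' Remove alignment columns containing gaps or ambiguous sites
#'
#' A column is removed when any row holds '-' or a character outside
#' A/C/G/T in it.
#'
#' @param aln An \code{msa_alignment} object.
#' @return A list: \code{alignment} (filtered), \code{removed} (number of
#'   columns dropped).
#' @export
drop_ambiguous_gap_columns <- function(aln) {
  mat <- aln_matrix(aln)
  bad <- apply(mat, 2L, function(col) any(!col %in% c("A", "C", "G", "T")))
  list(alignment = matrix_to_aln(aln, mat[, !bad, drop = FALSE]),
       removed = sum(bad))
}

# per-column singleton analysis: the index of the single row that differs
# from the unanimous state of all other rows, or NA.  With only two rows
# the minority row is not attributable and no column is a singleton column.
singleton_focal_rows <- function(mat) {
  n <- nrow(mat)
  apply(mat, 2L, function(col) {
    tab <- table(col)
    if (length(tab) != 2L) return(NA_integer_)
    minority <- names(tab)[tab == 1L]
    if (length(minority) != 1L || n - 1L < 2L) return(NA_integer_)
    which(col == minority)
  })
}

#' Remove runs of adjacent singleton columns attributable to one row
#'
#' A singleton column is one in which exactly one row differs from the
#' unanimous state of all other rows.  Every maximal run of at least
#' \code{min_run} consecutive singleton columns whose differing row is the
#' same is removed: multiple adjacent private differences in a single
#' individual are treated as alignment artefacts rather than substitutions.
#' Isolated singleton columns, and adjacent singleton columns belonging to
#' different rows, are kept.
#'
#' @param aln A gap- and ambiguity-free \code{msa_alignment}.
#' @param min_run Minimum run length to remove (default 2; must be >= 2).
#' @return A list: \code{alignment}, \code{removed}.
#' @export
drop_singleton_runs <- function(aln, min_run = 2L) {
  if (min_run < 2L) stop("min_run must be >= 2")
  mat <- aln_matrix(aln)
  if (ncol(mat) == 0L) return(list(alignment = aln, removed = 0L))
  focal <- singleton_focal_rows(mat)
  key <- ifelse(is.na(focal), 0L, focal)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  drop <- logical(ncol(mat))
  for (k in seq_along(r$values)) {
    if (r$values[k] != 0L && r$lengths[k] >= min_run) {
      drop[starts[k]:ends[k]] <- TRUE
    }
  }
  list(alignment = matrix_to_aln(aln, mat[, !drop, drop = FALSE]),
       removed = sum(drop))
}

#' Strict column filtering of an alignment before phylogenetic analysis
#'
#' Applies [drop_ambiguous_gap_columns()] followed by
#' [drop_singleton_runs()], the latter repeated until no removable run
#' remains: deleting a run can make singleton columns of another row newly
#' adjacent, and those artefact candidates are filtered with the same
#' rule.  This makes the whole filter idempotent.  A zero-column result is
#' returned with a warning, not an error.
#'
#' @param aln An \code{msa_alignment} object.
#' @param min_run Minimum singleton-run length to remove (default 2).
#' @return A list: \code{alignment} and \code{stats} — a one-row data.frame
#'   with \code{input_columns}, \code{removed_ambiguous_or_gap},
#'   \code{removed_singleton_runs}, \code{output_columns},
#'   \code{removed_fraction}.
#' @export
filter_alignment <- function(aln, min_run = 2L) {
  s1 <- drop_ambiguous_gap_columns(aln)
  cur <- s1$alignment
  removed_runs <- 0L
  repeat {
    s2 <- drop_singleton_runs(cur, min_run)
    removed_runs <- removed_runs + s2$removed
    cur <- s2$alignment
    if (s2$removed == 0L) break
  }
  out <- cur
  stats <- data.frame(input_columns = aln$length,
                      removed_ambiguous_or_gap = s1$removed,
                      removed_singleton_runs = removed_runs,
                      output_columns = out$length,
                      removed_fraction =
                        if (aln$length > 0) 1 - out$length / aln$length else 0)
  if (out$length == 0L) {
    warning("filter_alignment: all columns removed")
  }
  list(alignment = out, stats = stats)
}
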