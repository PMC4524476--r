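#' Read a tabular similarity-hit file (BLAST outfmt 6 dialect)
#'
#' Twelve tab-separated columns, no header: qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns \code{query_id}, \code{scaffold_id},
#'   \code{percent_identity}, \code{alignment_length}, \code{mismatch},
#'   \code{gapopen}, \code{query_start}, \code{query_end},
#'   \code{subject_start}, \code{subject_end}, \code{e_value},
#'   \code{bit_score}.
#' @export
read_hit_table <- function(path) {
  cols <- c("query_id", "scaffold_id", "percent_identity",
            "alignment_length", "mismatch", "gapopen", "query_start",
            "query_end", "subject_start", "subject_end", "e_value",
            "bit_score")
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character())
  if (length(first) == 0L || !nzchar(first)) {
    out <- data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(out) <- cols
    out$query_id <- character(); out$scaffold_id <- character()
    return(out)
  }
  hits <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE,
                            colClasses = c("character", "character",
                                           rep("numeric", 10)))
  if (ncol(hits) < 12L) stop("hit table must have 12 tab-separated columns")
  names(hits)[1:12] <- cols
  hits[, cols]
}

#' Select candidate scaffolds for one query from its similarity hits
#'
#' Applies the three-rule candidate filter to the hits of one exon/gene
#' query: (1) the best hit is the one with the lowest E value (ties broken
#' by higher bit score, then lexicographically smaller scaffold id);
#' (2) another scaffold is retained only if its percent identity is at
#' least 95\% of the best hit's identity (or, with
#' \code{similarity_mode = "absolute"}, at least an absolute 95\%); and
#' (3) its alignment length differs from the best hit's by at most 5\%.
#' Only the best-E-value hit per scaffold enters the comparison.
#'
#' @param hits data.frame of hits sharing one \code{query_id}
#'   (see [read_hit_table()]); must be non-empty.
#' @param similarity_mode \code{"relative"} (default) or \code{"absolute"}.
#' @param identity_frac Identity retention factor (default 0.95).
#' @param length_tol Maximum relative alignment-length difference
#'   (default 0.05).
#' @return A list of class \code{candidate_set}: \code{query_id},
#'   \code{best_hit} (one-row data.frame), \code{retained} (data.frame,
#'   includes the best hit), \code{confirmed} (NULL until
#'   [confirm_candidates()] is run).
#' @export
select_candidates <- function(hits, similarity_mode = c("relative", "absolute"),
                              identity_frac = 0.95, length_tol = 0.05) {
  similarity_mode <- match.arg(similarity_mode)
  if (is.null(hits) || nrow(hits) == 0L) {
    stop("select_candidates: empty hit list")
  }
  if (length(unique(hits$query_id)) != 1L) {
    stop("select_candidates: hits must share one query_id")
  }
  # deterministic canonical order: e_value asc, bit_score desc, scaffold asc
  ord <- order(hits$e_value, -hits$bit_score, hits$scaffold_id)
  hits <- hits[ord, , drop = FALSE]
  # at most one hit per scaffold: its best (first in canonical order)
  hits <- hits[!duplicated(hits$scaffold_id), , drop = FALSE]
  best <- hits[1L, , drop = FALSE]
  id_floor <- if (similarity_mode == "relative") {
    identity_frac * best$percent_identity
  } else {
    100 * identity_frac
  }
  len_ok <- abs(hits$alignment_length - best$alignment_length) /
    best$alignment_length <= length_tol
  keep <- (hits$percent_identity >= id_floor & len_ok)
  keep[1L] <- TRUE # best hit always retained
  retained <- hits[keep, , drop = FALSE]
  rownames(retained) <- NULL
  structure(list(query_id = best$query_id, best_hit = best,
                 retained = retained, confirmed = NULL),
            class = "candidate_set")
}

#' Global pairwise alignment with fixed scoring
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1, gap -2
#' (linear gap cost).  Traceback ties are broken deterministically:
#' diagonal first, then up (gap in the second sequence), then left (gap in
#' the first).
#'
#' @param seq_a,seq_b Non-empty nucleotide strings over A/C/G/T/N
#'   (case-insensitive).
#' @return A list: \code{score}, \code{aligned_a}, \code{aligned_b}.
#' @export
global_align <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1L]]
  b <- strsplit(toupper(seq_b), "")[[1L]]
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) stop("global_align: empty sequence")
  gap <- -2; match <- 1; mismatch <- -1
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- gap * (0:n)
  S[1L, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(b == a[i], match, mismatch)
    row_prev <- S[i, ]
    row_cur <- numeric(m + 1L)
    row_cur[1L] <- gap * i
    for (j in seq_len(m)) {
      row_cur[j + 1L] <- max(row_prev[j] + sub[j],   # diagonal
                             row_prev[j + 1L] + gap, # up
                             row_cur[j] + gap)       # left
    }
    S[i + 1L, ] <- row_cur
  }
  # traceback, diagonal > up > left on ties
  i <- n; j <- m
  ra <- character(0); rb <- character(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] == S[i, j] + (if (a[i] == b[j]) match else mismatch)) {
      ra <- c(a[i], ra); rb <- c(b[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      ra <- c(a[i], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(b[j], rb); j <- j - 1L
    }
  }
  list(score = S[n + 1L, m + 1L],
       aligned_a = paste(ra, collapse = ""),
       aligned_b = paste(rb, collapse = ""))
}

#' Identity fraction of the global alignment of two sequences
#'
#' Aligns with [global_align()] and returns matches divided by alignment
#' columns, after stripping terminal gap columns (leading/trailing columns
#' in which either row holds a gap).  Terminal overhangs are uninformative
#' when a short exon query is compared against a hit-delimited scaffold
#' fragment.
#'
#' @inheritParams global_align
#' @return Identity fraction in [0, 1].  Attribute \code{score} carries the
#'   alignment score.
#' @export
global_align_identity <- function(seq_a, seq_b) {
  aln <- global_align(seq_a, seq_b)
  ca <- strsplit(aln$aligned_a, "")[[1L]]
  cb <- strsplit(aln$aligned_b, "")[[1L]]
  gap_col <- ca == "-" | cb == "-"
  inner <- which(!gap_col)
  if (length(inner) == 0L) {
    ident <- 0
  } else {
    span <- inner[1L]:inner[length(inner)]
    ident <- sum(ca[span] == cb[span] & ca[span] != "-") / length(span)
  }
  structure(ident, score = aln$score)
}

#' Confirm candidate scaffolds by realignment identity
#'
#' Recomputes, for every retained hit, the global-alignment identity
#' between the exon query and the hit-delimited scaffold subsequence, and
#' keeps scaffolds with identity at or above \code{min_identity}
#' (inclusive, default 0.80).
#'
#' @param cset A \code{candidate_set} from [select_candidates()].
#' @param exon_seq The query (exon) nucleotide sequence.
#' @param scaffold_subseqs Named character vector or list mapping scaffold
#'   id to its hit-delimited subsequence; every retained scaffold must be
#'   present.
#' @param min_identity Inclusive identity threshold (default 0.80).
#' @return The candidate set with \code{confirmed} filled (a data.frame
#'   subset of \code{retained} with an extra \code{realign_identity}
#'   column).
#' @export
confirm_candidates <- function(cset, exon_seq, scaffold_subseqs,
                               min_identity = 0.80) {
  stopifnot(inherits(cset, "candidate_set"))
  ids <- cset$retained$scaffold_id
  missing <- setdiff(ids, names(scaffold_subseqs))
  if (length(missing)) {
    stop("consistency error: no subsequence for scaffold '", missing[1L], "'")
  }
  ident <- vapply(ids, function(s)
    as.numeric(global_align_identity(exon_seq, scaffold_subseqs[[s]])),
    numeric(1))
  conf <- cset$retained[ident >= min_identity, , drop = FALSE]
  conf$realign_identity <- ident[ident >= min_identity]
  rownames(conf) <- NULL
  cset$confirmed <- conf
  cset
}

#' Cross-reference confirmed candidates with AD-ratio labels
#'
#' One row per (query, confirmed scaffold).  A candidate agrees with the
#' coverage evidence when its scaffold is labelled Y; a scaffold labelled
#' autosomal or X disagrees (likely a gametolog or autosomal paralog); a
#' scaffold with no AD record at all (e.g. no reads mapped with sufficient
#' quality) is flagged \code{no_ad}.
#'
#' @param candidates List of \code{candidate_set} objects with
#'   \code{confirmed} filled.
#' @param ad_records data.frame of AD records
#'   (\code{run_classification()$records}).
#' @return data.frame with columns \code{query_id}, \code{scaffold_id},
#'   \code{ad_label}, \code{agreement} (one of \code{"agree"},
#'   \code{"disagree"}, \code{"no_ad"}).
#' @export
crossref_classes <- function(candidates, ad_records) {
  rows <- lapply(candidates, function(cs) {
    conf <- cs$confirmed
    if (is.null(conf) || nrow(conf) == 0L) return(NULL)
    idx <- match(conf$scaffold_id, ad_records$scaffold_id)
    lab <- ifelse(is.na(idx), NA_character_, ad_records$label[idx])
    agreement <- ifelse(is.na(lab), "no_ad",
                        ifelse(lab == "Y", "agree", "disagree"))
    data.frame(query_id = conf$query_id, scaffold_id = conf$scaffold_id,
               ad_label = ifelse(is.na(lab), "no_ad", lab),
               agreement = agreement, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(query_id = character(), scaffold_id = character(),
                      ad_label = character(), agreement = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
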