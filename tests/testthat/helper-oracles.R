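# Independent oracles used across the suite.  Each deliberately takes a
# different computational route from the implementation it checks.

# Materializes the full per-position depth vector and applies mask and cap
# directly, unlike average_depth() which works from the sparse records.
naive_average_depth <- function(pos, depth, length_bp, ambiguous,
                                depth_cap = 50L) {
  v <- integer(length_bp)
  v[pos] <- depth
  ok <- rep(TRUE, length_bp)
  ok[ambiguous] <- FALSE
  ok[v > depth_cap] <- FALSE
  list(usable_positions = sum(ok),
       sum_depth = sum(as.numeric(v[ok])),
       average_depth = if (sum(ok) > 0) sum(v[ok]) / sum(ok) else NA_real_,
       capped_positions = sum(v > depth_cap & !(seq_len(length_bp) %in%
                                                  ambiguous)))
}

# Exhaustive global-alignment score: enumerates every monotone match set
# between the two sequences.  A set of k matched pairs fixes the score as
# sum of per-pair match/mismatch values plus -2 per unmatched residue.
brute_force_align_score <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1L]]
  b <- strsplit(toupper(seq_b), "")[[1L]]
  m <- length(a); n <- length(b)
  C <- outer(a, b, function(x, y) ifelse(x == y, 1, -1))
  best <- -2 * (m + n) # k = 0
  for (k in seq_len(min(m, n))) {
    A <- utils::combn(m, k)
    B <- utils::combn(n, k)
    tot <- matrix(0, ncol(A), ncol(B))
    for (t in seq_len(k)) {
      tot <- tot + C[A[t, ], B[t, ], drop = FALSE]
    }
    best <- max(best, max(tot) - 2 * (m + n - 2 * k))
  }
  best
}

# Direct single-pass run scanner for the singleton-run filter: per-column
# focal detection by explicit row loops, runs found with a while loop.
naive_singleton_run_columns <- function(rows, min_run = 2L) {
  mat <- do.call(rbind, strsplit(rows, ""))
  nr <- nrow(mat); nc <- ncol(mat)
  focal <- rep(NA_integer_, nc)
  for (j in seq_len(nc)) {
    for (r in seq_len(nr)) {
      others <- mat[-r, j]
      if (length(unique(others)) == 1L && mat[r, j] != others[1L] &&
          length(others) >= 2L) {
        focal[j] <- r
        break
      }
    }
  }
  drop <- logical(nc)
  j <- 1L
  while (j <= nc) {
    if (!is.na(focal[j])) {
      k <- j
      while (k < nc && !is.na(focal[k + 1L]) && focal[k + 1L] == focal[j]) {
        k <- k + 1L
      }
      if (k - j + 1L >= min_run) drop[j:k] <- TRUE
      j <- k + 1L
    } else {
      j <- j + 1L
    }
  }
  which(drop)
}

# Random test alignment: constant consensus plus sprinkled single-row
# mutations and occasional gaps/ambiguity characters.
random_alignment <- function(n_rows = 5L, n_cols = 50L,
                             p_mut = 0.08, p_bad = 0.05) {
  bases <- c("A", "C", "G", "T")
  cons <- sample(bases, n_cols, replace = TRUE)
  mat <- matrix(rep(cons, each = n_rows), nrow = n_rows)
  for (j in seq_len(n_cols)) {
    if (stats::runif(1) < p_mut) {
      r <- sample(n_rows, 1L)
      mat[r, j] <- sample(setdiff(bases, cons[j]), 1L)
    }
    if (stats::runif(1) < p_bad) {
      mat[sample(n_rows, 1L), j] <- sample(c("-", "N", "R"), 1L)
    }
  }
  new_alignment(sprintf("r%02d", seq_len(n_rows)),
                apply(mat, 1L, paste, collapse = ""))
}

# Small hit data.frame builder for similarity-filter tests
hit_row <- function(query, scaffold, pident, len, evalue, bits) {
  data.frame(query_id = query, scaffold_id = scaffold,
             percent_identity = pident, alignment_length = len,
             mismatch = 0L, gapopen = 0L, query_start = 1L,
             query_end = len, subject_start = 1L, subject_end = len,
             e_value = evalue, bit_score = bits, stringsAsFactors = FALSE)
}
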