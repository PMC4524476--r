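#' Configuration for the depth simulator
#'
#' Describes a study design of one male and one female individual sequenced
#' at similar depth (~12x) and mapped against a male-derived assembly whose
#' scaffolds are autosomal, X-linked or Y-linked.  Per-position depths are
#' modelled as independent Poisson draws whose mean follows ploidy:
#' autosomes are diploid in both sexes (mean = coverage), the X is haploid
#' in the male (coverage/2) and diploid in the female, the Y is haploid in
#' the male and absent in the female except for a mismapping fraction of
#' the female coverage.
#'
#' @param n_autosomal,n_x,n_y Number of scaffolds per class (default 100
#'   each).
#' @param length_range_bp Inclusive scaffold length range (default
#'   1000-50000 bp).
#' @param male_autosomal_coverage,female_autosomal_coverage Mean autosomal
#'   depth per sex (default 12).
#' @param mismap_rate Fraction of female haploid-equivalent coverage
#'   spuriously mapped onto Y scaffolds (default 0.01).
#' @param n_run_rate Expected fraction of ambiguous (N) bases, laid out as
#'   geometric-length runs (default 0.01).
#' @param mean_n_run_length Mean length of an N run (default 20 bp).
#' @param read_length_bp,insert_size_bp Library metadata only (defaults
#'   101, 400); the depth model is per-position and does not use them.
#' @param seed Integer seed; the whole truth set is reproducible from it.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_autosomal = 100L, n_x = 100L, n_y = 100L,
                       length_range_bp = c(1000L, 50000L),
                       male_autosomal_coverage = 12,
                       female_autosomal_coverage = 12,
                       mismap_rate = 0.01, n_run_rate = 0.01,
                       mean_n_run_length = 20,
                       read_length_bp = 101L, insert_size_bp = 400L,
                       seed = 1L) {
  stopifnot(male_autosomal_coverage > 0, female_autosomal_coverage > 0,
            length_range_bp[1L] >= 1L,
            length_range_bp[2L] >= length_range_bp[1L],
            mismap_rate >= 0, mismap_rate < 1,
            n_run_rate >= 0, n_run_rate < 1)
  structure(list(n_autosomal = as.integer(n_autosomal),
                 n_x = as.integer(n_x), n_y = as.integer(n_y),
                 length_range_bp = as.integer(length_range_bp),
                 male_autosomal_coverage = male_autosomal_coverage,
                 female_autosomal_coverage = female_autosomal_coverage,
                 mismap_rate = mismap_rate, n_run_rate = n_run_rate,
                 mean_n_run_length = mean_n_run_length,
                 read_length_bp = as.integer(read_length_bp),
                 insert_size_bp = as.integer(insert_size_bp),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# geometric-length N runs at an expected per-base rate
draw_ambiguous_runs <- function(len, rate, mean_run) {
  if (rate <= 0) return(integer(0))
  p_start <- min(1, rate / mean_run)
  starts <- which(stats::runif(len) < p_start)
  if (length(starts) == 0L) return(integer(0))
  run_lens <- 1L + stats::rgeom(length(starts), 1 / mean_run)
  pos <- unlist(lapply(seq_along(starts), function(i)
    starts[i]:min(len, starts[i] + run_lens[i] - 1L)))
  sort(unique(pos))
}

#' Simulate a truth-labelled assembly with male/female depth tables
#'
#' Generates scaffolds of known chromosomal class with N-runs, per-position
#' Poisson depths for each sex under the ploidy model of [sim_config()],
#' and read totals proportional to the per-sex depth sums over the
#' autosomal compartment.  In a real whole-genome dataset the total mapped
#' read count is overwhelmingly autosomal, so its female/male ratio
#' estimates the coverage ratio; deriving simulated totals from the
#' autosomal scaffolds emulates that, even though the simulated assembly
#' deliberately over-represents the sex chromosomes.  Fully reproducible
#' from \code{cfg$seed}.
#'
#' @param cfg A [sim_config()] object.
#' @return A list of class \code{truth_set}: \code{scaffolds} (a
#'   \code{scaffold_info} data.frame with an extra \code{true_class}
#'   column), \code{female_depths}, \code{male_depths} (zero-depth
#'   positions omitted, as in \command{samtools depth} output),
#'   \code{totals}, \code{config}.
#' @export
simulate_truth_set <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_autosomal + cfg$n_x + cfg$n_y
  true_class <- c(rep("autosomal", cfg$n_autosomal),
                  rep("X", cfg$n_x), rep("Y", cfg$n_y))
  ids <- sprintf("scaffold_%04d", seq_len(n))
  lens <- sample(cfg$length_range_bp[1L]:cfg$length_range_bp[2L], n,
                 replace = TRUE)
  amb <- lapply(lens, draw_ambiguous_runs,
                rate = cfg$n_run_rate, mean_run = cfg$mean_n_run_length)

  cf <- cfg$female_autosomal_coverage
  cm <- cfg$male_autosomal_coverage
  mean_female <- c(autosomal = cf, X = cf, Y = cf * cfg$mismap_rate)
  mean_male <- c(autosomal = cm, X = cm / 2, Y = cm / 2)

  draw_tab <- function(means) {
    per <- lapply(seq_len(n), function(i) {
      d <- stats::rpois(lens[i], means[[true_class[i]]])
      nz <- which(d > 0L)
      list(pos = nz, depth = d[nz], total = sum(as.numeric(d)))
    })
    auto <- true_class == "autosomal"
    list(tab = data.frame(
           scaffold = rep(ids, vapply(per, function(x) length(x$pos),
                                      integer(1))),
           pos = unlist(lapply(per, `[[`, "pos")),
           depth = unlist(lapply(per, `[[`, "depth")),
           stringsAsFactors = FALSE),
         total = sum(vapply(per[auto], `[[`, numeric(1), "total")))
  }
  f <- draw_tab(mean_female)
  m <- draw_tab(mean_male)

  scaffolds <- scaffold_info(ids, lens, amb)
  scaffolds$true_class <- true_class
  structure(list(scaffolds = scaffolds,
                 female_depths = f$tab, male_depths = m$tab,
                 totals = read_totals(max(f$total, 1), max(m$total, 1)),
                 config = cfg),
            class = "truth_set")
}

#' Write a simulated truth set to disk in pipeline input formats
#'
#' Emits \code{reference.fa} (random ACGT bases with N at the ambiguous
#' positions), \code{female.depth.tsv} / \code{male.depth.tsv},
#' \code{totals.txt} (key=value) and \code{truth_labels.tsv}.
#'
#' @param truth A \code{truth_set} from [simulate_truth_set()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_truth_set <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(reference = file.path(dir, "reference.fa"),
             female = file.path(dir, "female.depth.tsv"),
             male = file.path(dir, "male.depth.tsv"),
             totals = file.path(dir, "totals.txt"),
             labels = file.path(dir, "truth_labels.tsv"))
  sc <- truth$scaffolds
  # sequence content is cosmetic; derive from the same seed for determinism
  set.seed(truth$config$seed + 1L)
  seqs <- vapply(seq_len(nrow(sc)), function(i) {
    s <- sample(c("A", "C", "G", "T"), sc$length_bp[i], replace = TRUE)
    s[sc$ambiguous[[i]]] <- "N"
    paste(s, collapse = "")
  }, character(1))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- sc$scaffold_id
  Biostrings::writeXStringSet(x, paths["reference"])
  write_depth_table(truth$female_depths, paths["female"])
  write_depth_table(truth$male_depths, paths["male"])
  writeLines(c(paste0("female=", format(truth$totals$female, scientific = FALSE)),
               paste0("male=", format(truth$totals$male, scientific = FALSE))),
             paths["totals"])
  utils::write.table(
    data.frame(scaffold_id = sc$scaffold_id, length_bp = sc$length_bp,
               true_class = sc$true_class,
               n_ambiguous = lengths(sc$ambiguous)),
    paths["labels"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Simulate a similarity-hit table with known expected candidate sets
#'
#' For each query, plants a best hit on a Y scaffold of the truth set plus
#' three decoys: one passing both retention rules (identity >= 95\% of the
#' best hit's, alignment length within 5\%), one failing the identity rule
#' and one failing the length rule.  The expected retained set per query is
#' therefore the best hit and the passing decoy.
#'
#' @param truth A \code{truth_set}; decoy scaffolds are drawn from it.
#' @param n_queries Number of queries (default 5).
#' @param seed Integer seed.
#' @return A list: \code{hits} (12-column hit data.frame, row order
#'   shuffled), \code{expected} (named list: query id -> character vector
#'   of retained scaffold ids, best first).
#' @export
simulate_hit_table <- function(truth, n_queries = 5L, seed = 1L) {
  set.seed(seed)
  sc <- truth$scaffolds
  y_ids <- sc$scaffold_id[sc$true_class == "Y"]
  other_ids <- sc$scaffold_id
  stopifnot(length(y_ids) >= 1L, length(other_ids) >= 4L)
  rows <- list(); expected <- list()
  for (q in seq_len(n_queries)) {
    qid <- sprintf("gene%02d_exon1", q)
    scafs <- c(sample(y_ids, 1L),
               sample(setdiff(other_ids, y_ids), 3L))
    best_id <- stats::runif(1, 96, 100)
    best_len <- sample(150:300, 1L)
    pass_id <- best_id * stats::runif(1, 0.96, 0.999)
    fail_id <- best_id * stats::runif(1, 0.80, 0.94)
    pass_len <- round(best_len * stats::runif(1, 0.96, 1.04))
    fail_len <- round(best_len * stats::runif(1, 1.10, 1.30))
    mk <- function(scaf, pid, len, ev, bs) {
      data.frame(query_id = qid, scaffold_id = scaf,
                 percent_identity = round(pid, 2), alignment_length = len,
                 mismatch = round(len * (1 - pid / 100)), gapopen = 0L,
                 query_start = 1L, query_end = len,
                 subject_start = 101L, subject_end = 100L + len,
                 e_value = ev, bit_score = bs, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- rbind(
      mk(scafs[1], best_id, best_len, 1e-60, 400),
      mk(scafs[2], pass_id, pass_len, 1e-50, 350), # retained
      mk(scafs[3], fail_id, best_len, 1e-40, 300), # identity too low
      mk(scafs[4], best_id, fail_len, 1e-45, 320)) # length off by >5%
    expected[[qid]] <- c(scafs[1], scafs[2])
  }
  hits <- do.call(rbind, rows)
  hits <- hits[sample(nrow(hits)), , drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits, expected = expected)
}

#' Simulate an alignment with an exactly planted removable fraction
#'
#' Builds an alignment whose strict column filters remove exactly
#' \code{planted_removable_fraction} of the columns: a mix of gap/ambiguity
#' columns and length-2 same-row singleton runs, separated by constant
#' buffer columns.  When space allows, one isolated singleton column and
#' one adjacent pair of singletons in different rows are planted as
#' features the filter must keep.
#'
#' @param n_rows Number of rows (>= 3 so singleton columns are
#'   attributable).
#' @param n_cols Number of columns.
#' @param planted_removable_fraction Fraction of columns to be removed;
#'   \code{n_cols * fraction} must be a whole number and the layout must
#'   fit, otherwise an error is raised.
#' @param seed Integer seed.
#' @return A list: \code{alignment} (an \code{msa_alignment}),
#'   \code{stats} (expected filter statistics, same layout as
#'   [filter_alignment()]'s).
#' @export
simulate_alignment <- function(n_rows, n_cols, planted_removable_fraction,
                               seed = 1L) {
  stopifnot(n_rows >= 3L, n_cols >= 1L,
            planted_removable_fraction >= 0,
            planted_removable_fraction <= 1)
  k_real <- planted_removable_fraction * n_cols
  k <- round(k_real)
  if (abs(k_real - k) > 1e-9) {
    stop("requested removable fraction is not a whole number of columns at n_cols = ",
         n_cols)
  }
  set.seed(seed)
  n_pairs <- k %/% 4L
  ks <- 2L * n_pairs
  ka <- k - ks
  feats <- c(rep("ambig", ka), rep("run", n_pairs))
  # kept features, added only when the layout still fits
  width <- function(f) c(ambig = 1L, run = 2L, lone = 1L, mixed = 2L)[[f]]
  fits <- function(fs) {
    sum(vapply(fs, width, integer(1))) + max(0L, length(fs) - 1L) <= n_cols
  }
  if (!fits(feats)) {
    stop("requested removable fraction does not fit at n_cols = ", n_cols)
  }
  for (extra in c("lone", "mixed")) {
    if (fits(c(feats, extra))) feats <- c(feats, extra)
  }
  feats <- sample(feats)

  bases <- c("A", "C", "G", "T")
  cons <- sample(bases, n_cols, replace = TRUE)
  mat <- matrix(rep(cons, each = n_rows), nrow = n_rows)
  alt <- function(b) sample(setdiff(bases, b), 1L)

  col <- 1L
  for (f in feats) {
    w <- width(f)
    if (f == "ambig") {
      mat[sample(n_rows, 1L), col] <- sample(c("-", "N"), 1L)
    } else if (f == "run") {
      r <- sample(n_rows, 1L)
      mat[r, col] <- alt(cons[col])
      mat[r, col + 1L] <- alt(cons[col + 1L])
    } else if (f == "lone") {
      mat[sample(n_rows, 1L), col] <- alt(cons[col])
    } else { # mixed: adjacent singletons in two different rows
      rr <- sample(n_rows, 2L)
      mat[rr[1L], col] <- alt(cons[col])
      mat[rr[2L], col + 1L] <- alt(cons[col + 1L])
    }
    col <- col + w + 1L # +1 constant buffer column
  }
  aln <- new_alignment(sprintf("ind%02d", seq_len(n_rows)),
                       apply(mat, 1L, paste, collapse = ""))
  stats <- data.frame(input_columns = n_cols,
                      removed_ambiguous_or_gap = ka,
                      removed_singleton_runs = ks,
                      output_columns = n_cols - k,
                      removed_fraction = k / n_cols)
  list(alignment = aln, stats = stats)
}
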