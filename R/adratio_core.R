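#' Classification thresholds and filters for the AD-ratio method
#'
#' Bundles the policy constants of the average-depth ratio approach:
#' the inclusive Y-linkage cutoff (AD-ratio <= \code{y_max}), the open
#' autosomal interval (\code{auto_low}, \code{auto_high}), the open X-linked
#' interval (\code{x_low}, \code{x_high}), the minimum scaffold length, the
#' per-position depth cap, and the histogram bin width.
#'
#' The defaults reflect a study design of one male and one female individual
#' at ~12x coverage mapped against a male-derived assembly: the expected
#' female/male depth ratio is 0 for Y-linked, 1 for autosomal and 2 for
#' X-linked scaffolds.  The relaxed Y cutoff of 0.3 tolerates mismapped
#' female reads on true Y scaffolds.
#'
#' @param y_max Inclusive upper AD-ratio bound for the Y label (default 0.3).
#' @param auto_low,auto_high Open interval for the autosomal label
#'   (defaults 0.7, 1.3).
#' @param x_low,x_high Open interval for the X label (defaults 1.7, 2.3).
#' @param min_scaffold_bp Scaffolds shorter than this are excluded
#'   (default 1000).
#' @param depth_cap Positions with more than this many reads are discarded
#'   (default 50).
#' @param bin_width Histogram bin width (default 0.02).
#' @param cap_mode How capped positions affect the average: \code{"trim"}
#'   removes them from numerator and denominator (unbiased trimmed mean,
#'   default); \code{"denominator_keeps_capped"} keeps them in the
#'   denominator only (the literal reading of the published sentence).
#' @return A list of class \code{ad_thresholds}.
#' @export
ad_thresholds <- function(y_max = 0.3, auto_low = 0.7, auto_high = 1.3,
                          x_low = 1.7, x_high = 2.3,
                          min_scaffold_bp = 1000L, depth_cap = 50L,
                          bin_width = 0.02,
                          cap_mode = c("trim", "denominator_keeps_capped")) {
  cap_mode <- match.arg(cap_mode)
  if (!(0 <= y_max && y_max < auto_low && auto_low < auto_high &&
        auto_high < x_low && x_low < x_high)) {
    stop("thresholds must satisfy 0 <= y_max < auto_low < auto_high < x_low < x_high")
  }
  if (min_scaffold_bp < 1L) stop("min_scaffold_bp must be >= 1")
  if (depth_cap < 1L) stop("depth_cap must be >= 1")
  if (bin_width <= 0) stop("bin_width must be > 0")
  structure(list(y_max = y_max, auto_low = auto_low, auto_high = auto_high,
                 x_low = x_low, x_high = x_high,
                 min_scaffold_bp = as.integer(min_scaffold_bp),
                 depth_cap = as.integer(depth_cap),
                 bin_width = bin_width, cap_mode = cap_mode),
            class = "ad_thresholds")
}

#' Average read depth of one scaffold for one individual
#'
#' Computes the scaffold's average depth as the sum of depth values at
#' ambiguity-free positions with at most \code{depth_cap} reads, divided by
#' the number of contributing positions.  Positions missing from the depth
#' records are zero-depth: they contribute nothing to the sum but are
#' counted in the denominator (unless ambiguous).
#'
#' @param pos Integer vector of 1-based positions with nonzero depth.
#' @param depth Integer vector of depths, parallel to \code{pos}.
#' @param length_bp Scaffold length.
#' @param ambiguous Integer vector of ambiguous (non-ACGT) positions.
#' @param depth_cap Maximum depth for a position to contribute (default 50).
#' @param cap_mode See [ad_thresholds()].
#' @return A list: \code{usable_positions}, \code{sum_depth},
#'   \code{average_depth} (NA when no position is usable),
#'   \code{capped_positions}.
#' @export
average_depth <- function(pos, depth, length_bp, ambiguous = integer(0),
                          depth_cap = 50L,
                          cap_mode = c("trim", "denominator_keeps_capped")) {
  cap_mode <- match.arg(cap_mode)
  if (length(pos) && max(pos) > length_bp) {
    stop("depth record position ", max(pos),
         " beyond scaffold length ", length_bp)
  }
  n_amb <- length(ambiguous)
  if (length(ambiguous)) {
    keep <- !(pos %in% ambiguous)
    pos <- pos[keep]
    depth <- depth[keep]
  }
  over <- depth > depth_cap
  capped <- sum(over)
  sum_depth <- sum(as.numeric(depth[!over]))
  usable <- length_bp - n_amb - if (cap_mode == "trim") capped else 0L
  avg <- if (usable > 0L) sum_depth / usable else NA_real_
  list(usable_positions = as.integer(usable),
       sum_depth = sum_depth,
       average_depth = avg,
       capped_positions = as.integer(capped))
}

#' Normalization factor between female and male read totals
#'
#' Divides the total number of mapped reads (quality >= 20) in the female
#' by that of the male, standardizing the two genomes to the same
#' genome-wide coverage before ratios are compared.
#'
#' @param totals List with positive elements \code{female} and \code{male}
#'   (see [read_totals()]).
#' @return The scalar normalization factor.
#' @export
normalization_factor <- function(totals) {
  if (is.null(totals$male) || totals$male <= 0) {
    stop("undefined normalization: male read total must be > 0")
  }
  if (is.null(totals$female) || totals$female <= 0) {
    stop("undefined normalization: female read total must be > 0")
  }
  totals$female / totals$male
}

#' Average-depth ratio of a scaffold
#'
#' \deqn{AD = \bar d_{female} / (\bar d_{male} \times norm)}
#' where \eqn{norm} is the female/male read-total ratio.  Undefined
#' (\code{NA}) when the male average depth is zero.
#'
#' @param avg_female,avg_male Non-negative average depths.
#' @param norm Positive normalization factor.
#' @return The AD-ratio, or \code{NA} when undefined.
#' @export
ad_ratio <- function(avg_female, avg_male, norm) {
  stopifnot(norm > 0)
  if (is.na(avg_female) || is.na(avg_male)) return(NA_real_)
  if (avg_male == 0) return(NA_real_)
  avg_female / (avg_male * norm)
}

#' Chromosomal class from an AD-ratio
#'
#' Y when \code{ad <= y_max} (inclusive), autosomal when strictly inside
#' (\code{auto_low}, \code{auto_high}), X when strictly inside
#' (\code{x_low}, \code{x_high}); anything else, including an undefined
#' ratio, is unassigned.  Comparisons are exact: thresholds are policy
#' constants, not estimates.
#'
#' @param ad Numeric vector of AD-ratios (NA = undefined).
#' @param thresholds An [ad_thresholds()] object.
#' @return Character vector of labels in
#'   \code{c("Y", "autosomal", "X", "unassigned")}.
#' @export
classify_ad <- function(ad, thresholds = ad_thresholds()) {
  t <- thresholds
  out <- rep("unassigned", length(ad))
  out[!is.na(ad) & ad <= t$y_max] <- "Y"
  out[!is.na(ad) & ad > t$auto_low & ad < t$auto_high] <- "autosomal"
  out[!is.na(ad) & ad > t$x_low & ad < t$x_high] <- "X"
  out
}

#' Histogram of AD-ratios in fixed-width bins
#'
#' Bins values into left-closed, right-open intervals
#' \eqn{[k w, (k+1) w)}: a value \eqn{v} falls in bin
#' \eqn{\lfloor v/w \rfloor}.  When scaffold lengths are supplied the
#' combined length per bin is reported alongside the counts.
#'
#' @param ads Numeric vector of finite, non-negative AD-ratios.
#' @param bin_width Bin width (default 0.02).
#' @param lengths_bp Optional vector of scaffold lengths parallel to
#'   \code{ads}.
#' @return data.frame with columns \code{bin}, \code{bin_start},
#'   \code{bin_end}, \code{count} and, when lengths are given,
#'   \code{combined_bp}; one row per non-empty bin, ordered by bin.
#' @export
ad_histogram <- function(ads, bin_width = 0.02, lengths_bp = NULL) {
  if (length(ads) == 0L) {
    out <- data.frame(bin = integer(), bin_start = numeric(),
                      bin_end = numeric(), count = integer())
    if (!is.null(lengths_bp)) out$combined_bp <- numeric()
    return(out)
  }
  if (any(!is.finite(ads)) || any(ads < 0)) {
    stop("histogram values must be finite and >= 0")
  }
  r <- ads / bin_width
  idx <- floor(r)
  # snap values that are within 1e-9 of a bin boundary onto it, so that the
  # left-closed convention survives floating point (0.06/0.02 = 2.999...)
  snap <- abs(r - round(r)) < 1e-9
  idx[snap] <- round(r[snap])
  idx <- as.integer(idx)
  bins <- sort(unique(idx))
  count <- vapply(bins, function(b) sum(idx == b), integer(1))
  out <- data.frame(bin = bins,
                    bin_start = bins * bin_width,
                    bin_end = (bins + 1L) * bin_width,
                    count = count)
  if (!is.null(lengths_bp)) {
    stopifnot(length(lengths_bp) == length(ads))
    out$combined_bp <- vapply(bins, function(b)
      sum(as.numeric(lengths_bp[idx == b])), numeric(1))
  }
  out
}

#' Classify every scaffold of an assembly from male and female depth tables
#'
#' The full AD-ratio pipeline: per-scaffold average depths in each sex
#' (ambiguity mask + depth cap), read-total normalization, AD-ratios,
#' threshold classification, exclusion filters and the binned histogram.
#'
#' Scaffolds shorter than \code{min_scaffold_bp} are excluded
#' (\code{too_short}); scaffolds with zero usable positions in either sex
#' are excluded (\code{no_usable_positions}); scaffolds in
#' \code{exclude_ids} (e.g. a low-mapping-quality list computed upstream)
#' are excluded (\code{excluded_list}).  A defined label or
#' \code{unassigned} is given to every remaining scaffold; a scaffold whose
#' male average depth is zero has an undefined ratio and is unassigned.
#'
#' @param female_depths,male_depths Depth data.frames (columns
#'   \code{scaffold}, \code{pos}, \code{depth}) as from
#'   [read_depth_table()].
#' @param reference_info A \code{scaffold_info} data.frame
#'   ([scan_reference()] or [scaffold_info()]).
#' @param totals Read totals list ([read_totals()]).
#' @param thresholds An [ad_thresholds()] object.
#' @param exclude_ids Optional character vector of scaffold ids to exclude.
#' @return A list with \code{records} (one row per scaffold, sorted by
#'   scaffold id: scaffold_id, length_bp, avg_female, avg_male, norm,
#'   ad_ratio, label, exclusion_reason, undefined) and \code{histogram}
#'   (non-excluded scaffolds with a defined ratio).
#' @export
run_classification <- function(female_depths, male_depths, reference_info,
                               totals, thresholds = ad_thresholds(),
                               exclude_ids = character(0)) {
  ids <- reference_info$scaffold_id
  for (tab in list(female_depths, male_depths)) {
    unknown <- setdiff(unique(tab$scaffold), ids)
    if (length(unknown)) {
      stop("consistency error: scaffold '", unknown[1L],
           "' in depth table but absent from reference")
    }
  }
  norm <- normalization_factor(totals)
  ord <- order(ids)
  f_idx <- split(seq_len(nrow(female_depths)), female_depths$scaffold)
  m_idx <- split(seq_len(nrow(male_depths)), male_depths$scaffold)

  n <- length(ids)
  avg_f <- avg_m <- ad <- rep(NA_real_, n)
  label <- rep("unassigned", n)
  reason <- rep(NA_character_, n)
  undef <- rep(FALSE, n)

  for (i in seq_len(n)) {
    id <- ids[i]
    len <- reference_info$length_bp[i]
    if (id %in% exclude_ids) {
      label[i] <- "excluded"; reason[i] <- "excluded_list"; next
    }
    if (len < thresholds$min_scaffold_bp) {
      label[i] <- "excluded"; reason[i] <- "too_short"; next
    }
    amb <- reference_info$ambiguous[[i]]
    fi <- f_idx[[id]]
    mi <- m_idx[[id]]
    sf <- average_depth(female_depths$pos[fi], female_depths$depth[fi],
                        len, amb, thresholds$depth_cap, thresholds$cap_mode)
    sm <- average_depth(male_depths$pos[mi], male_depths$depth[mi],
                        len, amb, thresholds$depth_cap, thresholds$cap_mode)
    if (sf$usable_positions == 0L || sm$usable_positions == 0L) {
      label[i] <- "excluded"; reason[i] <- "no_usable_positions"; next
    }
    avg_f[i] <- sf$average_depth
    avg_m[i] <- sm$average_depth
    if (avg_m[i] == 0 && avg_f[i] == 0) {
      # no reads mapped in either sex: no evidence at all
      label[i] <- "excluded"; reason[i] <- "no_usable_positions"; next
    }
    ad[i] <- ad_ratio(avg_f[i], avg_m[i], norm)
    if (is.na(ad[i])) {
      undef[i] <- TRUE
      label[i] <- "unassigned"
    } else {
      label[i] <- classify_ad(ad[i], thresholds)
    }
  }

  records <- data.frame(scaffold_id = ids,
                        length_bp = reference_info$length_bp,
                        avg_female = avg_f, avg_male = avg_m,
                        norm = norm, ad_ratio = ad, label = label,
                        exclusion_reason = reason, undefined = undef,
                        stringsAsFactors = FALSE)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  keep <- records$label != "excluded" & !is.na(records$ad_ratio)
  hist <- ad_histogram(records$ad_ratio[keep], thresholds$bin_width,
                       records$length_bp[keep])
  list(records = records, histogram = hist, norm = norm)
}

#' Write classification records and histogram as TSV
#'
#' @param result List returned by [run_classification()].
#' @param records_path,histogram_path Output paths (either may be NULL).
#' @param provenance Optional character vector written as leading
#'   \code{#}-comment lines.
#' @return Invisibly, \code{result}.
#' @export
write_classification <- function(result, records_path = NULL,
                                 histogram_path = NULL,
                                 provenance = NULL) {
  emit <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  if (!is.null(records_path)) emit(result$records, records_path)
  if (!is.null(histogram_path)) emit(result$histogram, histogram_path)
  invisible(result)
}
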