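test_that("average depth applies the ambiguity mask and depth cap", {
  # constant depth, nothing masked
  s <- average_depth(1:1000, rep(7L, 1000), 1000)
  expect_equal(s$average_depth, 7)
  expect_equal(s$usable_positions, 1000L)

  # depths (5, 10, 60, 0) with cap 50: position 3 is trimmed entirely
  s <- average_depth(1:3, c(5L, 10L, 60L), 4L)
  expect_equal(s$sum_depth, 15)
  expect_equal(s$usable_positions, 3L)
  expect_equal(s$average_depth, 5)
  expect_equal(s$capped_positions, 1L)

  # literal reading keeps capped positions in the denominator
  s2 <- average_depth(1:3, c(5L, 10L, 60L), 4L,
                      cap_mode = "denominator_keeps_capped")
  expect_equal(s2$usable_positions, 4L)
  expect_equal(s2$average_depth, 15 / 4)

  # ambiguity mask removes a constant block
  s <- average_depth(11:100, rep(4L, 90), 100L, ambiguous = 1:10)
  expect_equal(s$usable_positions, 90L)
  expect_equal(s$average_depth, 4)

  # a masked position does not count even if depth is listed there
  s <- average_depth(1:4, c(9L, 9L, 9L, 9L), 4L, ambiguous = 4L)
  expect_equal(s$usable_positions, 3L)
  expect_equal(s$sum_depth, 27)

  expect_error(average_depth(5L, 3L, 4L), "beyond scaffold length")
})

test_that("sparse average depth matches full-vector recomputation exactly", {
  set.seed(11)
  for (i in 1:100) {
    len <- sample(20:500, 1)
    n_amb <- sample(0:10, 1)
    amb <- sort(sample(len, n_amb))
    nzpos <- sort(sample(len, sample(0:len, 1)))
    depth <- sample(0:80, length(nzpos), replace = TRUE)
    keep <- depth > 0L
    got <- average_depth(nzpos[keep], depth[keep], len, amb)
    want <- naive_average_depth(nzpos[keep], depth[keep], len, amb)
    expect_identical(got$usable_positions, want$usable_positions)
    expect_identical(got$sum_depth, want$sum_depth)
    expect_equal(got$average_depth, want$average_depth)
    expect_identical(got$capped_positions, as.integer(want$capped_positions))
  }
})

test_that("normalization factor is the female/male read-total ratio", {
  expect_equal(normalization_factor(read_totals(1000, 1000)), 1)
  expect_equal(normalization_factor(read_totals(500, 1000)), 0.5)
  expect_error(normalization_factor(list(female = 100, male = 0)),
               "normalization")
})

test_that("AD-ratio handles zero numerator and undefined denominator", {
  expect_equal(ad_ratio(0, 6, 1), 0)
  expect_equal(ad_ratio(12, 6, 1), 2)
  expect_true(is.na(ad_ratio(3, 0, 1)))
  # scale invariance: scaling both totals leaves every ratio unchanged
  for (k in c(0.5, 3, 1e6)) {
    n1 <- normalization_factor(read_totals(400, 800))
    n2 <- normalization_factor(read_totals(400 * k, 800 * k))
    expect_equal(ad_ratio(5, 7, n1), ad_ratio(5, 7, n2))
  }
})

test_that("classification thresholds follow the published intervals", {
  expect_equal(classify_ad(0.075), "Y")     # validated SRY scaffold ratio
  expect_equal(classify_ad(1.0), "autosomal")
  expect_equal(classify_ad(2.0), "X")
  expect_equal(classify_ad(0.5), "unassigned")
  expect_equal(classify_ad(0.3), "Y")       # inclusive Y bound
  # strict autosomal/X bounds: the printed inequalities are open
  expect_equal(classify_ad(c(0.7, 1.3, 1.7, 2.3)), rep("unassigned", 4))
  expect_equal(classify_ad(NA_real_), "unassigned")
  expect_error(ad_thresholds(y_max = 0.8), "thresholds")
})

test_that("labels move monotonically with increasing female depth", {
  norm <- 1
  avg_m <- 10
  rank <- c(Y = 1, unassigned = NA, autosomal = 2, X = 3)
  labels <- classify_ad(vapply(seq(0, 30, by = 0.05),
                               function(f) ad_ratio(f, avg_m, norm),
                               numeric(1)))
  seen <- rank[labels[labels != "unassigned"]]
  expect_true(all(diff(seen) >= 0))
})

test_that("histogram uses left-closed bins and conserves totals", {
  h <- ad_histogram(c(0.01, 0.015, 0.03), 0.02)
  expect_equal(h$count[h$bin == 0], 2L)
  expect_equal(h$count[h$bin == 1], 1L)

  expect_equal(nrow(ad_histogram(numeric(0))), 0L)

  # boundary value lands in the upper bin (left-closed convention),
  # also for boundaries that are not exactly representable
  expect_equal(ad_histogram(0.02, 0.02)$bin, 1L)
  expect_equal(ad_histogram(0.06, 0.02)$bin, 3L)
  expect_equal(ad_histogram(1.0, 0.02)$bin, 50L)

  expect_error(ad_histogram(c(0.5, Inf)), "finite")

  set.seed(3)
  ads <- stats::runif(500, 0, 2.5)
  lens <- sample(1000:9999, 500)
  h <- ad_histogram(ads, 0.02, lens)
  expect_equal(sum(h$count), 500L)
  expect_equal(sum(h$combined_bp), sum(lens))
})

test_that("run_classification applies exclusion rules and partitions labels", {
  info <- scaffold_info(c("auto1", "short1", "silent1", "xlike", "ylike",
                          "fonly"),
                        c(2000L, 900L, 2000L, 2000L, 2000L, 2000L))
  mk <- function(id, len, d) data.frame(scaffold = id, pos = seq_len(len),
                                        depth = rep(d, len),
                                        stringsAsFactors = FALSE)
  female <- rbind(mk("auto1", 2000, 10L), mk("short1", 900, 10L),
                  mk("xlike", 2000, 20L), mk("fonly", 2000, 8L))
  male <- rbind(mk("auto1", 2000, 10L), mk("short1", 900, 10L),
                mk("xlike", 2000, 10L), mk("ylike", 2000, 5L))
  res <- run_classification(female, male, info, read_totals(1000, 1000))
  rec <- res$records
  get <- function(id) rec[rec$scaffold_id == id, ]

  expect_equal(get("auto1")$label, "autosomal")
  expect_equal(get("xlike")$label, "X")
  expect_equal(get("ylike")$label, "Y")
  expect_equal(get("ylike")$ad_ratio, 0)
  expect_equal(get("short1")$label, "excluded")
  expect_equal(get("short1")$exclusion_reason, "too_short")
  expect_equal(get("silent1")$label, "excluded")
  expect_equal(get("silent1")$exclusion_reason, "no_usable_positions")
  # female reads but zero male depth: ratio undefined, never Y
  expect_equal(get("fonly")$label, "unassigned")
  expect_true(get("fonly")$undefined)

  # every scaffold gets exactly one label; counts add up
  expect_setequal(rec$scaffold_id, info$scaffold_id)
  expect_equal(sum(table(rec$label)), nrow(info))
  expect_true(all(xor(rec$label == "excluded",
                      is.na(rec$exclusion_reason))))
  # output sorted by scaffold id
  expect_equal(rec$scaffold_id, sort(info$scaffold_id))

  # histogram covers exactly the classifiable scaffolds
  expect_equal(sum(res$histogram$count), 3L)

  expect_error(
    run_classification(mk("ghost", 10, 1L), male, info,
                       read_totals(1, 1)),
    "absent from reference")

  # upstream low-quality exclusion list
  res2 <- run_classification(female, male, info, read_totals(1000, 1000),
                             exclude_ids = "auto1")
  expect_equal(res2$records$exclusion_reason[
    res2$records$scaffold_id == "auto1"], "excluded_list")
})

test_that("a fully N scaffold is excluded for lack of usable positions", {
  info <- scaffold_info("nscaf", 1500L, list(1:1500))
  res <- run_classification(
    data.frame(scaffold = character(), pos = integer(), depth = integer()),
    data.frame(scaffold = character(), pos = integer(), depth = integer()),
    info, read_totals(10, 10))
  expect_equal(res$records$exclusion_reason, "no_usable_positions")
})
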