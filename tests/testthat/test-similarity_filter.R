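test_that("candidate selection applies the identity and length rules", {
  hits <- rbind(hit_row("ex1", "S1", 99, 200, 1e-50, 400),
                hit_row("ex1", "S2", 95, 198, 1e-45, 350),
                hit_row("ex1", "S3", 80, 100, 1e-10, 100))
  cs <- select_candidates(hits)
  expect_equal(cs$best_hit$scaffold_id, "S1")
  # S2: 95 >= 0.95 * 99 = 94.05 and |198-200|/200 = 1% <= 5%; S3 fails both
  expect_setequal(cs$retained$scaffold_id, c("S1", "S2"))

  # single hit is retained as its own best
  cs1 <- select_candidates(hit_row("ex1", "S9", 85, 120, 1e-3, 50))
  expect_equal(cs1$retained$scaffold_id, "S9")

  # identical scores: lexicographic scaffold tie-break, both retained
  tie <- rbind(hit_row("ex1", "S2", 97, 150, 1e-20, 200),
               hit_row("ex1", "S1", 97, 150, 1e-20, 200))
  cst <- select_candidates(tie)
  expect_equal(cst$best_hit$scaffold_id, "S1")
  expect_setequal(cst$retained$scaffold_id, c("S1", "S2"))

  # e-value tie broken by bit score before scaffold id
  bs <- rbind(hit_row("ex1", "S1", 97, 150, 1e-20, 150),
              hit_row("ex1", "S2", 97, 150, 1e-20, 260))
  expect_equal(select_candidates(bs)$best_hit$scaffold_id, "S2")

  expect_error(select_candidates(hits[0, ]), "empty")
  expect_error(select_candidates(rbind(hit_row("a", "S1", 9, 5, 1, 1),
                                       hit_row("b", "S1", 9, 5, 1, 1))),
               "one query_id")
})

test_that("selection keeps one hit per scaffold and ignores input order", {
  hits <- rbind(hit_row("ex1", "S1", 99, 200, 1e-50, 400),
                hit_row("ex1", "S1", 90, 180, 1e-20, 150), # worse S1 hit
                hit_row("ex1", "S2", 96, 205, 1e-44, 340),
                hit_row("ex1", "S3", 97, 260, 1e-30, 250)) # length off
  base <- select_candidates(hits)
  expect_equal(sum(base$retained$scaffold_id == "S1"), 1L)
  expect_equal(base$retained$percent_identity[
    base$retained$scaffold_id == "S1"], 99)
  expect_setequal(base$retained$scaffold_id, c("S1", "S2"))

  set.seed(5)
  for (i in 1:10) {
    perm <- select_candidates(hits[sample(nrow(hits)), ])
    expect_equal(perm$retained$scaffold_id, base$retained$scaffold_id)
  }
  # output is always a subset of the input, best hit included
  expect_true(all(base$retained$scaffold_id %in% hits$scaffold_id))
  expect_true(base$best_hit$scaffold_id %in% base$retained$scaffold_id)
})

test_that("absolute similarity mode thresholds identity at 95 percent", {
  hits <- rbind(hit_row("ex1", "S1", 99, 200, 1e-50, 400),
                hit_row("ex1", "S2", 94.5, 200, 1e-45, 350))
  expect_setequal(select_candidates(hits)$retained$scaffold_id,
                  c("S1", "S2"))                     # 94.5 >= 94.05
  expect_equal(select_candidates(hits, similarity_mode = "absolute")
               $retained$scaffold_id, "S1")          # 94.5 < 95
})

test_that("global alignment identity matches hand-checked cases", {
  expect_equal(as.numeric(global_align_identity("ACGT", "ACGT")), 1)
  expect_equal(as.numeric(global_align_identity("ACGT", "ACGA")), 0.75)
  # terminal gap columns are stripped from the identity denominator
  expect_equal(as.numeric(global_align_identity("ACGT", "ACGTAA")), 1)
  expect_equal(as.numeric(global_align_identity("CCACGT", "ACGT")), 1)
  expect_error(global_align("", "ACGT"), "empty")
})

test_that("alignment score equals the exhaustive enumeration oracle", {
  set.seed(2024)
  for (i in 1:200) {
    la <- sample(1:8, 1)
    lb <- sample(1:8, 1)
    a <- paste(sample(c("A", "C", "G", "T"), la, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), lb, TRUE), collapse = "")
    expect_equal(global_align(a, b)$score, brute_force_align_score(a, b),
                 info = paste(a, b))
  }
})

test_that("confirmation keeps candidates at or above 80 percent identity", {
  hits <- rbind(hit_row("ex1", "S1", 99, 20, 1e-50, 400),
                hit_row("ex1", "S2", 97, 20, 1e-45, 350))
  cs <- select_candidates(hits)
  exon <- "AAAAAAAAAA"
  subseqs <- c(S1 = exon,            # identity 1.00
               S2 = "CCCCCCCCCC")    # identity 0.00
  conf <- confirm_candidates(cs, exon, subseqs)
  expect_equal(conf$confirmed$scaffold_id, "S1")

  # inclusive threshold: exactly 8/10 = 0.80 is kept
  subseqs["S2"] <- "AAAAAAAACC"
  conf <- confirm_candidates(cs, exon, subseqs, min_identity = 0.80)
  expect_setequal(conf$confirmed$scaffold_id, c("S1", "S2"))

  # relaxing the threshold never shrinks the confirmed set
  ths <- c(0.95, 0.9, 0.8, 0.7, 0.5, 0)
  sizes <- vapply(ths, function(t)
    nrow(confirm_candidates(cs, exon, subseqs, min_identity = t)$confirmed),
    integer(1))
  expect_true(all(diff(sizes) >= 0))

  expect_error(confirm_candidates(cs, exon, subseqs["S1"]),
               "no subsequence")
})

test_that("cross-reference flags agreement with coverage labels", {
  ad <- data.frame(scaffold_id = c("S1", "S2", "S3"),
                   label = c("Y", "X", "autosomal"),
                   stringsAsFactors = FALSE)
  hits <- rbind(hit_row("ex1", "S1", 99, 20, 1e-50, 400),
                hit_row("ex1", "S2", 99, 20, 1e-45, 350),
                hit_row("ex1", "S4", 99, 20, 1e-40, 300))
  cs <- select_candidates(hits)
  cs$confirmed <- cs$retained
  rep <- crossref_classes(list(cs), ad)
  expect_equal(rep$agreement[rep$scaffold_id == "S1"], "agree")
  expect_equal(rep$agreement[rep$scaffold_id == "S2"], "disagree")
  # scaffold without an AD record (no reads mapped): flagged, not dropped
  expect_equal(rep$agreement[rep$scaffold_id == "S4"], "no_ad")
})
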