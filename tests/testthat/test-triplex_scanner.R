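test_that("pure poly(A) folds score floor((n - loop_min)/2)", {
  # brute-force oracle values frozen for the boundary lengths:
  # n = 50 -> 23, 40 -> 18, 39 -> 17, 20 -> 8
  for (case in list(c(50, 23), c(40, 18), c(39, 17), c(20, 8))) {
    n <- case[1]; want <- case[2]
    expect_equal(oracle_best_fold_score(strrep("A", n)), want)
    f <- score_fold(strrep("A", n))
    expect_equal(f$score, want)
    expect_equal(f$stem_length, want)
    expect_equal(f$stem_mismatches, 0L)
  }
  # shortest loop wins the tie, stems fill the tract
  f <- score_fold(strrep("A", 50))
  expect_equal(f$loop_end - f$loop_start, 4L)
  expect_equal(c(f$stem1_start, f$stem2_end), c(0L, 50L))
  # monotone in n, exact closed form from loop_min + 2 up
  scores <- vapply(6:60, function(n) score_fold(strrep("A", n))$score,
                   numeric(1))
  expect_equal(scores, floor(((6:60) - 4) / 2))
  expect_true(all(diff(scores) >= 0))
})

test_that("a mirrored G contributes a canonical C.G.C triplet", {
  # stems AAAAAAAAGAAAA / AAAAGAAAAAAAA around a CCCC loop: a perfect
  # 13-triplet mirror including the G.G position
  s <- "AAAAAAAAGAAAACCCCAAAAGAAAAAAAA"
  f <- score_fold(s)
  expect_equal(f$score, 13)
  expect_equal(f$canonical_triplets, 13L)
  expect_equal(f$stem_mismatches, 0L)
  expect_equal(oracle_best_fold_score(s), 13)

  # breaking the mirror (G not mirrored) costs the mismatch penalty
  s2 <- "AAAAAAAAGAAAACCCCAAAAAAAAAAAAA"
  expect_equal(score_fold(s2)$score, oracle_best_fold_score(s2))
  expect_lt(score_fold(s2)$score, 13)
})

test_that("fold scoring is invariant under sequence reversal", {
  set.seed(23)
  for (rep in 1:50) {
    n <- sample(10:60, 1)
    s <- paste(sample(c("A", "G"), n, replace = TRUE, prob = c(0.8, 0.2)),
               collapse = "")
    r <- paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
    expect_equal(score_fold(s)$score, score_fold(r)$score)
  }
})

test_that("extension scoring equals exhaustive fold enumeration", {
  set.seed(29)
  for (rep in 1:60) {
    n <- sample(7:60, 1)
    s <- paste(sample(c("A", "G"), n, replace = TRUE,
                      prob = c(0.7, 0.3)), collapse = "")
    want <- oracle_best_fold_score(s)
    got <- score_fold(s)
    if (want < 1) {
      expect_null(got)
    } else {
      expect_equal(got$score, want)
    }
  }
  # too short for any loop
  expect_null(score_fold("AAAAA"))
})

test_that("tract finding respects class, length and interruption rules", {
  scheme <- scoring_scheme()
  # (dA)50 between short pyrimidine flanks
  s <- paste0(strrep("C", 10), strrep("A", 50), strrep("T", 10))
  tr <- find_tracts(s, scheme)
  expect_equal(nrow(tr), 1L)
  expect_equal(c(tr$start, tr$end), c(10L, 60L))
  expect_equal(tr$purine_strand, "given")

  # alternating (AT)34 is neither class
  expect_equal(nrow(find_tracts(strrep("AT", 34), scheme)), 0L)

  # (dT)50 is a purine tract on the complementary strand
  tr <- find_tracts(paste0(strrep("G", 10), strrep("T", 50), strrep("A", 10)),
                    scheme)
  tr <- tr[tr$end - tr$start == 50, ]
  expect_equal(tr$purine_strand, "complement")

  # one interruption is tolerated inside, two split the tract
  one <- paste0(strrep("C", 5), strrep("A", 10), "C", strrep("A", 10),
                strrep("C", 5))
  tr <- find_tracts(one, scheme)
  expect_equal(tr$interruptions[tr$purine_strand == "given"], 1L)
  expect_equal(tr$end[tr$purine_strand == "given"] -
                 tr$start[tr$purine_strand == "given"], 21L)
  two <- paste0(strrep("C", 5), strrep("A", 10), "CC", strrep("A", 10),
                strrep("C", 5))
  expect_equal(sum(find_tracts(two, scheme)$purine_strand == "given"), 0L)

  # N conforms to neither class
  expect_equal(nrow(find_tracts(paste0(strrep("A", 10), "N",
                                       strrep("A", 10)),
                                scoring_scheme(max_interruptions = 0))), 0L)
})

test_that("longest A/T run follows leftmost-then-A tie-breaking", {
  r <- longest_AT_run("AAATTTTT")
  expect_equal(list(r$base, r$offset, r$length), list("T", 3L, 5L))
  expect_equal(longest_AT_run(strrep("A", 50))$length, 50L)
  expect_equal(longest_AT_run("ATATAT")$length, 1L)
  expect_equal(longest_AT_run("ATATAT")$base, "A")   # leftmost
  expect_equal(longest_AT_run("TTTAAA")$base, "T")   # leftmost at ties
  expect_equal(longest_AT_run("")$length, 0L)
  expect_equal(longest_AT_run("GGCC")$length, 0L)
})

test_that("region scans report runs, thresholds and non-overlapping hits", {
  set.seed(31)
  scheme <- scoring_scheme()
  bg <- generate_background(2000, 0.5, seed = 101)
  plant <- function(bg, tract) {
    # substitution with C guards, mid-window
    at <- 1000L
    paste0(substr(bg, 1, at - 2), "C", tract, "C",
           substr(bg, at + nchar(tract) + 1, nchar(bg)))
  }
  hits <- scan_triplexes(plant(bg, strrep("A", 50)), scheme)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$score, 23)
  expect_equal(hits$run_length, 50L)
  expect_true(hits$passing)

  hits <- scan_triplexes(plant(bg, strrep("A", 40)), scheme)
  expect_equal(hits$score, 18)      # boundary pass
  expect_true(hits$passing)
  hits <- scan_triplexes(plant(bg, strrep("A", 39)), scheme)
  expect_equal(hits$score, 17)
  expect_false(hits$passing)

  # scanning the complement flips the purine strand, scores unchanged
  s <- plant(bg, strrep("A", 50))
  comp <- chartr("ACGT", "TGCA", s)
  h1 <- scan_triplexes(s, scheme)
  h2 <- scan_triplexes(comp, scheme)
  expect_equal(h2$score, h1$score)
  expect_equal(h2$tract_start, h1$tract_start)
  expect_setequal(c(h1$purine_strand, h2$purine_strand),
                  c("given", "complement"))
})
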