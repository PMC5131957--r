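# build one synthetic promoter region with the requested planted features
planted_region <- function(features, seed = 301, gene_id = "G1") {
  spec <- promoter_spec(gene_id, features = features, seed = seed)
  bg <- generate_background(7000, 0.5, seed = seed)
  pl <- plant_features(bg, spec)
  region_from_sequence(pl$sequence, gene_id = gene_id)
}

con_feat <- function(at = 5100) list(kind = "con", at = at, spacer = 3L,
                                     mismatches = 0L)
tract_feat <- function(len, at = 2500, base = "A") {
  list(kind = "tract", at = at, base = base, length = len)
}

test_that("the joint filter passes exactly the qualifying combinations", {
  r <- planted_region(list(tract_feat(50), con_feat()))
  cand <- screen_region(r)
  expect_true(cand$passes)
  expect_gte(nrow(cand$con_sites), 1L)
  expect_equal(cand$best_hit$score, 23)
  expect_equal(cand$best_hit$run_length, 50L)

  # (dA)20: too short to fold past the threshold
  cand <- screen_region(planted_region(list(tract_feat(20), con_feat())))
  expect_false(cand$passes)
  expect_equal(cand$best_hit$score, 8)

  # triplex without CON fails, unless the CON requirement is lifted
  r <- planted_region(list(tract_feat(50)))
  expect_false(screen_region(r)$passes)
  expect_true(screen_region(
    r, screen_params(require_con = FALSE))$passes)

  # passing score but short run: a mirror A/G tract is not a candidate
  cand <- screen_region(planted_region(list(tract_feat(50, base = "AG"),
                                            con_feat())))
  expect_equal(cand$best_hit$score, 23)
  expect_false(cand$passes)
})

test_that("raising thresholds never adds candidates", {
  regions <- lapply(c(40, 45, 50), function(len) {
    planted_region(list(tract_feat(len), con_feat()), seed = 300 + len)
  })
  base_pass <- vapply(regions, function(r) screen_region(r)$passes,
                      logical(1))
  for (ms in c(18, 20, 23, 24)) {
    for (mr in c(41, 46, 51)) {
      p <- screen_params(triplex = scoring_scheme(min_score = ms),
                         min_AT_run = mr)
      pass <- vapply(regions, function(r) screen_region(r, p)$passes,
                     logical(1))
      expect_true(all(pass <= base_pass))
      base_ms_only <- vapply(regions, function(r) {
        screen_region(r, screen_params(
          triplex = scoring_scheme(min_score = ms)))$passes
      }, logical(1))
      expect_true(all(pass <= base_ms_only))
    }
  }
})

test_that("relative distance is signed positive toward downstream CONs", {
  con <- data.frame(span_start = 5090, span_end = 5110)   # midpoint +100
  hit <- data.frame(stem1_start = 2790, stem2_end = 2810) # midpoint -2200
  expect_equal(relative_distance(con, hit), 2300)
  expect_equal(relative_distance(con, con[, ] |>
                                   setNames(c("stem1_start", "stem2_end"))), 0)
  hit2 <- data.frame(stem1_start = 5590, stem2_end = 5610)
  expect_equal(relative_distance(con, hit2), -500)
  expect_equal(relative_distance(con, hit, anchor = "start"), 2300)
})

test_that("distance histograms use half-open bins and conserve counts", {
  h <- distance_histogram(c(2300, 2400), bin_width = 500)
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$bin_start, h$bin_end, h$count), c(2000, 2500, 2))

  # an exact bin edge falls into the upper bin
  h <- distance_histogram(2500, bin_width = 500)
  expect_equal(h$bin_start, 2500)

  expect_equal(nrow(distance_histogram(numeric(0))), 0L)

  set.seed(37)
  d <- rnorm(500, 0, 3000)
  for (w in c(250, 500, 1000)) {
    expect_equal(sum(distance_histogram(d, w)$count), length(d))
  }
  expect_true(all(distance_histogram(-2500, 500)$bin_start == -2500))
})

test_that("position profiles are TSS-relative with TSS at 0", {
  r <- planted_region(list(tract_feat(50), con_feat()))
  prof <- position_profile(screen_promoters(list(r)))
  trip <- prof[prof$feature == "triplex", ]
  expect_equal(trip$rel_start, 2500 - 5000)
  con <- prof[prof$feature == "con", ]
  expect_true(all(con$rel_start >= 0))  # planted downstream of the TSS
  # offset arithmetic at the extremes of the window
  off <- r$offset_of_tss
  expect_equal(0L - off, -5000L)
  expect_equal(6999L - off, 1999L)
  expect_equal(5000L - off, 0L)
})

test_that("the candidate report is sorted, deterministic and 1-based", {
  regions <- list(
    planted_region(list(tract_feat(42), con_feat()), seed = 401, gene_id = "A"),
    planted_region(list(tract_feat(50), con_feat()), seed = 402, gene_id = "B"),
    planted_region(list(tract_feat(20), con_feat()), seed = 403, gene_id = "C"),
    planted_region(list(tract_feat(46), con_feat()), seed = 404, gene_id = "D"),
    planted_region(list(con_feat()), seed = 405, gene_id = "E"))
  scr <- screen_promoters(regions)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  rep1 <- write_candidate_report(scr, tsv)
  expect_equal(rep1$gene_id, c("B", "D", "A"))  # descending run length
  expect_equal(rep1$triplex_genomic_start[rep1$gene_id == "B"],
               scr$candidates[[2]]$best_hit$stem1_start + 1L)
  rep2 <- write_candidate_report(scr, tsv)
  expect_identical(rep1, rep2)

  # empty pass set still writes a header-only file
  none <- screen_promoters(regions[5])
  write_candidate_report(none, tsv)
  expect_equal(length(readLines(tsv)), 1L)
})
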