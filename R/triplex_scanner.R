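#' Scoring scheme for intramolecular triplex (H-DNA) folds
#'
#' An intramolecular triplex forms when one half of a mirror-repeated
#' homopurine/homopyrimidine tract folds back into the major groove of the
#' remaining duplex. Each mirror-matched position contributes one canonical
#' base triplet (A gives T.A.T / T.A.A, G gives C.G.C / C.G.G) worth
#' \code{triplet_weight}; a mirror mismatch costs \code{mismatch_penalty}.
#' The fold needs a single-stranded loop of \code{loop_min}..\code{loop_max}
#' nt between the duplex stem and the fold-back third strand, and no
#' insertions are allowed in the stems.
#'
#' With the defaults (+1 / -2, loop 4-12) a pure poly(A) tract of length n
#' scores \code{floor((n - loop_min) / 2)}, which makes the two screen
#' thresholds coherent: a score of 18 is first reached at tract length 40,
#' i.e. exactly where a poly(A/T) run "longer than 40 bp" begins to pass.
#'
#' @param triplet_weight Score per canonical triplet (> 0).
#' @param mismatch_penalty Score per stem mismatch (<= 0).
#' @param loop_min,loop_max Allowed loop lengths in nt.
#' @param min_score Minimum fold score for a hit to pass the screen.
#' @param min_tract Minimum homopurine/homopyrimidine tract length in nt.
#' @param max_interruptions Maximum non-conforming bases tolerated inside a
#'   tract.
#' @return A list of class \code{scoring_scheme}.
#' @export
scoring_scheme <- function(triplet_weight = 1, mismatch_penalty = -2,
                           loop_min = 4, loop_max = 12, min_score = 18,
                           min_tract = 15, max_interruptions = 1) {
  stopifnot(triplet_weight > 0, mismatch_penalty <= 0, loop_min >= 1,
            loop_min <= loop_max, min_tract >= 2, max_interruptions >= 0)
  structure(list(triplet_weight = triplet_weight,
                 mismatch_penalty = mismatch_penalty,
                 loop_min = as.integer(loop_min),
                 loop_max = as.integer(loop_max),
                 min_score = min_score,
                 min_tract = as.integer(min_tract),
                 max_interruptions = as.integer(max_interruptions)),
            class = "scoring_scheme")
}

# greedy left-to-right maximal tracts for one base class; conform is a
# logical vector; returns 0-based half-open [start, end) with interruption
# counts.  After emitting a tract the scan resumes at the conforming run
# that follows the first interruption consumed, so overlapping tracts that
# share a suffix are both found; exact containments are dropped afterwards.
.find_tracts_one <- function(conform, min_tract, max_interruptions) {
  r <- rle(conform)
  nr <- length(r$lengths)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  res <- list()
  i <- if (nr > 0L && r$values[1L]) 1L else 2L
  while (i <= nr) {
    b <- i
    ints <- 0L
    first_false <- NA_integer_
    k <- i + 1L
    while (k + 1L <= nr) {
      flen <- r$lengths[k]
      if (ints + flen > max_interruptions) break
      ints <- ints + flen
      if (is.na(first_false)) first_false <- k
      b <- k + 1L
      k <- k + 2L
    }
    s0 <- starts[i] - 1L
    e0 <- ends[b]
    if (e0 - s0 >= min_tract) {
      res[[length(res) + 1L]] <- c(s0, e0, ints)
    }
    i <- if (is.na(first_false)) b + 2L else first_false + 1L
  }
  if (length(res) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      interruptions = integer()))
  }
  m <- do.call(rbind, res)
  df <- data.frame(start = m[, 1L], end = m[, 2L], interruptions = m[, 3L])
  # drop tracts contained in another tract of the same class
  keep <- rep(TRUE, nrow(df))
  for (a in seq_len(nrow(df))) {
    contained <- df$start <= df$start[a] & df$end >= df$end[a] &
      (df$start != df$start[a] | df$end != df$end[a])
    if (any(contained & keep)) keep[a] <- FALSE
  }
  df[keep, , drop = FALSE]
}

#' Find homopurine / homopyrimidine tracts
#'
#' Maximal runs of purines (A/G) of length at least \code{min_tract}
#' containing at most \code{max_interruptions} non-conforming bases;
#' pyrimidine (C/T) runs are reported symmetrically as purine tracts on the
#' complementary strand. Non-conforming bases never sit at tract ends, and
#' \code{N} conforms to neither class.
#'
#' @param region A [regulatory_region] or sequence string.
#' @param scheme A [scoring_scheme].
#' @return Data frame with 0-based half-open \code{start}, \code{end},
#'   \code{purine_strand} (\code{"given"} or \code{"complement"}) and
#'   \code{interruptions}, sorted by start.
#' @export
find_tracts <- function(region, scheme = scoring_scheme()) {
  seq <- if (inherits(region, "regulatory_region")) region$sequence
         else toupper(region)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pur <- .find_tracts_one(chars == "A" | chars == "G",
                          scheme$min_tract, scheme$max_interruptions)
  pyr <- .find_tracts_one(chars == "C" | chars == "T",
                          scheme$min_tract, scheme$max_interruptions)
  if (nrow(pur)) pur$purine_strand <- "given"
  else pur$purine_strand <- character(0)
  if (nrow(pyr)) pyr$purine_strand <- "complement"
  else pyr$purine_strand <- character(0)
  out <- rbind(pur, pyr)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("start", "end", "purine_strand", "interruptions")]
}

#' Score the best intramolecular-triplex fold of a tract
#'
#' Enumerates every fold of the purine-strand tract sequence: an innermost
#' stem pair \code{(i, j)} leaving a loop of \code{loop_min}..\code{loop_max}
#' nt, extended outward one triplet at a time. At stem depth d the duplex
#' base at \code{i - d} pairs with the fold-back third-strand base derived
#' from \code{j + d}; the triplet is canonical iff the two tract bases are
#' identical purines (the mirror-repeat criterion), otherwise it is a stem
#' mismatch. Stems never extend past the tract. Ties are broken by shorter
#' loop, then leftmost first-stem start; the hit carries the pyrimidine
#' motif label (the purine-motif fold of the same geometry scores
#' identically under this scheme).
#'
#' @param tract_sequence Purine-strand view of the tract (a string; for a
#'   pyrimidine tract pass the complemented sequence).
#' @param scheme A [scoring_scheme].
#' @return A one-row data frame describing the best fold (0-based half-open
#'   \code{stem1_start/end, loop_start/end, stem2_start/end} relative to the
#'   tract, \code{stem_length}, \code{canonical_triplets},
#'   \code{stem_mismatches}, \code{score}, \code{motif}), or \code{NULL} if
#'   no fold scores at least 1.
#' @examples
#' score_fold(strrep("A", 50))$score  # 23
#' @export
score_fold <- function(tract_sequence, scheme = scoring_scheme()) {
  x <- strsplit(toupper(tract_sequence), "", fixed = TRUE)[[1L]]
  n <- length(x)
  if (n < 2L + scheme$loop_min) return(NULL)
  w <- scheme$triplet_weight
  p <- scheme$mismatch_penalty
  ispur <- x == "A" | x == "G"
  best <- NULL   # c(score, loop_len, stem1_start0, i, j, k)
  for (loop_len in scheme$loop_min:scheme$loop_max) {
    imax <- n - loop_len - 1L
    if (imax < 1L) break
    for (i in seq_len(imax)) {
      j <- i + loop_len + 1L
      kmax <- min(i, n - j + 1L)
      d <- 0:(kmax - 1L)
      li <- i - d
      ri <- j + d
      match <- (x[li] == x[ri]) & ispur[li] & ispur[ri]
      cums <- cumsum(ifelse(match, w, p))
      smax <- max(cums)
      # largest k at the max => leftmost stem1 start among ties
      k <- max(which(cums == smax))
      stem1_start0 <- i - k
      cand <- c(smax, loop_len, stem1_start0, i, j, k)
      if (is.null(best) ||
          smax > best[1L] ||
          (smax == best[1L] && loop_len < best[2L]) ||
          (smax == best[1L] && loop_len == best[2L] &&
           stem1_start0 < best[3L])) {
        best <- cand
      }
    }
  }
  if (is.null(best) || best[1L] < 1) return(NULL)
  i <- best[4L]; j <- best[5L]; k <- best[6L]
  d <- 0:(k - 1L)
  canon <- sum((x[i - d] == x[j + d]) & ispur[i - d] & ispur[j + d])
  data.frame(stem1_start = i - k, stem1_end = i,
             loop_start = i, loop_end = j - 1L,
             stem2_start = j - 1L, stem2_end = j - 1L + k,
             stem_length = k, canonical_triplets = canon,
             stem_mismatches = k - canon, score = best[1L],
             motif = "pyrimidine", stringsAsFactors = FALSE)
}

#' Longest poly(A) or poly(T) run
#'
#' The longest maximal run of identical A's or identical T's; ties go to
#' the leftmost run, and to A before T at equal offset (unreachable for
#' distinct bases). An empty sequence, or one without any A or T, yields a
#' length-0 run.
#'
#' @param sequence Sequence string.
#' @return List with \code{base}, \code{offset} (0-based) and \code{length}.
#' @examples
#' longest_AT_run("AAATTTTT")  # T run of length 5 at offset 3
#' @export
longest_AT_run <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L) {
    return(list(base = NA_character_, offset = 0L, length = 0L))
  }
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  at <- which(r$values %in% c("A", "T"))
  if (length(at) == 0L) {
    return(list(base = NA_character_, offset = 0L, length = 0L))
  }
  lens <- r$lengths[at]
  cand <- at[lens == max(lens)]
  pick <- cand[1L]  # leftmost
  list(base = r$values[pick], offset = starts[pick] - 1L,
       length = r$lengths[pick])
}

.empty_triplex_hits <- function() {
  data.frame(tract_start = integer(), tract_end = integer(),
             purine_strand = character(), interruptions = integer(),
             stem1_start = integer(), stem1_end = integer(),
             loop_start = integer(), loop_end = integer(),
             stem2_start = integer(), stem2_end = integer(),
             stem_length = integer(), canonical_triplets = integer(),
             stem_mismatches = integer(), score = numeric(),
             motif = character(), run_base = character(),
             run_start = integer(), run_length = integer(),
             passing = logical(), stringsAsFactors = FALSE)
}

#' Scan a region for intramolecular-triplex hits
#'
#' Finds homopurine/homopyrimidine tracts, scores the best mirror-repeat
#' fold of each, annotates the longest poly(A)/poly(T) run within the
#' tract, flags hits reaching \code{min_score}, and greedily keeps
#' non-overlapping hits in descending score order.
#'
#' For a pyrimidine tract the purine-strand view is obtained by
#' complementing (without reversing) the given-strand slice; the mirror
#' criterion is reversal-invariant, so scores and coordinates are identical
#' to scoring the true 5'-to-3' purine strand.
#'
#' @param region A [regulatory_region] or sequence string.
#' @param scheme A [scoring_scheme].
#' @return Data frame of hits with tract, stem/loop coordinates (0-based
#'   half-open, region frame), scores, run annotation and a \code{passing}
#'   flag; sorted by position.
#' @export
scan_triplexes <- function(region, scheme = scoring_scheme()) {
  seq <- if (inherits(region, "regulatory_region")) region$sequence
         else toupper(region)
  tracts <- find_tracts(seq, scheme)
  if (nrow(tracts) == 0L) return(.empty_triplex_hits())
  hits <- .empty_triplex_hits()
  for (t in seq_len(nrow(tracts))) {
    s0 <- tracts$start[t]; e0 <- tracts$end[t]
    slice <- substr(seq, s0 + 1L, e0)
    view <- if (tracts$purine_strand[t] == "complement") {
      chartr("ACGTN", "TGCAN", slice)
    } else slice
    fold <- score_fold(view, scheme)
    if (is.null(fold)) next
    run <- longest_AT_run(slice)
    hits <- rbind(hits, data.frame(
      tract_start = s0, tract_end = e0,
      purine_strand = tracts$purine_strand[t],
      interruptions = tracts$interruptions[t],
      stem1_start = s0 + fold$stem1_start, stem1_end = s0 + fold$stem1_end,
      loop_start = s0 + fold$loop_start, loop_end = s0 + fold$loop_end,
      stem2_start = s0 + fold$stem2_start, stem2_end = s0 + fold$stem2_end,
      stem_length = fold$stem_length,
      canonical_triplets = fold$canonical_triplets,
      stem_mismatches = fold$stem_mismatches, score = fold$score,
      motif = fold$motif, run_base = run$base,
      run_start = s0 + run$offset, run_length = run$length,
      passing = fold$score >= scheme$min_score, stringsAsFactors = FALSE))
  }
  if (nrow(hits) <= 1L) return(hits)
  # greedy non-overlap on the fold span, best score first
  ord <- order(-hits$score, hits$stem1_start)
  kept <- integer(0L)
  for (h in ord) {
    overlaps <- any(hits$stem1_start[kept] < hits$stem2_end[h] &
                    hits$stem2_end[kept] > hits$stem1_start[h])
    if (!overlaps) kept <- c(kept, h)
  }
  hits <- hits[sort(kept), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
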