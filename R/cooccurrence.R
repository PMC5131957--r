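#' Parameters for the joint CON + triplex promoter screen
#'
#' @param con A [con_scan_params] object.
#' @param triplex A [scoring_scheme] object.
#' @param min_AT_run Minimum longest poly(A)/poly(T) run, in nt, of the best
#'   triplex hit (default 41, i.e. strictly longer than 40 bp).
#' @param require_con Whether a promoter must also carry at least one CON
#'   site to pass.
#' @return A list of class \code{screen_params}.
#' @export
screen_params <- function(con = con_scan_params(),
                          triplex = scoring_scheme(),
                          min_AT_run = 41, require_con = TRUE) {
  stopifnot(min_AT_run >= 1)
  structure(list(con = con, triplex = triplex,
                 min_AT_run = as.integer(min_AT_run),
                 require_con = isTRUE(require_con)),
            class = "screen_params")
}

#' Screen one promoter region
#'
#' Runs the CON scanner and the triplex scanner on a region, picks the best
#' triplex hit (highest score, then longest run, then leftmost), and applies
#' the candidate filter: at least one CON site (unless
#' \code{require_con = FALSE}), best fold score at least
#' \code{triplex$min_score}, and the best hit's poly(A/T) run at least
#' \code{min_AT_run} nt.
#'
#' @param region A [regulatory_region].
#' @param params A [screen_params] object.
#' @return An object of class \code{candidate_gene}: list with the region,
#'   \code{con_sites} and \code{triplex_hits} data frames, the
#'   \code{best_hit} row (or NULL), signed \code{relative_distances} between
#'   each CON and the best hit, and the \code{passes} flag.
#' @export
screen_region <- function(region, params = screen_params()) {
  stopifnot(inherits(region, "regulatory_region"))
  cons <- scan_con(region, params$con)
  hits <- scan_triplexes(region, params$triplex)
  best <- NULL
  if (nrow(hits)) {
    ord <- order(-hits$score, -hits$run_length, hits$stem1_start)
    best <- hits[ord[1L], , drop = FALSE]
  }
  passes <- (!params$require_con || nrow(cons) >= 1L) &&
    !is.null(best) &&
    best$score >= params$triplex$min_score &&
    best$run_length >= params$min_AT_run
  dists <- numeric(0L)
  if (!is.null(best) && nrow(cons)) {
    dists <- vapply(seq_len(nrow(cons)), function(i) {
      relative_distance(cons[i, ], best)
    }, numeric(1L))
  }
  structure(list(region = region, con_sites = cons, triplex_hits = hits,
                 best_hit = best, relative_distances = dists,
                 passes = passes, params = params),
            class = "candidate_gene")
}

#' @export
print.candidate_gene <- function(x, ...) {
  cat(sprintf("<candidate_gene> %s: %d CON site(s), %d triplex hit(s)%s -- %s\n",
              x$region$gene_id, nrow(x$con_sites), nrow(x$triplex_hits),
              if (!is.null(x$best_hit))
                sprintf(", best score %g (run %d nt)",
                        x$best_hit$score, x$best_hit$run_length)
              else "",
              if (x$passes) "PASSES" else "does not pass"))
  invisible(x)
}

#' Screen a set of promoters
#'
#' @param regions List of [regulatory_region] objects.
#' @param params A [screen_params] object.
#' @return Object of class \code{triplex_screen}: list of
#'   \code{candidate_gene} results plus the parameters.
#' @export
screen_promoters <- function(regions, params = screen_params()) {
  res <- lapply(regions, screen_region, params = params)
  structure(list(candidates = res, params = params),
            class = "triplex_screen")
}

#' @export
print.triplex_screen <- function(x, ...) {
  n <- length(x$candidates)
  pass <- sum(vapply(x$candidates, function(c) c$passes, logical(1L)))
  cat(sprintf("<triplex_screen> %d promoter(s) screened, %d candidate(s) pass\n",
              n, pass))
  invisible(x)
}

#' @method summary triplex_screen
#' @export
summary.triplex_screen <- function(object, ...) {
  cands <- object$candidates
  with_con <- sum(vapply(cands, function(c) nrow(c$con_sites) >= 1L,
                         logical(1L)))
  pass_score <- vapply(cands, function(c) {
    any(c$triplex_hits$passing)
  }, logical(1L))
  # both readings of "sequences with a passing triplex": promoters, and
  # distinct passing loci
  n_loci <- sum(vapply(cands, function(c) sum(c$triplex_hits$passing),
                       integer(1L)))
  passes <- vapply(cands, function(c) c$passes, logical(1L))
  out <- list(n_screened = length(cands), n_with_con = with_con,
              n_with_passing_triplex = sum(pass_score),
              n_passing_triplex_loci = n_loci,
              n_candidates = sum(passes),
              candidate_ids = vapply(cands[passes],
                                     function(c) c$region$gene_id,
                                     character(1L)))
  class(out) <- "summary.triplex_screen"
  out
}

#' @export
print.summary.triplex_screen <- function(x, ...) {
  cat("Promoters screened:            ", x$n_screened, "\n")
  cat("  with >= 1 CON site:          ", x$n_with_con, "\n")
  cat("  with passing triplex:        ", x$n_with_passing_triplex,
      sprintf("(%d distinct loci)\n", x$n_passing_triplex_loci))
  cat("  joint candidates:            ", x$n_candidates, "\n")
  if (length(x$candidate_ids)) {
    cat("Candidates:", paste(x$candidate_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

.feature_midpoint <- function(start, end) (start + end) / 2

#' Signed distance between a CON site and a triplex hit
#'
#' Positive when the CON midpoint lies downstream (3' in transcription
#' orientation) of the triplex midpoint; magnitude is the midpoint
#' separation in bp. Start-to-start anchoring is available via
#' \code{anchor = "start"}.
#'
#' @param con One row of a CON-site data frame (\code{span_start},
#'   \code{span_end}).
#' @param hit One row of a triplex-hit data frame (\code{stem1_start},
#'   \code{stem2_end}).
#' @param anchor \code{"midpoint"} (default) or \code{"start"}.
#' @return Signed distance in bp.
#' @export
relative_distance <- function(con, hit, anchor = c("midpoint", "start")) {
  anchor <- match.arg(anchor)
  if (anchor == "midpoint") {
    .feature_midpoint(con$span_start, con$span_end) -
      .feature_midpoint(hit$stem1_start, hit$stem2_end)
  } else {
    con$span_start - hit$stem1_start
  }
}

#' Histogram of CON-to-triplex distances
#'
#' Bins are half-open \code{[k*w, (k+1)*w)} over signed distances; counts
#' conserve the number of (CON, best triplex) pairs tallied.
#'
#' @param screen A \code{triplex_screen}, a list of \code{candidate_gene}
#'   objects, or a numeric vector of signed distances.
#' @param bin_width Bin width in bp (> 0).
#' @param passing_only Tally only promoters that pass the screen (default).
#' @return Data frame with \code{bin_start}, \code{bin_end}, \code{count};
#'   empty for no pairs.
#' @export
distance_histogram <- function(screen, bin_width = 500,
                               passing_only = TRUE) {
  stopifnot(bin_width > 0)
  if (is.numeric(screen)) {
    dists <- screen
  } else {
    cands <- if (inherits(screen, "triplex_screen")) screen$candidates
             else screen
    dists <- unlist(lapply(cands, function(c) {
      if (passing_only && !c$passes) return(numeric(0L))
      c$relative_distances
    }))
  }
  if (length(dists) == 0L) {
    return(data.frame(bin_start = numeric(), bin_end = numeric(),
                      count = integer()))
  }
  k <- floor(dists / bin_width)
  tab <- table(k)
  ks <- as.numeric(names(tab))
  data.frame(bin_start = ks * bin_width, bin_end = (ks + 1) * bin_width,
             count = as.integer(tab))
}

#' TSS-relative positions of CON sites and best triplex hits
#'
#' @param screen A \code{triplex_screen} or list of \code{candidate_gene}
#'   objects.
#' @param passing_only Restrict to passing promoters (default).
#' @return Long data frame: \code{gene_id, feature} (\code{"con"} or
#'   \code{"triplex"}), \code{rel_start, rel_end} (TSS-relative,
#'   transcription-oriented, TSS = 0).
#' @export
position_profile <- function(screen, passing_only = TRUE) {
  cands <- if (inherits(screen, "triplex_screen")) screen$candidates
           else screen
  rows <- lapply(cands, function(c) {
    if (passing_only && !c$passes) return(NULL)
    off <- c$region$offset_of_tss
    out <- NULL
    if (nrow(c$con_sites)) {
      out <- data.frame(gene_id = c$region$gene_id, feature = "con",
                        rel_start = c$con_sites$span_start - off,
                        rel_end = c$con_sites$span_end - off,
                        stringsAsFactors = FALSE)
    }
    if (!is.null(c$best_hit)) {
      out <- rbind(out, data.frame(
        gene_id = c$region$gene_id, feature = "triplex",
        rel_start = c$best_hit$stem1_start - off,
        rel_end = c$best_hit$stem2_end - off, stringsAsFactors = FALSE))
    }
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), feature = character(),
                      rel_start = integer(), rel_end = integer())
  }
  rownames(out) <- NULL
  out
}

#' Write the candidate-gene report
#'
#' One row per passing promoter, sorted by descending poly(A/T) run length
#' then descending score (the screen ranks primarily on predicted triplex
#' length). Coordinates are 1-based inclusive genomic plus TSS-relative
#' positions; CON positions and distances are semicolon-joined lists.
#'
#' @param screen A \code{triplex_screen} or list of \code{candidate_gene}s.
#' @param path Output TSV path.
#' @return The report data frame, invisibly.
#' @export
write_candidate_report <- function(screen, path) {
  cands <- if (inherits(screen, "triplex_screen")) screen$candidates
           else screen
  rows <- lapply(cands, function(c) {
    if (!c$passes) return(NULL)
    r <- c$region
    off <- r$offset_of_tss
    b <- c$best_hit
    gstart <- min(region_to_genomic(r, c(b$stem1_start, b$stem2_end - 1L)))
    data.frame(
      gene_id = r$gene_id, transcript_id = r$transcript_id,
      chrom = r$chrom, strand = r$strand,
      triplex_genomic_start = gstart + 1L,                  # 1-based incl.
      triplex_genomic_end = gstart + (b$stem2_end - b$stem1_start),
      triplex_rel_start = b$stem1_start - off,
      triplex_rel_end = b$stem2_end - off,
      triplex_score = b$score, run_base = b$run_base,
      run_length = b$run_length,
      n_con = nrow(c$con_sites),
      con_rel_starts = paste(c$con_sites$span_start - off, collapse = ";"),
      relative_distances = paste(round(c$relative_distances, 1),
                                 collapse = ";"),
      stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  if (is.null(report)) {
    report <- data.frame(gene_id = character(), transcript_id = character(),
                         chrom = character(), strand = character(),
                         triplex_genomic_start = integer(),
                         triplex_genomic_end = integer(),
                         triplex_rel_start = integer(),
                         triplex_rel_end = integer(),
                         triplex_score = numeric(), run_base = character(),
                         run_length = integer(), n_con = integer(),
                         con_rel_starts = character(),
                         relative_distances = character())
  } else {
    report <- report[order(-report$run_length, -report$triplex_score,
                           report$gene_id), , drop = FALSE]
    rownames(report) <- NULL
  }
  write_tsv(report, path)
  invisible(report)
}

#' Plot positional statistics of a screen
#'
#' Draws the distance histogram (CON midpoint minus triplex midpoint) for
#' passing promoters.
#'
#' @param x A \code{triplex_screen}.
#' @param bin_width Histogram bin width in bp.
#' @param ... Further arguments passed to [graphics::barplot()].
#' @method plot triplex_screen
#' @export
plot.triplex_screen <- function(x, bin_width = 500, ...) {
  h <- distance_histogram(x, bin_width = bin_width)
  if (nrow(h) == 0L) {
    warning("no passing promoters to plot")
    return(invisible(NULL))
  }
  graphics::barplot(h$count,
                    names.arg = sprintf("%g", h$bin_start),
                    xlab = "CON - triplex distance (bp, bin start)",
                    ylab = "pairs", ...)
  invisible(h)
}
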