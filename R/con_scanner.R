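#' Parameters for the p53 consensus (CON) scan
#'
#' The p53 response element is two copies of the degenerate 10-mer
#' RRRCWWGYYY (R = A/G, W = A/T, Y = C/T) separated by a short spacer. The
#' defaults follow the stringent screen: at most 1 mismatch over the full
#' 20 bp site and an inter-half spacer below 21 bp. The classic definition
#' (spacer 0-13 bp) is reachable via \code{max_spacer = 13}.
#'
#' @param max_total_mismatches Maximum mismatches summed over both
#'   half-sites.
#' @param max_spacer Maximum spacer in bp between the end of the first
#'   half-site and the start of the second.
#' @param min_spacer Minimum spacer in bp.
#' @return A list of class \code{con_scan_params}.
#' @export
con_scan_params <- function(max_total_mismatches = 1, max_spacer = 20,
                            min_spacer = 0) {
  stopifnot(max_total_mismatches >= 0, min_spacer >= 0,
            min_spacer <= max_spacer)
  structure(list(max_total_mismatches = as.integer(max_total_mismatches),
                 max_spacer = as.integer(max_spacer),
                 min_spacer = as.integer(min_spacer)),
            class = "con_scan_params")
}

# position classes of RRRCWWGYYY; N conforms to no class
.halfsite_allowed <- list(
  c("A", "G"), c("A", "G"), c("A", "G"),
  "C",
  c("A", "T"), c("A", "T"),
  "G",
  c("C", "T"), c("C", "T"), c("C", "T"))

#' Mismatch count of a 10-mer against the RRRCWWGYYY half-site pattern
#'
#' Positions 1-3 must be purines, 4 a C, 5-6 A or T, 7 a G, 8-10
#' pyrimidines; every violated position counts one mismatch and all
#' positions weigh equally. \code{N} violates every class.
#'
#' @param window_10mer String of length exactly 10.
#' @return Integer mismatch count in 0..10.
#' @examples
#' half_site_mismatches("GGGCATGCCC")  # 0
#' half_site_mismatches("GGGCATGCCA")  # 1
#' @export
half_site_mismatches <- function(window_10mer) {
  if (nchar(window_10mer) != 10L) {
    stop("half-site window must be exactly 10 nt, got ", nchar(window_10mer))
  }
  chars <- strsplit(toupper(window_10mer), "", fixed = TRUE)[[1L]]
  sum(vapply(seq_len(10L),
             function(p) !(chars[p] %in% .halfsite_allowed[[p]]),
             logical(1L)))
}

# vectorized mismatch profile: mm[o] for the 10-mer starting at 0-based
# offset o-1; returns integer(0) for sequences shorter than 10
.halfsite_mm_profile <- function(chars) {
  n <- length(chars)
  if (n < 10L) return(integer(0L))
  pur <- chars == "A" | chars == "G"
  w <- chars == "A" | chars == "T"
  pyr <- chars == "C" | chars == "T"
  isc <- chars == "C"
  isg <- chars == "G"
  o <- seq_len(n - 9L)
  (!pur[o]) + (!pur[o + 1L]) + (!pur[o + 2L]) + (!isc[o + 3L]) +
    (!w[o + 4L]) + (!w[o + 5L]) + (!isg[o + 6L]) +
    (!pyr[o + 7L]) + (!pyr[o + 8L]) + (!pyr[o + 9L])
}

#' Scan a region for RRRCWWGYYY half-sites
#'
#' A single-strand scan suffices: the reverse complement of RRRCWWGYYY is
#' again RRRCWWGYYY, so every minus-strand site is found at the same locus
#' with the same mismatch count.
#'
#' @param region A [regulatory_region] or a plain sequence string.
#' @param max_mm Maximum mismatches per half-site.
#' @return Data frame with columns \code{offset} (0-based) and
#'   \code{mismatches}, in ascending offset order.
#' @export
scan_half_sites <- function(region, max_mm = 1) {
  stopifnot(max_mm >= 0)
  seq <- if (inherits(region, "regulatory_region")) region$sequence
         else toupper(region)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  mm <- .halfsite_mm_profile(chars)
  keep <- which(mm <= max_mm)
  data.frame(offset = keep - 1L, mismatches = mm[keep])
}

#' Pair half-site matches into CON sites
#'
#' Every ordered pair of half-sites whose spacer (end of the first 10-mer to
#' start of the second) lies in \code{[min_spacer, max_spacer]} and whose
#' summed mismatch count does not exceed the configured maximum becomes one
#' CON site. Overlapping half-sites (negative spacer) are excluded; a
#' half-site may participate in several CON sites, all of which are
#' reported.
#'
#' @param matches Data frame from [scan_half_sites()], sorted by offset.
#' @param params A [con_scan_params] object.
#' @return Data frame with one row per CON site: \code{first_offset,
#'   second_offset, spacer, mismatches, span_start, span_end} (0-based
#'   half-open span covering both half-sites).
#' @export
pair_half_sites <- function(matches, params = con_scan_params()) {
  empty <- data.frame(first_offset = integer(), second_offset = integer(),
                      spacer = integer(), mismatches = integer(),
                      span_start = integer(), span_end = integer())
  n <- nrow(matches)
  if (n < 2L) return(empty)
  stopifnot(!is.unsorted(matches$offset))
  rows <- empty
  for (i in seq_len(n - 1L)) {
    o1 <- matches$offset[i]
    js <- which(matches$offset >= o1 + 10L + params$min_spacer &
                matches$offset <= o1 + 10L + params$max_spacer)
    js <- js[js > i]
    for (j in js) {
      m <- matches$mismatches[i] + matches$mismatches[j]
      if (m <= params$max_total_mismatches) {
        o2 <- matches$offset[j]
        rows <- rbind(rows, data.frame(
          first_offset = o1, second_offset = o2,
          spacer = o2 - (o1 + 10L), mismatches = m,
          span_start = o1, span_end = o2 + 10L))
      }
    }
  }
  rows
}

#' Scan a region for full p53 CON sites
#'
#' Convenience wrapper: [scan_half_sites()] followed by
#' [pair_half_sites()]. Half-sites are pre-filtered at the full-site
#' mismatch budget, so no qualifying pair is lost.
#'
#' @inheritParams scan_half_sites
#' @param params A [con_scan_params] object.
#' @return Data frame as from [pair_half_sites()].
#' @export
scan_con <- function(region, params = con_scan_params()) {
  matches <- scan_half_sites(region, max_mm = params$max_total_mismatches)
  pair_half_sites(matches, params)
}
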