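# run expr with a fixed RNG seed without disturbing the caller's stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-promoter sub-seed fan-out, kept below 2^31 - 1
.sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + 7919 * as.numeric(i)) %%
               (2^31 - 1))
}

.draw_bases <- function(n, gc_content) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc_content) / 2, gc_content / 2,
                  gc_content / 2, (1 - gc_content) / 2))
}

# scan a character vector for the three kinds of background contamination;
# returns a list of 0-based half-open intervals (matrix cols: start, end)
.background_violations <- function(chars) {
  iv <- list()
  mm <- .halfsite_mm_profile(chars)
  hs <- which(mm <= 1L)
  for (o in hs) iv[[length(iv) + 1L]] <- c(o - 1L, o + 9L)
  for (cls in list(c("A", "G"), c("C", "T"))) {
    tr <- .find_tracts_one(chars %in% cls, 15L, 1L)
    for (t in seq_len(nrow(tr))) {
      iv[[length(iv) + 1L]] <- c(tr$start[t], tr$end[t])
    }
  }
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  long <- which(r$values %in% c("A", "T") & r$lengths >= 10L)
  for (k in long) iv[[length(iv) + 1L]] <- c(starts[k], ends[k])
  iv
}

#' Generate motif-free background promoter sequence
#'
#' Draws i.i.d. bases at the requested GC content, then locally redraws any
#' stretch that happens to contain a CON half-site with at most 1 mismatch,
#' a homopurine/homopyrimidine tract of 15+ nt (allowing one interruption),
#' or a poly(A)/poly(T) run of 10+ nt. These cleanliness bounds are
#' deliberately stricter than the scanners' reporting minima, so planted
#' features sit on a background guaranteed to contribute zero hits.
#'
#' @param length Sequence length in nt.
#' @param gc_content GC fraction, strictly between 0 and 1.
#' @param seed Integer seed (the draw is deterministic given the seed).
#' @param max_passes Redraw passes before giving up.
#' @return Sequence string.
#' @export
generate_background <- function(length, gc_content = 0.5, seed = NULL,
                                max_passes = 100) {
  stopifnot(length > 0)
  if (!(gc_content > 0 && gc_content < 1)) {
    stop("gc_content must lie strictly between 0 and 1")
  }
  .with_seed(seed, {
    chars <- .draw_bases(length, gc_content)
    for (pass in seq_len(max_passes)) {
      iv <- .background_violations(chars)
      if (length(iv) == 0L) break
      redo <- logical(length)
      for (x in iv) {
        lo <- max(x[1L] - 2L, 0L)
        hi <- min(x[2L] + 2L, length)
        redo[(lo + 1L):hi] <- TRUE
      }
      chars[redo] <- .draw_bases(sum(redo), gc_content)
      if (pass == max_passes) {
        stop("background not motif-free after ", max_passes,
             " redraw passes")
      }
    }
    paste(chars, collapse = "")
  })
}

# ---- planted feature construction ------------------------------------------

.perfect_half <- "GGGCATGCCC"

# a half-site with m controlled mismatches (pyrimidine tail -> A)
.half_with_mismatches <- function(m) {
  h <- strsplit(.perfect_half, "", fixed = TRUE)[[1L]]
  if (m >= 1L) h[10L] <- "A"
  if (m >= 2L) h[8L] <- "A"
  paste(h, collapse = "")
}

# mirror-symmetric purine tract of length n with G at mirrored interior
# positions; prevailing base is A but the longest A run stays well under n
.mirror_ag_tract <- function(n) {
  x <- rep("A", n)
  g <- max(2L, floor(n / 4))
  x[g] <- "G"
  x[n + 1L - g] <- "G"
  paste(x, collapse = "")
}

.mirror_ag_run <- function(n) {
  # longest A segment of the construction above, computable from arithmetic
  g <- max(2L, floor(n / 4))
  max(g - 1L, (n + 1L - g) - g - 1L)
}

#' Specify a synthetic promoter
#'
#' Features are planted by substitution (never insertion) into clean
#' background. Supported kinds: \code{con} (two RRRCWWGYYY half-sites with
#' controlled spacer and mismatch count), \code{tract} (poly(A), poly(T) or
#' a mirror A/G purine tract, shielded by two same-side guard bases of the
#' opposite class so it can neither extend its run nor its tract into the
#' background), and \code{decoy} (an alternating (AT)m repeat, which forms
#' neither a tract nor a long run).
#'
#' @param gene_id Unique gene identifier.
#' @param features List of feature descriptors, each a list with
#'   \code{kind} in \code{c("con", "tract", "decoy")}, \code{at} (0-based
#'   window offset) and kind-specific fields: \code{spacer}, \code{mismatches}
#'   for \code{con}; \code{base} (\code{"A"}, \code{"T"} or \code{"AG"}) and
#'   \code{length} for \code{tract}; \code{length} (total nt, even) for
#'   \code{decoy}.
#' @param window_length Window length in nt (default 7000, the
#'   -5000..+1999 convention).
#' @param gc_content Background GC fraction.
#' @param strand Strand on which the promoter is laid onto its synthetic
#'   chromosome.
#' @param seed Integer seed for the promoter's background.
#' @return List of class \code{promoter_spec}.
#' @export
promoter_spec <- function(gene_id, features = list(), window_length = 7000,
                          gc_content = 0.5, strand = "+", seed = NULL) {
  stopifnot(strand %in% c("+", "-"))
  structure(list(gene_id = gene_id, features = features,
                 window_length = as.integer(window_length),
                 gc_content = gc_content, strand = strand, seed = seed),
            class = "promoter_spec")
}

# feature footprint as 0-based half-open interval(s), guards included
.feature_span <- function(f) {
  if (f$kind == "con") {
    spacer <- if (is.null(f$spacer)) 3L else as.integer(f$spacer)
    c(f$at, f$at + 20L + spacer)
  } else if (f$kind == "tract") {
    c(f$at - 2L, f$at + f$length + 2L)
  } else {
    c(f$at - 1L, f$at + f$length + 1L)
  }
}

# returns list(seq_chars, mask) after substituting features into background
.apply_features <- function(chars, features) {
  n <- length(chars)
  mask <- logical(n)
  put <- function(at0, s) {
    v <- strsplit(s, "", fixed = TRUE)[[1L]]
    idx <- (at0 + 1L):(at0 + length(v))
    if (any(idx < 1L) || any(idx > n)) {
      stop("planted feature out of window bounds")
    }
    chars[idx] <<- v
    mask[idx] <<- TRUE
  }
  for (f in features) {
    if (f$kind == "con") {
      spacer <- if (is.null(f$spacer)) 3L else as.integer(f$spacer)
      mm <- if (is.null(f$mismatches)) 0L else as.integer(f$mismatches)
      put(f$at, .half_with_mismatches(0L))
      put(f$at + 10L + spacer, .half_with_mismatches(mm))
      # mask the spacer too so pairing geometry is stable
      if (spacer > 0L) mask[(f$at + 11L):(f$at + 10L + spacer)] <- TRUE
    } else if (f$kind == "tract") {
      base <- f$base
      guard <- if (base == "T") "GG" else "CC"
      body <- if (base == "AG") .mirror_ag_tract(f$length)
              else strrep(base, f$length)
      put(f$at - 2L, paste0(guard, body, guard))
    } else if (f$kind == "decoy") {
      body <- substr(strrep("AT", ceiling(f$length / 2)), 1L, f$length)
      put(f$at - 1L, paste0("C", body, "C"))
    } else {
      stop("unknown feature kind: ", f$kind)
    }
  }
  list(chars = chars, mask = mask)
}

#' Plant features into background and derive the truth row
#'
#' Substitutes the spec's features into the background, re-verifies the
#' unplanted sequence around every junction (redrawing locally until no
#' accidental half-site, long run, or background tract remains), and
#' computes the truth row from the spec parameters alone via the
#' closed-form filter arithmetic (a pure poly(A/T) or perfect-mirror tract
#' of length n folds to score \code{floor((n - loop_min)/2)}), never from
#' the scanner code.
#'
#' @param background Background sequence string (from
#'   [generate_background()]).
#' @param spec A [promoter_spec].
#' @param params [screen_params] whose thresholds define
#'   \code{expected_pass}.
#' @param max_passes Redraw passes for junction re-verification.
#' @return List with \code{sequence} (the planted window) and \code{truth}
#'   (one-row data frame).
#' @export
plant_features <- function(background, spec, params = screen_params(),
                           max_passes = 100) {
  chars <- strsplit(toupper(background), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  stopifnot(n == spec$window_length)
  spans <- lapply(spec$features, .feature_span)
  if (length(spans) > 1L) {
    ord <- order(vapply(spans, `[`, numeric(1L), 1L))
    for (k in seq_along(ord)[-1L]) {
      if (spans[[ord[k]]][1L] < spans[[ord[k - 1L]]][2L]) {
        stop("planted features overlap")
      }
    }
  }
  planted <- .apply_features(chars, spec$features)
  chars <- planted$chars
  mask <- planted$mask
  gc <- spec$gc_content
  for (pass in seq_len(max_passes + 1L)) {
    iv <- .background_violations(chars)
    redo <- logical(n)
    for (x in iv) {
      idx <- (x[1L] + 1L):x[2L]
      bg <- idx[!mask[idx]]
      width <- x[2L] - x[1L]
      problem <- if (width >= 15L) length(bg) >= 15L else length(bg) > 0L
      if (problem) redo[bg] <- TRUE
    }
    if (!any(redo)) break
    if (pass > max_passes) {
      stop("junction re-verification failed after ", max_passes, " passes")
    }
    chars[redo] <- .draw_bases(sum(redo), gc)
  }
  list(sequence = paste(chars, collapse = ""),
       truth = .truth_row(spec, params))
}

# truth flags from spec parameters alone (independent of the scanners)
.truth_row <- function(spec, params = screen_params()) {
  loop_min <- params$triplex$loop_min
  cons <- Filter(function(f) f$kind == "con", spec$features)
  n_con <- sum(vapply(cons, function(f) {
    mm <- if (is.null(f$mismatches)) 0L else f$mismatches
    sp <- if (is.null(f$spacer)) 3L else f$spacer
    mm <= params$con$max_total_mismatches &&
      sp >= params$con$min_spacer && sp <= params$con$max_spacer
  }, logical(1L)))
  tracts <- Filter(function(f) f$kind == "tract", spec$features)
  score <- 0L; run <- 0L; tract_desc <- "none"
  for (f in tracts) {
    s <- if (f$length >= loop_min + 2L) (f$length - loop_min) %/% 2L else 0L
    r <- if (f$base == "AG") .mirror_ag_run(f$length) else f$length
    if (s > score || (s == score && r > run)) {
      score <- s; run <- r
    }
    tract_desc <- paste0("(d", f$base, ")", f$length)
  }
  pass <- (n_con >= 1L || !params$require_con) &&
    score >= params$triplex$min_score && run >= params$min_AT_run
  data.frame(gene_id = spec$gene_id, planted_con = n_con,
             planted_tract = tract_desc, planted_score = score,
             planted_run = run, expected_pass = pass,
             stringsAsFactors = FALSE)
}

#' Build the standard synthetic promoter specification set
#'
#' \code{n_qualifying} promoters carry a perfect CON plus a 50 nt poly(A)
#' or poly(T) tract (the synthetic analogue of a (dA)50.(dT)50 insert);
#' the rest cycle through decoy classes: CON only, CON + (dA)20 (a tract
#' too short to fold past the score threshold), CON + (AT)34 (alternating,
#' no tract at all), a 50 nt tract without CON, CON + a 50 nt mirror A/G
#' tract (folds to a passing score but its longest A run stays short), and
#' pure background.
#'
#' @param n Total promoters.
#' @param n_qualifying How many must pass the joint screen.
#' @param seed Global seed; per-promoter seeds are derived as
#'   \code{(seed * 1009 + 7919 * i) mod (2^31 - 1)}.
#' @param window_length,gc_content Passed to each [promoter_spec].
#' @return List of [promoter_spec] objects.
#' @export
promoter_spec_set <- function(n = 100, n_qualifying = 7, seed = 1,
                              window_length = 7000, gc_content = 0.5) {
  stopifnot(n_qualifying <= n)
  specs <- vector("list", n)
  decoy_kinds <- c("con_only", "con_A20", "con_AT34", "tract_only",
                   "con_mirror50", "background")
  for (i in seq_len(n)) {
    strand <- if (i %% 3L == 0L) "-" else "+"
    tract_at <- 2400L + 37L * (i %% 8L)
    con_at <- 5050L + 41L * (i %% 9L)
    if (i <= n_qualifying) {
      base <- if (i %% 2L == 0L) "T" else "A"
      feats <- list(
        list(kind = "tract", at = tract_at, base = base, length = 50L),
        list(kind = "con", at = con_at, spacer = 3L, mismatches = 0L))
      kind <- "qualifying"
    } else {
      kind <- decoy_kinds[((i - n_qualifying - 1L) %% length(decoy_kinds)) + 1L]
      feats <- switch(kind,
        con_only = list(
          list(kind = "con", at = con_at, spacer = 3L, mismatches = 0L)),
        con_A20 = list(
          list(kind = "tract", at = tract_at, base = "A", length = 20L),
          list(kind = "con", at = con_at, spacer = 3L, mismatches = 0L)),
        con_AT34 = list(
          list(kind = "decoy", at = tract_at, length = 68L),
          list(kind = "con", at = con_at, spacer = 3L, mismatches = 0L)),
        tract_only = list(
          list(kind = "tract", at = tract_at, base = "A", length = 50L)),
        con_mirror50 = list(
          list(kind = "tract", at = tract_at, base = "AG", length = 50L),
          list(kind = "con", at = con_at, spacer = 3L, mismatches = 0L)),
        background = list())
    }
    specs[[i]] <- promoter_spec(
      gene_id = sprintf("G%03d_%s", i, kind), features = feats,
      window_length = window_length, gc_content = gc_content,
      strand = strand, seed = .sub_seed(seed, i))
  }
  specs
}

#' Generate a synthetic promoter set on disk
#'
#' Writes a FASTA file (one synthetic chromosome per promoter), a BED6 TSS
#' table and a truth TSV, laid out so that [read_fasta()],
#' [read_tss_table()] and [extract_windows()] recover each planted window
#' exactly: plus-strand promoters sit at TSS coordinate \code{upstream},
#' minus-strand promoters are stored reverse-complemented with the TSS at
#' coordinate \code{downstream - 1}.
#'
#' @param specs List of [promoter_spec] objects (unique gene ids).
#' @param out_prefix Path prefix; writes \code{<prefix>.fa},
#'   \code{<prefix>_tss.bed}, \code{<prefix>_truth.tsv}.
#' @param params [screen_params] defining the truth flags.
#' @param upstream,downstream Window convention (defaults 5000/2000; must
#'   sum to each spec's window length).
#' @return Invisible list with file paths and the truth data frame.
#' @export
generate_promoter_set <- function(specs, out_prefix,
                                  params = screen_params(),
                                  upstream = 5000, downstream = 2000) {
  ids <- vapply(specs, function(s) s$gene_id, character(1L))
  if (anyDuplicated(ids)) {
    stop("duplicate gene ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  fa <- paste0(out_prefix, ".fa")
  bed <- paste0(out_prefix, "_tss.bed")
  truth_path <- paste0(out_prefix, "_truth.tsv")
  fa_lines <- character(0L)
  bed_rows <- vector("list", length(specs))
  truth <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    stopifnot(s$window_length == upstream + downstream)
    bg <- generate_background(s$window_length, s$gc_content, seed = s$seed)
    pl <- plant_features(bg, s, params)
    truth[[i]] <- pl$truth
    chromname <- paste0("synthchr_", s$gene_id)
    if (s$strand == "+") {
      chromseq <- pl$sequence
      tss <- upstream
      bed_rows[[i]] <- data.frame(chrom = chromname, start = tss,
                                  end = tss + 1L, name = s$gene_id,
                                  score = 0L, strand = "+")
    } else {
      chromseq <- reverse_complement(pl$sequence)
      tss <- downstream - 1L
      # BED6 minus-strand TSS convention: tss == end - 1
      bed_rows[[i]] <- data.frame(chrom = chromname, start = tss,
                                  end = tss + 1L, name = s$gene_id,
                                  score = 0L, strand = "-")
    }
    fa_lines <- c(fa_lines, paste0(">", chromname),
                  substring(chromseq,
                            seq(1L, nchar(chromseq), 70L),
                            pmin(seq(1L, nchar(chromseq), 70L) + 69L,
                                 nchar(chromseq))))
  }
  writeLines(fa_lines, fa)
  write_bed(do.call(rbind, bed_rows), bed)
  truth <- do.call(rbind, truth)
  write_tsv(truth, truth_path)
  invisible(list(fasta = fa, tss_bed = bed, truth_tsv = truth_path,
                 truth = truth))
}

#' Simulate a noisy saturation binding curve
#'
#' Responses follow the hyperbolic (Hill coefficient 1) or Hill model at
#' the given dissociation constant plus i.i.d. Gaussian noise, drawn
#' independently per replicate and concentration. The default grid covers
#' the assay range 0.1-90 nM with 12 log-spaced points.
#'
#' @param kd Generating dissociation constant in nM.
#' @param bmax Generating maximal response.
#' @param hill_n Generating Hill coefficient (1 = hyperbolic).
#' @param grid Concentration grid in nM (strictly positive).
#' @param noise_sd Gaussian noise standard deviation in response units.
#' @param replicates Replicates per concentration.
#' @param seed Integer seed; the curve is deterministic given the seed.
#' @param probe Probe label carried on the returned curve.
#' @return A [binding_curve].
#' @examples
#' cv <- generate_binding_curve(kd = 0.75, noise_sd = 0, seed = 1)
#' fit_hyperbolic(cv)$Kd
#' @export
generate_binding_curve <- function(kd, bmax = 1, hill_n = 1, grid = NULL,
                                   noise_sd = 0.03, replicates = 3,
                                   seed = NULL, probe = "probe") {
  if (is.null(grid)) {
    grid <- exp(seq(log(0.1), log(90), length.out = 12))
  }
  stopifnot(kd > 0, bmax > 0, hill_n > 0, all(grid > 0), noise_sd >= 0,
            replicates >= 1)
  .with_seed(seed, {
    conc <- rep(grid, times = replicates)
    repl <- rep(seq_len(replicates), each = length(grid))
    mu <- bmax * conc^hill_n / (kd^hill_n + conc^hill_n)
    resp <- mu + stats::rnorm(length(mu), 0, noise_sd)
    binding_curve(conc, resp, replicate = repl, probe = probe)
  })
}
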