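#' Read a genome (or promoter set) from FASTA
#'
#' Reads a FASTA file into a named character vector of upper-case DNA
#' sequences. Only the alphabet \code{A,C,G,T,N} is accepted; anything else
#' (including RNA \code{U}) is an error naming the offending record and
#' position, so malformed inputs fail early rather than silently matching
#' nothing downstream.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record, sequences
#'   upper-cased.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTACGT", ">chr2", "ttttnnnn"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  # BStringSet (not DNAStringSet) so alphabet violations reach our own
  # diagnostics instead of a generic letter error
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  if (is.null(headers) || any(!nzchar(headers))) {
    stop("FASTA record with empty header in ", path)
  }
  headers <- sub("\\s.*$", "", headers)
  if (anyDuplicated(headers)) {
    stop("duplicate FASTA header(s): ",
         paste(unique(headers[duplicated(headers)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  widths <- nchar(seqs)
  if (any(widths == 0L)) {
    stop("empty FASTA record: ", headers[which(widths == 0L)[1L]])
  }
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal character '%s' at position %d of record '%s'",
                 substr(seqs[i], bad[i], bad[i]), bad[i], headers[i]))
  }
  names(seqs) <- headers
  seqs
}

#' Read a TSS table (BED6 or TSV)
#'
#' @param path Path to the table.
#' @param dialect \code{"bed6"}: standard 0-based half-open BED6; the TSS is
#'   the \code{start} position for + strand records and \code{end - 1} for
#'   \eqn{-} strand records. \code{"tsv"}: a headered table with columns
#'   \code{gene_id, transcript_id, chrom, tss, strand} where \code{tss} is the
#'   1-based coordinate of the TSS base.
#' @return \code{data.frame} with columns \code{gene_id}, \code{transcript_id},
#'   \code{chrom}, \code{tss} (0-based genomic position of the TSS base) and
#'   \code{strand}.
#' @export
read_tss_table <- function(path, dialect = c("bed6", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("TSS table not found: ", path)
  if (dialect == "bed6") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
    if (length(lines) == 0L) {
      return(data.frame(gene_id = character(), transcript_id = character(),
                        chrom = character(), tss = integer(),
                        strand = character(), stringsAsFactors = FALSE))
    }
    fields <- strsplit(lines, "[ \t]+")
    out <- vector("list", length(fields))
    for (i in seq_along(fields)) {
      f <- fields[[i]]
      if (length(f) < 6L) {
        stop(sprintf("malformed BED6 line %d: expected 6 fields, got %d",
                     i, length(f)))
      }
      start <- suppressWarnings(as.integer(f[2L]))
      end <- suppressWarnings(as.integer(f[3L]))
      if (is.na(start) || is.na(end) || start < 0L || end <= start) {
        stop(sprintf("malformed BED6 coordinates on line %d", i))
      }
      strand <- f[6L]
      if (!strand %in% c("+", "-")) {
        stop(sprintf("unknown strand symbol '%s' on line %d", strand, i))
      }
      ids <- strsplit(f[4L], "|", fixed = TRUE)[[1L]]
      out[[i]] <- data.frame(
        gene_id = ids[1L],
        transcript_id = if (length(ids) > 1L) ids[2L] else ids[1L],
        chrom = f[1L],
        tss = if (strand == "+") start else end - 1L,
        strand = strand, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "transcript_id", "chrom", "tss", "strand")
    if (!all(need %in% names(tab))) {
      stop("TSV TSS table must have columns: ", paste(need, collapse = ", "))
    }
    if (!all(tab$strand %in% c("+", "-"))) {
      stop("unknown strand symbol in TSS table: ",
           paste(setdiff(unique(tab$strand), c("+", "-")), collapse = ", "))
    }
    data.frame(gene_id = as.character(tab$gene_id),
               transcript_id = as.character(tab$transcript_id),
               chrom = as.character(tab$chrom),
               tss = as.integer(tab$tss) - 1L,  # 1-based in file
               strand = tab$strand, stringsAsFactors = FALSE)
  }
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Construct a regulatory region
#'
#' A TSS-anchored, strand-oriented promoter window. The sequence is stored in
#' transcription orientation; for a minus-strand gene it is the reverse
#' complement of the plus-strand genomic slice. \code{offset_of_tss} is the
#' 0-based index of the TSS base within \code{sequence} (\code{upstream} for
#' untruncated windows).
#'
#' @param gene_id,transcript_id Identifiers.
#' @param chrom Chromosome name.
#' @param window_start,window_end 0-based half-open genomic coordinates of the
#'   window on the + strand.
#' @param strand \code{"+"} or \code{"-"}.
#' @param tss 0-based genomic position of the TSS base.
#' @param sequence Oriented window sequence.
#' @param offset_of_tss 0-based index of the TSS base within \code{sequence}.
#' @param truncated Logical; whether the window was clipped at a chromosome
#'   end.
#' @return An object of class \code{regulatory_region}.
#' @export
regulatory_region <- function(gene_id, transcript_id = gene_id, chrom = "chr",
                              window_start, window_end, strand = "+",
                              tss, sequence, offset_of_tss,
                              truncated = FALSE) {
  stopifnot(window_start >= 0, window_end > window_start,
            strand %in% c("+", "-"),
            nchar(sequence) == window_end - window_start,
            offset_of_tss >= 0, offset_of_tss < nchar(sequence))
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, window_start = as.integer(window_start),
                 window_end = as.integer(window_end), strand = strand,
                 tss = as.integer(tss), sequence = toupper(sequence),
                 offset_of_tss = as.integer(offset_of_tss),
                 truncated = truncated),
            class = "regulatory_region")
}

#' @export
print.regulatory_region <- function(x, ...) {
  cat(sprintf("<regulatory_region> %s (%s) %s:%d-%d (%s), %d nt, TSS offset %d%s\n",
              x$gene_id, x$transcript_id, x$chrom, x$window_start,
              x$window_end, x$strand, nchar(x$sequence), x$offset_of_tss,
              if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

#' Extract TSS-anchored promoter windows
#'
#' Cuts a strand-oriented window covering relative positions
#' \code{[-upstream, +downstream)} around each TSS (the TSS base itself is
#' relative position 0 and counts as downstream). On the + strand this is the
#' genomic slice \code{[t - upstream, t + downstream)}; on the \eqn{-} strand
#' the genomic slice \code{[t - downstream + 1, t + upstream + 1)} is taken
#' and reverse-complemented. Windows running off a chromosome end are
#' truncated and flagged, with \code{offset_of_tss} adjusted.
#'
#' @param genome Named character vector as returned by [read_fasta()].
#' @param tss_table Data frame as returned by [read_tss_table()].
#' @param upstream,downstream Non-negative window half-lengths in bp
#'   (defaults 5000 and 2000 give the conventional 7 kb promoter window).
#' @return List of [regulatory_region] objects.
#' @export
extract_windows <- function(genome, tss_table, upstream = 5000,
                            downstream = 2000) {
  stopifnot(upstream >= 0, downstream >= 0, upstream + downstream > 0)
  out <- vector("list", nrow(tss_table))
  for (i in seq_len(nrow(tss_table))) {
    row <- tss_table[i, ]
    if (!row$chrom %in% names(genome)) {
      stop("chromosome not in genome: ", row$chrom)
    }
    chrlen <- nchar(genome[[row$chrom]])
    t <- row$tss
    if (t < 0L || t >= chrlen) {
      stop(sprintf("TSS %d of %s outside chromosome %s (length %d)",
                   t, row$gene_id, row$chrom, chrlen))
    }
    if (row$strand == "+") {
      gs <- t - upstream; ge <- t + downstream
    } else {
      gs <- t - downstream + 1L; ge <- t + upstream + 1L
    }
    cs <- max(gs, 0L); ce <- min(ge, chrlen)
    truncated <- (cs != gs) || (ce != ge)
    slice <- substr(genome[[row$chrom]], cs + 1L, ce)
    if (row$strand == "+") {
      seq <- slice
      off <- t - cs
    } else {
      seq <- reverse_complement(slice)
      off <- (ce - 1L) - t
    }
    out[[i]] <- regulatory_region(
      gene_id = row$gene_id, transcript_id = row$transcript_id,
      chrom = row$chrom, window_start = cs, window_end = ce,
      strand = row$strand, tss = t, sequence = seq,
      offset_of_tss = off, truncated = truncated)
  }
  out
}

#' Map a region offset back to a genomic (+ strand) position
#'
#' @param region A [regulatory_region].
#' @param offset 0-based offset(s) into the oriented sequence.
#' @return 0-based genomic position(s) on the + strand.
#' @export
region_to_genomic <- function(region, offset) {
  if (region$strand == "+") region$window_start + offset
  else (region$window_end - 1L) - offset
}

#' Write hits as BED6
#'
#' @param hits Data frame with columns \code{chrom, start, end, name, score,
#'   strand}; coordinates 0-based half-open genomic.
#' @param path Output path.
#' @export
write_bed <- function(hits, path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  stopifnot(all(cols %in% names(hits)))
  utils::write.table(hits[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a report table as headered TSV
#'
#' Human-facing reports use 1-based inclusive coordinates; the caller is
#' responsible for the conversion, this writer only guarantees the header
#' line and tab separation.
#'
#' @param report Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
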