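# Independent brute-force oracles, written as plain enumerations so they
# share no code path with the package implementation.

# mismatch count of a 10-mer against RRRCWWGYYY, position by position
oracle_halfsite_mm <- function(w) {
  classes <- list(c("A", "G"), c("A", "G"), c("A", "G"), "C",
                  c("A", "T"), c("A", "T"), "G",
                  c("C", "T"), c("C", "T"), c("C", "T"))
  ch <- strsplit(w, "", fixed = TRUE)[[1L]]
  mm <- 0L
  for (p in 1:10) if (!(ch[p] %in% classes[[p]])) mm <- mm + 1L
  mm
}

# every CON site by direct enumeration of all (offset1, offset2) pairs
oracle_con_sites <- function(seq, max_total_mm = 1, min_spacer = 0,
                             max_spacer = 20) {
  n <- nchar(seq)
  out <- list()
  if (n < 20L) return(data.frame(first_offset = integer(),
                                 second_offset = integer()))
  for (o1 in 0:(n - 20L)) {
    m1 <- oracle_halfsite_mm(substr(seq, o1 + 1L, o1 + 10L))
    if (m1 > max_total_mm) next
    for (o2 in (o1 + 10L):(n - 10L)) {
      s <- o2 - (o1 + 10L)
      if (s < min_spacer || s > max_spacer) next
      m2 <- oracle_halfsite_mm(substr(seq, o2 + 1L, o2 + 10L))
      if (m1 + m2 <= max_total_mm) {
        out[[length(out) + 1L]] <- c(o1, o2)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(first_offset = integer(), second_offset = integer()))
  }
  m <- do.call(rbind, out)
  data.frame(first_offset = m[, 1L], second_offset = m[, 2L])
}

# best fold score by exhaustive enumeration over every innermost pair,
# loop length and stem length; returns -Inf when no fold exists
oracle_best_fold_score <- function(tract, w = 1, p_mm = -2, loop_min = 4,
                                   loop_max = 12) {
  x <- strsplit(toupper(tract), "", fixed = TRUE)[[1L]]
  n <- length(x)
  best <- -Inf
  for (i in seq_len(n)) {
    for (loop_len in loop_min:loop_max) {
      j <- i + loop_len + 1L
      if (j > n) next
      for (k in 1:min(i, n - j + 1L)) {
        s <- 0
        for (d in 0:(k - 1L)) {
          a <- x[i - d]; b <- x[j + d]
          if (a == b && a %in% c("A", "G")) s <- s + w else s <- s + p_mm
        }
        if (s > best) best <- s
      }
    }
  }
  best
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# wrap a bare sequence into a full-window regulatory region for screening
region_from_sequence <- function(seq, gene_id = "G1", offset_of_tss = 5000) {
  regulatory_region(gene_id = gene_id, chrom = "chr1", window_start = 0,
                    window_end = nchar(seq), strand = "+", tss = offset_of_tss,
                    sequence = seq, offset_of_tss = offset_of_tss)
}
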