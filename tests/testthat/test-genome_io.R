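test_that("FASTA reading enforces alphabet, case and header contracts", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGTACGT", ">chr2 some description", "ttttnnnn"), fa)
  g <- read_fasta(fa)
  expect_named(g, c("chr1", "chr2"))
  expect_equal(unname(nchar(g)), c(8L, 8L))
  expect_equal(unname(g["chr2"]), "TTTTNNNN")  # upper-cased

  writeLines(c(">rna", "ACGu"), fa)
  expect_error(read_fasta(fa), "rna")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), fa)
  expect_error(read_fasta(fa), "duplicate")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("TSS tables follow the BED6 and 1-based TSV conventions", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tG1\t0\t+",
               "chr1\t100\t200\tG2|T2\t0\t-"), bed)
  tab <- read_tss_table(bed, "bed6")
  expect_equal(tab$tss, c(100L, 199L))
  expect_equal(tab$gene_id, c("G1", "G2"))
  expect_equal(tab$transcript_id, c("G1", "T2"))

  writeLines("chr1\t100\t200\tG1\t0\t.", bed)
  expect_error(read_tss_table(bed, "bed6"), "strand")
  writeLines("chr1\t100", bed)
  expect_error(read_tss_table(bed, "bed6"), "line 1")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ttranscript_id\tchrom\ttss\tstrand",
               "G1\tT1\tchr1\t101\t+"), tsv)
  expect_equal(read_tss_table(tsv, "tsv")$tss, 100L)  # 1-based column
})

test_that("window extraction follows the [-upstream, +downstream) convention", {
  set.seed(7)
  chr <- random_dna(20000)
  genome <- c(chr1 = chr)
  tss <- data.frame(gene_id = "G1", transcript_id = "G1", chrom = "chr1",
                    tss = 10000L, strand = "+", stringsAsFactors = FALSE)
  r <- extract_windows(genome, tss)[[1]]
  expect_equal(c(r$window_start, r$window_end), c(5000L, 12000L))
  expect_equal(nchar(r$sequence), 7000L)
  expect_equal(r$offset_of_tss, 5000L)
  expect_false(r$truncated)
  expect_equal(r$sequence, substr(chr, 5001, 12000))
  # the TSS base is relative position 0 (counts as downstream)
  expect_equal(substr(r$sequence, 5001, 5001), substr(chr, 10001, 10001))

  tss$strand <- "-"
  rm <- extract_windows(genome, tss)[[1]]
  expect_equal(c(rm$window_start, rm$window_end), c(8001L, 15001L))
  expect_equal(rm$sequence, revcomp_chr(substr(chr, 8002, 15001)))
  expect_equal(rm$offset_of_tss, 5000L)

  tss$strand <- "+"; tss$tss <- 100L
  rt <- extract_windows(genome, tss)[[1]]
  expect_equal(c(rt$window_start, rt$window_end), c(0L, 2100L))
  expect_true(rt$truncated)
  expect_equal(rt$offset_of_tss, 100L)

  tss$tss <- 30000L
  expect_error(extract_windows(genome, tss), "outside")
})

test_that("window offsets round-trip to genomic coordinates on both strands", {
  set.seed(11)
  genome <- c(chrA = random_dna(12000))
  for (strand in c("+", "-")) {
    for (t in c(5000L, 6000L, 9500L)) {
      tss <- data.frame(gene_id = "g", transcript_id = "g", chrom = "chrA",
                        tss = t, strand = strand, stringsAsFactors = FALSE)
      r <- extract_windows(genome, tss, upstream = 4000,
                           downstream = 1500)[[1]]
      expect_equal(region_to_genomic(r, r$offset_of_tss), t)
      # every offset maps inside the window
      offs <- c(0L, 100L, nchar(r$sequence) - 1L)
      g <- region_to_genomic(r, offs)
      expect_true(all(g >= r$window_start & g < r$window_end))
    }
  }
})

test_that("reverse-complementing the genome and flipping strands is a no-op", {
  set.seed(13)
  L <- 9000L
  chr <- random_dna(L)
  for (t in c(4000L, 5200L)) {
    fwd <- extract_windows(c(c1 = chr),
                           data.frame(gene_id = "g", transcript_id = "g",
                                      chrom = "c1", tss = t, strand = "+",
                                      stringsAsFactors = FALSE),
                           upstream = 3000, downstream = 1000)[[1]]
    flp <- extract_windows(c(c1 = revcomp_chr(chr)),
                           data.frame(gene_id = "g", transcript_id = "g",
                                      chrom = "c1", tss = L - 1L - t,
                                      strand = "-", stringsAsFactors = FALSE),
                           upstream = 3000, downstream = 1000)[[1]]
    expect_equal(flp$sequence, fwd$sequence)
    expect_equal(flp$offset_of_tss, fwd$offset_of_tss)
  }
})

test_that("BED output round-trips bit-exactly and empty outputs are valid", {
  hits <- data.frame(chrom = c("chr1", "chr2"), start = c(5000L, 0L),
                     end = c(5020L, 55L), name = c("a", "b"),
                     score = c(23L, 18L), strand = c("+", "-"),
                     stringsAsFactors = FALSE)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(hits, bed)
  back <- utils::read.table(bed, sep = "\t", stringsAsFactors = FALSE,
                            col.names = names(hits))
  expect_equal(back, hits)

  write_bed(hits[0, ], bed)
  expect_length(readLines(bed), 0L)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(hits[0, ], tsv)
  expect_equal(readLines(tsv)[1],
               paste(names(hits), collapse = "\t"))  # header survives
})
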