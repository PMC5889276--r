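test_that("read_fasta handles FASTA, case, whitespace and multi-record files", {
  f <- withr::local_tempfile(lines = c(">g", "acgt", "ACGT"))
  recs <- read_fasta(f)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$id, "g")
  expect_equal(recs[[1]]$seq, "ACGTACGT")
  expect_equal(recs[[1]]$length, 8L)

  f2 <- withr::local_tempfile(lines = c(">a desc here", "ACGT", ">b", "GG", "TT"))
  recs2 <- read_fasta(f2)
  expect_equal(vapply(recs2, `[[`, "", "id"), c("a", "b"))
  expect_equal(recs2[[2]]$seq, "GGTT")
})

test_that("read_fasta accepts the headerless bare-text dialect", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("  1 GATC", "  5 GATC"), f)   # line numbers + whitespace
  on.exit(unlink(f))
  recs <- read_fasta(f)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$seq, "GATCGATC")
  expect_equal(recs[[1]]$id, sub("\\.txt$", "", basename(f)))
})

test_that("read_fasta and genome_record reject bad input with useful errors", {
  f <- withr::local_tempfile(lines = character(0))
  expect_error(read_fasta(f), "no sequence")
  f2 <- withr::local_tempfile(lines = c(">x", "ACGZGT"))
  expect_error(read_fasta(f2), "offset 4")
  expect_error(read_fasta(tempfile()), "not found")
  expect_warning(g <- genome_record("ACGU"), "U")
  expect_equal(g$seq, "ACGT")
})

test_that("reverse_complement is IUPAC-aware and an involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  # hand-derived: complement C Y C G R G -> G R G C Y C, reversed -> CYCGRG
  expect_equal(reverse_complement("CYCGRG"), "CYCGRG")
  # hand-derived non-palindrome
  expect_equal(reverse_complement("CCCAGC"), "GCTGGG")
  expect_error(reverse_complement("ACXGT"), "offset")

  set.seed(42)
  letters15 <- c("A","C","G","T","R","Y","S","W","K","M","B","D","H","V","N")
  for (i in 1:25) {
    s <- paste(sample(letters15, sample(5:40, 1), replace = TRUE), collapse = "")
    expect_equal(reverse_complement(reverse_complement(s)), s)
    expect_equal(reverse_complement(s), oracle_rc(s))
  }
})

test_that("FASTA writing round-trips the sequence exactly", {
  g <- genome_record(random_seq(1234, seed = 9), id = "round")
  f <- withr::local_tempfile()
  write_fasta(g, f)
  back <- read_fasta(f)[[1]]
  expect_equal(back$seq, g$seq)
  expect_equal(back$id, "round")
})

test_that("write_gff3 emits valid, deterministically ordered GFF3", {
  g <- genome_record(random_seq(700, seed = 1), id = "gtest")
  cds <- data.frame(label = c("a", "b"), start = c(13L, 100L),
                    end = c(600L, 220L), strand = "+")
  prom <- data.frame(pos35 = 100L, pos10 = 122L, spacer = 16L, mm35 = 0L,
                     mm10 = 1L, mm_total = 1L, strand = "+",
                     box35 = "TTGACA", box10 = "TATAAT")
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(g, list(cds, prom), f)
  lines <- readLines(f)
  expect_equal(lines[1], "##gff-version 3")
  body <- lines[!startsWith(lines, "#")]
  fields <- strsplit(body, "\t")
  expect_true(all(lengths(fields) == 9L))
  starts <- as.integer(vapply(fields, `[`, "", 4L))
  expect_equal(starts, sort(starts))
  # tie at start 100: CDS ranks before promoter
  types_at_100 <- vapply(fields[starts == 100L], `[`, "", 3L)
  expect_equal(types_at_100, c("CDS", "promoter"))
  # strict re-parse with rtracklayer: no warnings, coordinates intact
  gr <- rtracklayer::import(f)
  expect_equal(sort(BiocGenerics::start(gr)), sort(c(13L, 100L, 100L)))
  expect_equal(sort(BiocGenerics::end(gr)), sort(c(600L, 220L, 127L)))
})

test_that("write_gff3 rejects out-of-range features and handles empty input", {
  g <- genome_record("ACGTACGTAC", id = "tiny")
  f <- withr::local_tempfile()
  expect_error(write_gff3(g, data.frame(label = "bad", start = 2L, end = 99L,
                                        strand = "+"), f),
               "out of range")
  write_gff3(g, list(), f)
  expect_true(all(startsWith(readLines(f), "#")))
})

test_that("read_genbank extracts the ORIGIN sequence and CDS intervals", {
  gbk <- c(
    "LOCUS       TESTREC                 24 bp    DNA     linear   PHG",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..9",
    "                     /product=\"demo\"",
    "     CDS             complement(10..18)",
    "ORIGIN",
    "        1 atggcttaat tagccattaa gatc",
    "//")
  f <- withr::local_tempfile(lines = gbk)
  rec <- read_genbank(f)
  expect_equal(rec$genome$id, "TESTREC")
  expect_equal(rec$genome$length, 24L)
  expect_equal(rec$cds$start, c(1L, 10L))
  expect_equal(rec$cds$strand, c("+", "-"))
})

test_that("subseq1 respects bounds and strand", {
  g <- genome_record("AATGCCGT")
  expect_equal(subseq1(g, 2, 4), "ATG")
  expect_equal(subseq1(g, 2, 4, "-"), "CAT")
  expect_error(subseq1(g, 0, 4), "out of range")
  expect_error(subseq1(g, 5, 9), "out of range")
})
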