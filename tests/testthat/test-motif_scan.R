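test_that("IUPAC matcher counts mismatches under degeneracy", {
  expect_equal(iupac_mismatches("CYCGRG", "CTCGAG"), 0L)
  expect_equal(iupac_mismatches("GATC", "GATG"), 1L)
  for (w in c("ACGT", "GGGG", "TTAA"))
    expect_equal(iupac_mismatches("NNNN", w), 0L)
  # conservative counting: an ambiguous genome letter matches nothing
  expect_equal(iupac_mismatches("NNNN", "ACNT"), 1L)
  expect_equal(iupac_mismatches("NNNN", "ACNT", permissive_ambiguity = TRUE), 0L)
  expect_error(compile_iupac("ACXT"), "offset")
})

test_that("scan_pattern reports every in-budget window on both strands", {
  hits <- scan_pattern("GATCGATC", "GATC", strands = "forward")
  expect_equal(hits$position, c(1L, 5L))
  # overlapping hits are all reported
  expect_equal(scan_pattern("AAAA", "AA", strands = "forward")$position, 1:3)
  # palindromic pattern: forward and reverse position sets coincide
  s <- random_seq(800, seed = 31)
  both <- scan_pattern(s, "GATC", strands = "both")
  expect_equal(both$position[both$strand == "+"],
               both$position[both$strand == "-"])
})

test_that("scan_pattern agrees with the all-windows oracle", {
  cases <- expand.grid(seed = 1:5, pattern = c("CYCGRG", "GATC", "RGWYCNR"),
                       mm = 0:1, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    s <- random_seq(400, seed = cases$seed[i])
    got <- scan_pattern(s, cases$pattern[i], cases$mm[i])
    want <- oracle_scan(s, cases$pattern[i], cases$mm[i])
    expect_equal(nrow(got), nrow(want),
                 info = sprintf("seed %d pattern %s mm %d", cases$seed[i],
                                cases$pattern[i], cases$mm[i]))
    expect_equal(got$position, want$position)
    expect_equal(got$strand, want$strand)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("count_recognition_sites counts distinct genomic site positions", {
  expect_true(is_iupac_palindrome("GATC"))
  expect_true(is_iupac_palindrome("CYCGRG"))
  expect_false(is_iupac_palindrome("CCCAGC"))
  expect_equal(count_recognition_sites("CCCAGCTT", "CCCAGC"), 1L)
  expect_equal(count_recognition_sites("AAGCTGGG", "CCCAGC"), 1L)
  # invariance under reverse complement of the genome
  for (seed in 1:5) {
    s <- random_seq(600, seed = seed)
    for (p in c("GATC", "CCCAGC", "CYCGRG", "CGATCG"))
      expect_equal(count_recognition_sites(s, p),
                   count_recognition_sites(reverse_complement(s), p),
                   info = sprintf("seed %d pattern %s", seed, p))
  }
})

test_that("the built-in registry and TSV registries load", {
  reg <- restriction_patterns()
  expect_equal(unname(reg["Gst1588I"]), "CYCGRG")
  expect_equal(unname(reg["Gst1588II"]), "GATC")
  f <- withr::local_tempfile(lines = c("name\tpattern", "MyEnz\tGGCgCC"))
  expect_equal(read_patterns(f), c(MyEnz = "GGCGCC"))
  f2 <- withr::local_tempfile(lines = c("a\tb", "x\ty"))
  expect_error(read_patterns(f2), "name")
})

test_that("find_promoters finds a planted perfect site exactly once", {
  s <- paste0(strrep("A", 60), "TTGACA", strrep("C", 16), "TATAAT",
              strrep("A", 60))
  hits <- find_promoters(s)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$pos35, 61L)
  expect_equal(hits$spacer, 16L)
  expect_equal(hits$mm_total, 0L)
  expect_equal(hits$pos10, hits$pos35 + 6L + hits$spacer)
})

test_that("find_promoters agrees with exhaustive enumeration", {
  for (seed in c(11, 1:4)) {
    s <- random_seq(2000, seed = seed, gc = 0.4)
    got <- find_promoters(s)
    want <- oracle_promoters(s)
    expect_equal(got$pos35, want$pos35, info = paste("seed", seed))
    expect_equal(got$pos10, want$pos10)
    expect_equal(got$mm_total, want$mm_total)
    expect_equal(got$spacer, want$spacer)
  }
})

test_that("promoter hits grow monotonically with budget and spacer range", {
  for (seed in 1:5) {
    s <- random_seq(1500, seed = seed, gc = 0.45)
    base <- find_promoters(s)
    wider_budget <- find_promoters(s, max_total_mismatch = 3L)
    wider_spacer <- find_promoters(s, spacer_range = c(14L, 19L))
    expect_true(all(base$pos10 %in% wider_budget$pos10))
    expect_true(all(base$pos10 %in% wider_spacer$pos10))
  }
})

test_that("both-strand promoter scanning mirrors correctly", {
  s <- paste0(strrep("G", 30), "TTGACA", strrep("C", 15), "TATAAT",
              strrep("G", 30))
  rc <- reverse_complement(s)
  fwd <- find_promoters(s, strand = "both")
  rev <- find_promoters(rc, strand = "both")
  minus <- rev[rev$strand == "-", ]
  expect_equal(nrow(minus), nrow(fwd[fwd$strand == "+", ]))
  n <- nchar(s)
  expect_equal(sort(n - (minus$pos10 + 5L) + 1L),
               sort(fwd$pos10[fwd$strand == "+"]))
})
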