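test_that("find_hairpins finds a planted perfect inverted repeat", {
  s <- paste0("GGGCGC", "AAAA", "GCGCCC")
  hp0 <- find_hairpins(s, max_mismatch_in_stem = 0L)
  expect_equal(nrow(hp0), 1L)
  expect_equal(hp0$stem_len, 6L)
  expect_equal(hp0$loop_len, 4L)
  expect_equal(hp0$start, 1L)
  expect_equal(hp0$end, 16L)
  # with the default 1-mismatch budget, shifted registers appear too, but
  # the planted register is always among them
  hp1 <- find_hairpins(s)
  expect_true(any(hp1$stem_len == 6L & hp1$loop_len == 4L))
  expect_equal(nrow(find_hairpins(strrep("A", 200))), 0L)
})

test_that("find_hairpins matches the brute-force enumerator", {
  for (seed in c(5, 1:4)) {
    s <- random_seq(800, seed = seed, gc = 0.5)
    got <- find_hairpins(s)
    want <- oracle_hairpins(s)
    expect_equal(paste(got$start, got$end, got$loop_len),
                 paste(want$start, want$end, want$loop_len),
                 info = paste("seed", seed))
    expect_equal(got$stem_len, want$stem_len)
    expect_equal(got$n_mismatch, want$n_mismatch)
  }
})

test_that("stem_dg reproduces hand-added published stack terms", {
  # 3-bp helix GCG: stacks 5'GC3'/3'CG5' (-3.42) + 5'CG3'/3'GC5' (-2.36)
  expect_equal(stem_dg("GCG"), -5.78, tolerance = 1e-9)
  # reverse-complement symmetry of the stack table
  expect_equal(stem_dg("AAT"), stem_dg("ATT"))
})

test_that("score_terminator applies energy and U-tract filters", {
  stem <- "GGGGCCGC"   # not its own reverse complement
  hairpin_seq <- paste0(stem, "ATAA", reverse_complement(stem))
  # C flanks cannot pair with the T tail, so the planted register is maximal
  ok <- paste0(strrep("C", 10), hairpin_seq, strrep("T", 8), strrep("C", 10))
  hp <- find_hairpins(ok)
  hp <- hp[which.max(hp$stem_len), ]
  expect_equal(hp$stem_len, 8L)
  cand <- score_terminator(ok, hp)
  expect_true(is.data.frame(cand))
  expect_equal(cand$u_score, 1.0)
  expect_lt(cand$dg_stem, -8)

  bad_tail <- paste0(strrep("C", 10), hairpin_seq, strrep("G", 8),
                     strrep("A", 10))
  hpb <- find_hairpins(bad_tail)
  hpb <- hpb[which.max(hpb$stem_len), ]
  expect_equal(score_terminator(bad_tail, hpb)$reject, "no U-tract")

  # hairpin at the genome end: tail window truncated
  trunc <- paste0(strrep("C", 10), hairpin_seq)
  hpt <- find_hairpins(trunc)
  hpt <- hpt[which.max(hpt$stem_len), ]
  expect_equal(score_terminator(trunc, hpt)$reject, "truncated tail")

  # weak stem: AT-only arms never reach -8 kcal/mol
  weak <- paste0(strrep("C", 10), "ATATAT", "GCCA",
                 reverse_complement("ATATAT"), strrep("T", 8),
                 strrep("C", 10))
  hpw <- find_hairpins(weak)
  hpw <- hpw[which.max(hpw$stem_len), ]
  expect_equal(score_terminator(weak, hpw)$reject, "weak stem")
})

test_that("tightening any threshold never adds candidates", {
  sim <- generate_genome(synthetic_spec(length = 6000, n_cds = 4,
                                        n_promoters = 0, n_terminators = 4,
                                        sites = integer(0), seed = 23))
  g <- sim$genome
  base <- find_terminators(g)
  # tightening a threshold can shift the chosen register of a surviving
  # locus, but it can never create a new locus or increase the count
  overlaps_some <- function(x, ref) {
    vapply(seq_len(nrow(x)), function(i)
      any(x$hairpin_start[i] <= ref$hairpin_end &
          x$hairpin_end[i] >= ref$hairpin_start), logical(1L))
  }
  for (strict in list(find_terminators(g, dg_threshold = -12),
                      find_terminators(g, u_min = 0.75),
                      find_terminators(g, stem_range = c(6L, 30L)))) {
    expect_lte(nrow(strict), nrow(base))
    if (nrow(strict) > 0L)
      expect_true(all(overlaps_some(strict, base)))
  }
  stricter <- find_terminators(g, stem_range = c(6L, 30L))
  expect_true(all(stricter$stem_len >= 6L))
})

test_that("detection is strand-consistent under reverse complement", {
  sim <- generate_genome(synthetic_spec(length = 5000, n_cds = 3,
                                        n_promoters = 0, n_terminators = 3,
                                        sites = integer(0), seed = 29))
  g <- sim$genome
  fwd <- find_terminators(g, strand = "both")
  rev <- find_terminators(reverse_complement(g$seq), strand = "both")
  n <- g$length
  mirrored <- sort(paste(n - rev$hairpin_end + 1L, n - rev$hairpin_start + 1L))
  expect_equal(sort(paste(fwd$hairpin_start, fwd$hairpin_end)), mirrored)
})

test_that("overlapping survivors collapse to the most stable candidate", {
  sim <- generate_genome(synthetic_spec(length = 5000, n_cds = 3,
                                        n_promoters = 0, n_terminators = 3,
                                        sites = integer(0), seed = 31))
  cand <- find_terminators(sim$genome)
  if (nrow(cand) > 1L) {
    for (i in 2:nrow(cand))
      expect_true(cand$hairpin_start[i] > cand$hairpin_end[i - 1L] ||
                  cand$hairpin_end[i] < cand$hairpin_start[i - 1L])
  }
  expect_true(all(cand$dg_stem <= -8))
  expect_true(all(cand$u_score >= 0.5))
})
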