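small_spec <- function(seed, ...) {
  synthetic_spec(length = 6000, n_cds = 5, n_promoters = 3, n_terminators = 2,
                 sites = c(CGATCG = 2L), seed = seed, ...)
}

test_that("the generator is deterministic per seed", {
  a <- generate_genome(small_spec(3))
  b <- generate_genome(small_spec(3))
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(a$truth$cds, b$truth$cds)
  expect_identical(a$truth$promoters, b$truth$promoters)
  c <- generate_genome(small_spec(4))
  expect_false(identical(a$genome$seq, c$genome$seq))
})

test_that("every planted feature is literally present at its coordinates", {
  sim <- generate_genome(small_spec(12))
  s <- sim$genome$seq
  t <- sim$truth
  for (i in seq_len(nrow(t$cds))) {
    cds <- substr(s, t$cds$start[i], t$cds$end[i])
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in%
                c("TAA", "TAG", "TGA"))
  }
  for (i in seq_len(nrow(t$promoters))) {
    p <- t$promoters[i, ]
    mm <- iupac_mismatches("TTGACA", substr(s, p$pos35, p$pos35 + 5)) +
          iupac_mismatches("TATAAT", substr(s, p$pos10, p$pos10 + 5))
    expect_equal(mm, p$mm_total)
  }
  for (i in seq_len(nrow(t$terminators))) {
    tr <- t$terminators[i, ]
    arm1 <- substr(s, tr$hairpin_start, tr$hairpin_start + tr$stem_len - 1)
    arm2 <- substr(s, tr$hairpin_end - tr$stem_len + 1, tr$hairpin_end)
    expect_equal(reverse_complement(arm1), arm2)
    expect_equal(substr(s, tr$hairpin_end + 1, tr$end), strrep("T", 8))
  }
  for (i in seq_len(nrow(t$sites))) {
    win <- substr(s, t$sites$position[i],
                  t$sites$position[i] + nchar(t$sites$pattern[i]) - 1)
    expect_equal(iupac_mismatches(t$sites$pattern[i], win), 0L)
  }
})

test_that("a TP-84-scale genome hits its target GC within 0.01", {
  sim <- generate_genome(synthetic_spec(length = 47703, target_gc = 0.545,
                                        seed = 1))
  expect_equal(sim$genome$length, 47703L)
  expect_equal(global_gc(sim$genome), 0.545, tolerance = 0.01)
})

test_that("planted promoters are recovered with matching mismatch counts", {
  spec <- synthetic_spec(length = 8000, n_cds = 4, n_promoters = 5,
                         promoter_mismatches = c(0L, 1L, 1L, 2L, 2L),
                         n_terminators = 0, sites = integer(0), seed = 19)
  sim <- generate_genome(spec)
  hits <- find_promoters(sim$genome)
  t <- sim$truth$promoters
  for (i in seq_len(nrow(t))) {
    h <- hits[hits$pos10 == t$pos10[i], ]
    expect_equal(nrow(h), 1L)
    expect_equal(h$mm_total, t$mm_total[i])
  }
})

test_that("an unsatisfiable spec errors instead of silently truncating", {
  expect_error(generate_genome(synthetic_spec(length = 3000, n_cds = 20,
                                              cds_length_range = c(600, 900),
                                              seed = 1)),
               "unsatisfiable")
})

test_that("mixed strand mode plants on both strands and stays recoverable", {
  spec <- synthetic_spec(length = 14000, n_cds = 12,
                         strand_mode = "mixed", n_promoters = 0,
                         n_terminators = 0, sites = integer(0), seed = 21)
  sim <- generate_genome(spec)
  expect_setequal(unique(sim$truth$cds$strand), c("+", "-"))
  o <- find_orfs(sim$genome)
  expect_equal(paste(o$start, o$end, o$strand),
               paste(sim$truth$cds$start, sim$truth$cds$end,
                     sim$truth$cds$strand))
})

test_that("recovery_report computes sensitivity, precision and mm matches", {
  sim <- generate_genome(small_spec(14))
  outputs <- list(
    cds = find_orfs(sim$genome),
    promoters = find_promoters(sim$genome),
    terminators = find_terminators(sim$genome),
    sites = scan_pattern(sim$genome, "CGATCG", pattern_name = "CGATCG"))
  rep <- recovery_report(outputs, sim$truth, sim$genome)
  expect_setequal(rep$class, c("cds", "promoters", "terminators", "sites"))
  expect_equal(rep$sensitivity[rep$class == "cds"], 1.0)
  expect_equal(rep$precision[rep$class == "cds"], 1.0)
  expect_equal(rep$sensitivity[rep$class == "promoters"], 1.0)
  expect_equal(rep$n_exact_mm[rep$class == "promoters"],
               nrow(sim$truth$promoters))
  expect_equal(rep$sensitivity[rep$class == "sites"], 1.0)
  expect_equal(rep$precision[rep$class == "sites"], 1.0)

  # dropping one truth CDS from the outputs lowers sensitivity to (n-1)/n
  o2 <- outputs
  drop <- which(paste(o2$cds$start, o2$cds$end) ==
                paste(sim$truth$cds$start[1], sim$truth$cds$end[1]))
  o2$cds <- o2$cds[-drop, ]
  rep2 <- recovery_report(o2, sim$truth, sim$genome)
  n <- nrow(sim$truth$cds)
  expect_equal(rep2$sensitivity[rep2$class == "cds"], (n - 1) / n)
})

test_that("recovery_report rejects outputs from a different genome", {
  sim1 <- generate_genome(small_spec(1))
  sim2 <- generate_genome(small_spec(2))
  out <- list(cds = find_orfs(sim2$genome))
  expect_error(recovery_report(out, sim1$truth), "ledger")
})

test_that("ground-truth ledgers serialize to disk", {
  sim <- generate_genome(small_spec(5))
  d <- withr::local_tempdir()
  write_ground_truth(sim$truth, d)
  expect_true(all(file.exists(file.path(d, c("cds.tsv", "promoters.tsv",
                                             "terminators.tsv", "sites.tsv",
                                             "spec.json")))))
  back <- utils::read.delim(file.path(d, "cds.tsv"))
  expect_equal(back$start, sim$truth$cds$start)
})
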