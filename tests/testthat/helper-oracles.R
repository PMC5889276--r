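# Brute-force oracles, written independently of the package's vectorized
# implementations: explicit loops, substring arithmetic, and (where
# available) Biostrings as an external reference.

random_seq <- function(n, seed, gc = 0.5) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Independent IUPAC letter -> base set table.
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

oracle_mismatches <- function(pattern, window) {
  p <- strsplit(pattern, "")[[1]]
  w <- strsplit(window, "")[[1]]
  mm <- 0L
  for (i in seq_along(p)) {
    ok <- w[i] %in% c("A", "C", "G", "T") && w[i] %in% ORACLE_IUPAC[[p[i]]]
    if (!ok) mm <- mm + 1L
  }
  mm
}

oracle_rc <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# All-windows degenerate scan; forward coordinates for both strands.
oracle_scan <- function(seq, pattern, max_mm = 0L, strands = "both") {
  n <- nchar(seq)
  k <- nchar(pattern)
  hits <- list()
  pats <- list()
  if (strands %in% c("both", "forward")) pats[["+"]] <- pattern
  if (strands %in% c("both", "reverse")) pats[["-"]] <- oracle_rc(pattern)
  for (str in names(pats)) {
    for (pos in seq_len(n - k + 1)) {
      mm <- oracle_mismatches(pats[[str]], substr(seq, pos, pos + k - 1))
      if (mm <= max_mm)
        hits[[length(hits) + 1]] <- data.frame(position = pos, strand = str,
                                               mismatches = mm)
    }
  }
  if (length(hits) == 0)
    return(data.frame(position = integer(), strand = character(),
                      mismatches = integer()))
  out <- do.call(rbind, hits)
  out[order(out$position, out$strand), , drop = FALSE]
}

# Exhaustive bipartite promoter enumeration with per--10 deduplication.
oracle_promoters <- function(seq, box35 = "TTGACA", box10 = "TATAAT",
                             spacer = 15:18, budget = 2L) {
  n <- nchar(seq)
  k35 <- nchar(box35); k10 <- nchar(box10)
  cand <- list()
  for (p35 in seq_len(n)) {
    if (p35 + k35 - 1 > n) break
    mm35 <- oracle_mismatches(box35, substr(seq, p35, p35 + k35 - 1))
    if (mm35 > budget) next
    for (s in spacer) {
      p10 <- p35 + k35 + s
      if (p10 + k10 - 1 > n) next
      mm10 <- oracle_mismatches(box10, substr(seq, p10, p10 + k10 - 1))
      if (mm35 + mm10 <= budget)
        cand[[length(cand) + 1]] <- data.frame(pos35 = p35, pos10 = p10,
                                               spacer = s, mm35 = mm35,
                                               mm10 = mm10,
                                               mm_total = mm35 + mm10)
    }
  }
  if (length(cand) == 0)
    return(data.frame(pos35 = integer(), pos10 = integer(), spacer = integer(),
                      mm35 = integer(), mm10 = integer(), mm_total = integer()))
  all <- do.call(rbind, cand)
  all <- all[order(all$pos10, all$mm_total, all$spacer), , drop = FALSE]
  all <- all[!duplicated(all$pos10), , drop = FALSE]
  all[order(all$pos35), , drop = FALSE]
}

# Naive ORF enumeration: every (strand, frame, stop) with its most upstream
# start after the previous in-frame stop. Mass filter via Biostrings
# translation.
oracle_orfs <- function(seq, min_mass = 0,
                        starts = c("ATG", "GTG", "TTG")) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") seq else oracle_rc(seq)
    for (frame in 0:2) {
      prev_stop_end <- frame  # local coord of last consumed base
      pos <- frame + 1
      region_start <- NULL
      while (pos + 2 <= n) {
        codon <- substr(ss, pos, pos + 2)
        if (is.null(region_start) && codon %in% starts) region_start <- pos
        if (codon %in% stops) {
          if (!is.null(region_start)) {
            ls <- region_start; le <- pos + 2
            aa <- as.character(Biostrings::translate(
              Biostrings::DNAString(substr(ss, ls, le - 3)),
              genetic.code = Biostrings::getGeneticCode("11")))
            aa <- paste0("M", substr(aa, 2, nchar(aa)))
            mass <- average_mass(aa)
            if (mass >= min_mass) {
              if (strand == "+") {
                fs <- ls; fe <- le
              } else {
                fs <- n - le + 1; fe <- n - ls + 1
              }
              out[[length(out) + 1]] <- data.frame(start = fs, end = fe,
                                                   strand = strand,
                                                   protein = aa)
            }
          }
          region_start <- NULL
        }
        pos <- pos + 3
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      protein = character()))
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

# Naive maximal-inverted-repeat enumeration mirroring the declared
# definition with explicit character loops.
oracle_hairpins <- function(seq, stem_range = c(4L, 30L),
                            loop_range = c(3L, 10L), max_mm = 1L,
                            wobble = TRUE) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  pt <- function(x, y) {
    if ((x == "A" && y == "T") || (x == "T" && y == "A") ||
        (x == "G" && y == "C") || (x == "C" && y == "G")) return(2L)
    if (wobble && ((x == "G" && y == "T") || (x == "T" && y == "G")))
      return(1L)
    0L
  }
  out <- list()
  for (L in seq(loop_range[1], loop_range[2])) {
    for (l in seq_len(n - L + 1)) {
      d <- 0L; mm <- 0L
      ptypes <- integer(0)
      while (d < stem_range[2]) {
        i <- l - d - 1L; j <- l + L + d
        if (i < 1 || j > n) break
        p <- pt(v[i], v[j])
        if (p == 0L && mm + 1L > max_mm) break
        d <- d + 1L
        if (p == 0L) mm <- mm + 1L
        ptypes <- c(ptypes, p)
      }
      while (d > 0L && ptypes[d] == 0L) d <- d - 1L
      if (d < stem_range[1]) next
      if (ptypes[1] == 0L) next   # mismatch adjacent to the loop: no stem
      if (L - 2 >= loop_range[1] && pt(v[l], v[l + L - 1]) > 0L &&
          d < stem_range[2]) next
      out[[length(out) + 1]] <- data.frame(
        start = l - d, end = l + L - 1 + d, loop_start = l, loop_len = L,
        stem_len = d, n_mismatch = sum(ptypes[seq_len(d)] == 0L))
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(), end = integer(),
                      loop_start = integer(), loop_len = integer(),
                      stem_len = integer(), n_mismatch = integer()))
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

# Independent vectorized grid scan for the isoelectric point: its own
# Henderson-Hasselbalch assembly, 1e5-point grid.
oracle_pi_grid <- function(protein, pka = pka_set(), points = 1e5) {
  chars <- strsplit(protein, "")[[1]]
  nt_res <- chars[1]; ct_res <- chars[length(chars)]
  nt_pka <- if (nt_res %in% names(pka$nterm_by_residue))
    pka$nterm_by_residue[[nt_res]] else pka$nterm_default
  ct_pka <- if (ct_res %in% names(pka$cterm_by_residue))
    pka$cterm_by_residue[[ct_res]] else pka$cterm_default
  pos <- c(nt_pka, rep(pka$side[["H"]], sum(chars == "H")),
           rep(pka$side[["K"]], sum(chars == "K")),
           rep(pka$side[["R"]], sum(chars == "R")))
  neg <- c(ct_pka, rep(pka$side[["D"]], sum(chars == "D")),
           rep(pka$side[["E"]], sum(chars == "E")),
           rep(pka$side[["C"]], sum(chars == "C")),
           rep(pka$side[["Y"]], sum(chars == "Y")))
  grid <- seq(0, 14, length.out = points)
  q <- rowSums(1 / (1 + 10^outer(grid, pos, `-`))) -
       rowSums(1 / (1 + 10^(-outer(grid, neg, `-`))))
  grid[which.min(abs(q))]
}

# Independent re-verification of one reported terminator candidate from
# the raw sequence: pairing geometry, energy arithmetic, and U-tract.
oracle_verify_terminator <- function(seq, cand, dg_threshold = -8,
                                     u_min = 0.5, tail_len = 8L) {
  v <- strsplit(seq, "")[[1]]
  d <- cand$stem_len
  top <- v[cand$hairpin_start + seq_len(d) - 1]
  bot <- v[cand$hairpin_end - seq_len(d) + 1]
  pt <- function(x, y) {
    if ((x == "A" && y == "T") || (x == "T" && y == "A") ||
        (x == "G" && y == "C") || (x == "C" && y == "G")) return(2L)
    if ((x == "G" && y == "T") || (x == "T" && y == "G")) return(1L)
    0L
  }
  ptypes <- mapply(pt, top, bot)
  if (sum(ptypes == 0) > 1) return(FALSE)
  if (ptypes[1] == 0 || ptypes[d] == 0) return(FALSE)
  tail <- v[(cand$hairpin_end + 1):(cand$hairpin_end + tail_len)]
  if (sum(tail == "T") / tail_len < u_min) return(FALSE)
  stacks <- c(AA = -0.93, AT = -1.10, TA = -1.33, CT = -2.08, CA = -2.11,
              GT = -2.24, GA = -2.35, CG = -2.36, GG = -3.26, GC = -3.42)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  dg <- 4.09
  for (k in seq_len(d - 1)) {
    if (ptypes[k] == 0 || ptypes[k + 1] == 0) next
    if (ptypes[k] == 2 && ptypes[k + 1] == 2) {
      key <- paste0(top[k], top[k + 1])
      val <- stacks[key]
      if (is.na(val)) val <- stacks[paste0(comp[top[k + 1]], comp[top[k]])]
      dg <- dg + unname(val)
    } else dg <- dg - 1.3
  }
  for (e in c(1, d))
    if (ptypes[e] == 1 || (ptypes[e] == 2 && top[e] %in% c("A", "T")))
      dg <- dg + 0.45
  dg <- dg + 1.7 * sum(ptypes == 0)
  dg <= dg_threshold
}
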