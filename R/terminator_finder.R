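# Native rho-independent (intrinsic) terminator detection: inverted-repeat
# hairpin search, a stem-only nearest-neighbor stability estimate on the
# transcribed strand, and a downstream U-tract score.

# Watson-Crick nearest-neighbor stack free energies (RNA, 37 C, kcal/mol),
# keyed by two consecutive 5'->3' bases of the paired top strand, written in
# DNA letters (T for U). Missing keys are resolved through the
# reverse-complement symmetry of helix stacks.
NN_STACK_DG <- c(
  AA = -0.93, AT = -1.10, TA = -1.33, CT = -2.08, CA = -2.11,
  GT = -2.24, GA = -2.35, CG = -2.36, GG = -3.26, GC = -3.42
)

# Single configurable term for any stack involving a G.U wobble pair; a
# deliberately simple stand-in for the full wobble tables.
WOBBLE_STACK_DG <- -1.3

# Remaining terms of the standard duplex model: helix initiation, the
# terminal A.U/G.U closing penalty (applied per helix end), and a flat
# penalty for an internal 1x1 mismatch (which also interrupts stacking).
HELIX_INIT_DG <- 4.09
TERMINAL_AU_DG <- 0.45
INTERNAL_MISMATCH_DG <- 1.7

# Pair type between top-strand base x and bottom-strand base y (both read on
# the forward/template string): 2 = Watson-Crick, 1 = G.T wobble, 0 = none.
.pair_type <- function(x, y, wobble = TRUE) {
  wc <- (x == "A" & y == "T") | (x == "T" & y == "A") |
        (x == "G" & y == "C") | (x == "C" & y == "G")
  wb <- wobble & ((x == "G" & y == "T") | (x == "T" & y == "G"))
  ifelse(wc, 2L, ifelse(wb, 1L, 0L))
}

#' Find candidate hairpins (maximal inverted repeats)
#'
#' For every loop placement (loop length within `loop_range`) the stem is
#' extended outward pair by pair while at most `max_mismatch_in_stem`
#' non-complementary pairs have accumulated, up to `stem_range[2]` pairs;
#' terminal mismatches are trimmed so that both the outermost retained pair
#' and the pair adjacent to the loop are real pairs. G.T (G.U on the
#' transcript) counts as a weak pair when
#' `wobble = TRUE`. A hairpin is reported only if it is maximal: its stem is
#' at least `stem_range[1]` pairs and it cannot be extended inward (the loop
#' cannot shrink by one more pair while staying within `loop_range`).
#'
#' @param genome Genome or string (scanned as written; strand handling is
#'   done by [find_terminators()]).
#' @param stem_range `c(min, max)` paired nt per arm (default 4-30).
#' @param loop_range `c(min, max)` loop nt (default 3-10).
#' @param max_mismatch_in_stem Allowed non-complementary pairs (default 1).
#' @param wobble Count G.T as a (weak) pair (default `TRUE`).
#' @return Data frame with columns `start`, `end` (hairpin bounds),
#'   `loop_start`, `loop_len`, `stem_len`, `n_mismatch`, `n_wobble`.
#' @export
find_hairpins <- function(genome, stem_range = c(4L, 30L),
                          loop_range = c(3L, 10L), max_mismatch_in_stem = 1L,
                          wobble = TRUE) {
  s <- .as_seq(genome)
  n <- nchar(s)
  empty <- data.frame(start = integer(), end = integer(),
                      loop_start = integer(), loop_len = integer(),
                      stem_len = integer(), n_mismatch = integer(),
                      n_wobble = integer(), stringsAsFactors = FALSE)
  if (n < 2L * stem_range[1L] + loop_range[1L]) return(empty)
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  smax <- stem_range[2L]
  out <- list()
  for (L in seq(loop_range[1L], loop_range[2L])) {
    # candidate loop starts l: need at least one pair on each side
    l <- seq_len(n - L + 1L)
    # pair-type matrix: row d = pair (l-d, l+L-1+d); out-of-bounds = hard stop
    pt <- matrix(0L, nrow = smax, ncol = length(l))
    cost <- matrix(0L, nrow = smax, ncol = length(l))
    for (d in seq_len(smax)) {
      i <- l - d
      j <- l + L - 1L + d
      ok <- i >= 1L & j <= n
      p <- integer(length(l))
      p[ok] <- .pair_type(v[i[ok]], v[j[ok]], wobble)
      pt[d, ] <- p
      cost[d, ] <- ifelse(!ok, 99L, as.integer(p == 0L))
    }
    cm <- apply(cost, 2L, cumsum)
    exceeded <- cm > max_mismatch_in_stem
    depth <- smax - colSums(exceeded)          # last d with budget intact
    # trim terminal mismatches
    for (iter in seq_len(smax)) {
      idx <- which(depth > 0L)
      idx <- idx[pt[cbind(depth[idx], idx)] == 0L]
      if (length(idx) == 0L) break
      depth[idx] <- depth[idx] - 1L
    }
    keep <- which(depth >= stem_range[1L])
    # both stem ends must be real pairs: outer mismatches were trimmed
    # above, and a mismatch adjacent to the loop is no stem at all
    keep <- keep[pt[1L, keep] != 0L]
    if (length(keep) == 0L) next
    # maximality: drop if the loop could shrink (inner bases pair) and the
    # resulting stem would still be admissible
    if (L - 2L >= loop_range[1L]) {
      inner <- .pair_type(v[l[keep]], v[l[keep] + L - 1L], wobble) > 0L
      keep <- keep[!(inner & depth[keep] < smax)]
    }
    if (length(keep) == 0L) next
    d <- depth[keep]
    lk <- l[keep]
    mism <- cm[cbind(d, keep)]
    nwob <- vapply(seq_along(keep), function(i)
      sum(pt[seq_len(d[i]), keep[i]] == 1L), integer(1L))
    out[[length(out) + 1L]] <- data.frame(
      start = lk - d, end = lk + L - 1L + d, loop_start = lk, loop_len = L,
      stem_len = d, n_mismatch = mism, n_wobble = nwob,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Pure nearest-neighbor stack sum over consecutive pair steps of a stem.
# Steps where both pairs are Watson-Crick use the published table; steps
# touching a wobble pair use `wobble_dg`; steps touching a mismatch
# contribute nothing (stacking is interrupted).
.stack_sum <- function(v, hp, wobble = TRUE, wobble_dg = WOBBLE_STACK_DG) {
  d <- hp$stem_len
  if (d < 2L) return(0)
  top_i <- hp$start + seq_len(d) - 1L            # 5' arm, outermost first
  bot_i <- hp$end - seq_len(d) + 1L              # paired positions
  ptypes <- .pair_type(v[top_i], v[bot_i], wobble)
  dg <- 0
  for (k in seq_len(d - 1L)) {
    p1 <- ptypes[k]; p2 <- ptypes[k + 1L]
    if (p1 == 0L || p2 == 0L) next
    if (p1 == 2L && p2 == 2L) {
      key <- paste0(v[top_i[k]], v[top_i[k + 1L]])
      val <- NN_STACK_DG[key]
      if (is.na(val)) {
        key2 <- paste0(IUPAC_COMPLEMENT[v[top_i[k + 1L]]],
                       IUPAC_COMPLEMENT[v[top_i[k]]])
        val <- NN_STACK_DG[key2]
      }
      dg <- dg + unname(val)
    } else {
      dg <- dg + wobble_dg
    }
  }
  dg
}

# Full stem stability: initiation + stacks + terminal A.U/G.U closing
# penalties + internal-mismatch penalties. No loop term (the geometry
# filter owns the loop); this approximates the usual full-hairpin dG
# criterion once initiation stands in for the loop penalty.
.dg_stem <- function(v, hp, wobble = TRUE, wobble_dg = WOBBLE_STACK_DG) {
  d <- hp$stem_len
  top_i <- hp$start + seq_len(d) - 1L
  bot_i <- hp$end - seq_len(d) + 1L
  ptypes <- .pair_type(v[top_i], v[bot_i], wobble)
  dg <- HELIX_INIT_DG + .stack_sum(v, hp, wobble, wobble_dg)
  for (endk in c(1L, d)) {
    if (ptypes[endk] == 1L ||
        (ptypes[endk] == 2L && v[top_i[endk]] %in% c("A", "T")))
      dg <- dg + TERMINAL_AU_DG
  }
  dg + INTERNAL_MISMATCH_DG * sum(ptypes == 0L)
}

#' Nearest-neighbor stack sum of a perfect helix
#'
#' Accessor for the core of the energy model: the sum of published
#' nearest-neighbor stack terms of a fully Watson-Crick helix whose 5' arm
#' is `arm` (DNA letters; RNA parameters applied to the transcribed
#' strand). The full candidate score adds helix initiation, terminal
#' A.U/G.U penalties and internal-mismatch penalties on top of this sum.
#'
#' @param arm 5'->3' top-strand bases of the helix.
#' @return Stack-sum free energy in kcal/mol.
#' @export
stem_dg <- function(arm) {
  arm <- toupper(arm)
  v <- strsplit(paste0(arm, "AAA", reverse_complement(arm)), "", fixed = TRUE)[[1L]]
  hp <- list(start = 1L, end = length(v), stem_len = nchar(arm))
  .stack_sum(v, hp)
}

#' Score a hairpin as a terminator candidate
#'
#' Computes the stem stability estimate and the U-tract score (fraction of T
#' in the `tail_len` nt immediately 3' of the hairpin) and applies the
#' acceptance thresholds.
#'
#' @param genome Genome or string.
#' @param hairpin One row from [find_hairpins()].
#' @param dg_threshold Keep if `dg_stem <= dg_threshold` (default -8.0).
#' @param u_min Keep if `u_score >= u_min` (default 0.5).
#' @param tail_len U-tract window (default 8 nt).
#' @param wobble,wobble_dg Energy-model knobs (see [find_hairpins()]).
#' @return One-row candidate data frame, or `NULL` with attribute-free
#'   rejection: a list `list(reject = reason)` when the candidate fails.
#' @export
score_terminator <- function(genome, hairpin, dg_threshold = -8.0,
                             u_min = 0.5, tail_len = 8L, wobble = TRUE,
                             wobble_dg = WOBBLE_STACK_DG, stem_min = 4L) {
  s <- .as_seq(genome)
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  .score_terminator_v(v, hairpin, dg_threshold, u_min, tail_len, wobble,
                      wobble_dg, stem_min)
}

.score_terminator_v <- function(v, hairpin, dg_threshold, u_min, tail_len,
                                wobble, wobble_dg, stem_min) {
  n <- length(v)
  # A maximal inverted repeat often over-extends its 3' arm into the very
  # U-tract that should follow it (U pairs A and, as a wobble, G). Peeling
  # outer pairs restores such registers, so every trim down to the minimum
  # stem is scored and the most stable candidate that passes both filters
  # is kept.
  best <- NULL
  reason <- NULL
  d0 <- hairpin$stem_len
  pt_all <- .pair_type(v[hairpin$start + seq_len(d0) - 1L],
                       v[hairpin$end - seq_len(d0) + 1L], wobble)
  for (trim in 0:(hairpin$stem_len - stem_min)) {
    if (pt_all[trim + 1L] == 0L) next   # a stem cannot open on a mismatch
    hp <- list(start = hairpin$start + trim, end = hairpin$end - trim,
               stem_len = hairpin$stem_len - trim,
               loop_len = hairpin$loop_len)
    if (hp$end + tail_len > n) {
      if (is.null(reason)) reason <- "truncated tail"
      next
    }
    dg <- .dg_stem(v, hp, wobble, wobble_dg)
    tail <- v[(hp$end + 1L):(hp$end + tail_len)]
    u <- sum(tail == "T") / tail_len
    if (dg > dg_threshold) {
      if (is.null(reason)) reason <- "weak stem"
      next
    }
    if (u < u_min) {
      if (is.null(reason)) reason <- "no U-tract"
      next
    }
    top <- hp$start + seq_len(hp$stem_len) - 1L
    bot <- hp$end - seq_len(hp$stem_len) + 1L
    mism <- sum(.pair_type(v[top], v[bot], wobble) == 0L)
    cand <- data.frame(start = hp$start, end = hp$end + tail_len,
                       hairpin_start = hp$start, hairpin_end = hp$end,
                       stem_len = hp$stem_len, loop_len = hp$loop_len,
                       n_mismatch = mism, dg_stem = dg, u_score = u,
                       stringsAsFactors = FALSE)
    if (is.null(best) || cand$dg_stem < best$dg_stem) best <- cand
  }
  if (is.null(best)) return(list(reject = reason))
  best
}

.empty_terminators <- function() {
  data.frame(start = integer(), end = integer(), hairpin_start = integer(),
             hairpin_end = integer(), stem_len = integer(),
             loop_len = integer(), n_mismatch = integer(), dg_stem = numeric(),
             u_score = numeric(), strand = character(), stringsAsFactors = FALSE)
}

#' Find rho-independent terminator candidates
#'
#' Composition of [find_hairpins()] and [score_terminator()]: hairpins are
#' enumerated, scored, filtered at the thresholds, and overlapping survivors
#' (hairpin intervals sharing any position) are collapsed to the one with
#' the lowest stem free energy (tie: smaller start).
#'
#' @inheritParams find_hairpins
#' @inheritParams score_terminator
#' @param strand `"forward"` (default, transcription direction of a
#'   unidirectional genome) or `"both"`.
#' @return Data frame of terminator candidates sorted by start, with a
#'   `strand` column; minus-strand candidates are in forward coordinates.
#' @export
find_terminators <- function(genome, stem_range = c(4L, 30L),
                             loop_range = c(3L, 10L),
                             max_mismatch_in_stem = 1L,
                             dg_threshold = -8.0, u_min = 0.5, tail_len = 8L,
                             wobble = TRUE, wobble_dg = WOBBLE_STACK_DG,
                             strand = c("forward", "both")) {
  strand <- match.arg(strand)
  s <- .as_seq(genome)
  one <- function(seqstr, str) {
    hp <- find_hairpins(seqstr, stem_range, loop_range, max_mismatch_in_stem,
                        wobble)
    v <- strsplit(seqstr, "", fixed = TRUE)[[1L]]
    rows <- list()
    for (i in seq_len(nrow(hp))) {
      sc <- .score_terminator_v(v, hp[i, ], dg_threshold, u_min, tail_len,
                                wobble, wobble_dg, stem_range[1L])
      if (is.data.frame(sc)) rows[[length(rows) + 1L]] <- sc
    }
    if (length(rows) == 0L) return(.empty_terminators())
    cand <- do.call(rbind, rows)
    cand$strand <- str
    # collapse overlapping hairpins to the most stable candidate
    cand <- cand[order(cand$dg_stem, cand$start), , drop = FALSE]
    kept <- cand[0L, ]
    for (i in seq_len(nrow(cand))) {
      x <- cand[i, ]
      if (nrow(kept) == 0L ||
          all(x$hairpin_end < kept$hairpin_start | x$hairpin_start > kept$hairpin_end))
        kept <- rbind(kept, x)
    }
    kept
  }
  out <- one(s, "+")
  if (strand == "both") {
    rcout <- one(reverse_complement(s), "-")
    if (nrow(rcout) > 0L) {
      n <- nchar(s)
      flip <- function(a, b) list(start = n - b + 1L, end = n - a + 1L)
      f1 <- flip(rcout$start, rcout$end)
      f2 <- flip(rcout$hairpin_start, rcout$hairpin_end)
      rcout$start <- f1$start; rcout$end <- f1$end
      rcout$hairpin_start <- f2$start; rcout$hairpin_end <- f2$end
      out <- rbind(out, rcout)
    }
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "genome_id") <- .genome_id(genome)
  out
}
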