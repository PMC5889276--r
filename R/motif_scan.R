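# Degenerate motif scanning: IUPAC restriction-site screens and the
# bipartite sigma-70 promoter search.

#' Compile an IUPAC pattern into a positional matcher
#'
#' Each pattern letter becomes a 4-bit base mask (A=1, C=2, G=4, T=8;
#' degenerate letters OR their bases). A genome position is compatible with
#' a pattern position when the masks intersect, which makes Hamming distance
#' under IUPAC degeneracy well defined.
#'
#' @param pattern IUPAC nucleotide string.
#' @return An object of class `iupac_matcher` with fields `pattern`,
#'   `length`, `masks`.
#' @export
compile_iupac <- function(pattern) {
  pattern <- toupper(pattern)
  .validate_alphabet(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  structure(list(pattern = pattern, length = length(chars),
                 masks = unname(IUPAC_MASK[chars])),
            class = "iupac_matcher")
}

#' Count mismatches of a pattern against an equal-length window
#'
#' @param matcher From [compile_iupac()] (or a pattern string).
#' @param window Concrete sequence window of the same length.
#' @param permissive_ambiguity If `FALSE` (default), degenerate letters in
#'   the *window* match nothing (conservative counting); if `TRUE` they match
#'   by mask intersection.
#' @return Integer mismatch count.
#' @export
iupac_mismatches <- function(matcher, window, permissive_ambiguity = FALSE) {
  if (!inherits(matcher, "iupac_matcher")) matcher <- compile_iupac(matcher)
  codes <- .seq_codes(toupper(window), permissive_ambiguity)
  if (length(codes) != matcher$length) stop("window length != pattern length")
  sum(bitwAnd(codes, matcher$masks) == 0L)
}

# Integer mask codes for a genome string. Under conservative counting every
# non-ACGT genome letter gets code 0 and therefore mismatches any pattern
# letter, including N.
.seq_codes <- function(seq, permissive_ambiguity = FALSE) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  codes <- unname(IUPAC_MASK[chars])
  if (anyNA(codes)) .validate_alphabet(seq)
  if (!permissive_ambiguity) codes[!chars %in% c("A", "C", "G", "T")] <- 0L
  as.integer(codes)
}

# Mismatch count of `matcher` at every window start of `codes`
# (length n - k + 1). O(n * k) vectorized over n.
.window_mismatches <- function(codes, matcher) {
  n <- length(codes)
  k <- matcher$length
  if (k > n) return(integer(0))
  nwin <- n - k + 1L
  mm <- integer(nwin)
  for (j in seq_len(k)) {
    mm <- mm + (bitwAnd(codes[j:(j + nwin - 1L)], matcher$masks[j]) == 0L)
  }
  mm
}

#' Scan a genome for a degenerate pattern
#'
#' Reports every window within the mismatch budget. Reverse-strand hits are
#' found by scanning the reverse complement of the pattern on the forward
#' sequence and are reported in forward coordinates (position of the
#' leftmost base of the matched window). Overlapping hits are all reported.
#'
#' @param genome A `phage_genome` or sequence string.
#' @param pattern IUPAC pattern.
#' @param max_mismatch Mismatch budget (default 0).
#' @param strands `"both"` (default), `"forward"` or `"reverse"`.
#' @param pattern_name Name recorded on the hits (defaults to the pattern).
#' @param permissive_ambiguity Passed to the matcher; see
#'   [iupac_mismatches()].
#' @return Data frame with columns `pattern_name`, `pattern`, `position`,
#'   `strand`, `mismatches`, sorted by position then strand.
#' @export
scan_pattern <- function(genome, pattern, max_mismatch = 0L,
                         strands = c("both", "forward", "reverse"),
                         pattern_name = pattern, permissive_ambiguity = FALSE) {
  strands <- match.arg(strands)
  s <- .as_seq(genome)
  pattern <- toupper(pattern)
  if (nchar(pattern) > nchar(s)) stop("pattern longer than genome")
  codes <- .seq_codes(s, permissive_ambiguity)
  out <- list()
  if (strands %in% c("both", "forward")) {
    mm <- .window_mismatches(codes, compile_iupac(pattern))
    pos <- which(mm <= max_mismatch)
    if (length(pos) > 0L)
      out[[length(out) + 1L]] <- data.frame(
        pattern_name = pattern_name, pattern = pattern, position = pos,
        strand = "+", mismatches = mm[pos], stringsAsFactors = FALSE)
  }
  if (strands %in% c("both", "reverse")) {
    mm <- .window_mismatches(codes, compile_iupac(reverse_complement(pattern)))
    pos <- which(mm <= max_mismatch)
    if (length(pos) > 0L)
      out[[length(out) + 1L]] <- data.frame(
        pattern_name = pattern_name, pattern = pattern, position = pos,
        strand = "-", mismatches = mm[pos], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    hits <- data.frame(pattern_name = character(), pattern = character(),
                       position = integer(), strand = character(),
                       mismatches = integer(), stringsAsFactors = FALSE)
  } else {
    hits <- do.call(rbind, out)
    hits <- hits[order(hits$position, hits$strand), , drop = FALSE]
    rownames(hits) <- NULL
  }
  attr(hits, "genome_id") <- .genome_id(genome)
  hits
}

#' Is a pattern IUPAC-palindromic?
#'
#' A recognition sequence equal to its IUPAC-aware reverse complement (e.g.
#' GATC, CGATCG, CYCGRG), so that one strand's matches enumerate all sites.
#'
#' @param pattern IUPAC pattern.
#' @export
is_iupac_palindrome <- function(pattern) {
  toupper(pattern) == reverse_complement(pattern)
}

#' Count distinct recognition-site positions for a restriction pattern
#'
#' Exact matching only. For IUPAC-palindromic patterns this is the
#' forward-strand match count; otherwise it is the size of the union of
#' forward positions of matches on either strand.
#'
#' @param genome Genome or string.
#' @param pattern IUPAC recognition sequence.
#' @return Integer count of distinct site positions.
#' @export
count_recognition_sites <- function(genome, pattern) {
  if (is_iupac_palindrome(pattern)) {
    hits <- scan_pattern(genome, pattern, 0L, strands = "forward")
    nrow(hits)
  } else {
    hits <- scan_pattern(genome, pattern, 0L, strands = "both")
    length(unique(hits$position))
  }
}

#' Built-in restriction recognition-site registry
#'
#' Host (Geobacillus stearothermophilus) Type II enzymes plus a panel of
#' common endonucleases, as degenerate IUPAC recognition sequences.
#'
#' @return Named character vector: enzyme name -> recognition sequence.
#' @export
restriction_patterns <- function() {
  c(Gst1588I = "CYCGRG", Gst1588II = "GATC", GstI = "GGATCC",
    Gst4109 = "CGATCG", GsaI = "CCCAGC",
    BamHI = "GGATCC", EcoRV = "GATATC", HpaI = "GTTAAC", KpnI = "GGTACC",
    PstI = "CTGCAG", SacI = "GAGCTC", SalI = "GTCGAC", SmaI = "CCCGGG")
}

#' Read a pattern registry from a two-column TSV
#'
#' @param path TSV with columns `name` and `pattern` (header required).
#' @return Named character vector.
#' @export
read_patterns <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "pattern") %in% names(df)))
    stop("pattern registry needs columns 'name' and 'pattern'")
  stats::setNames(toupper(df$pattern), df$name)
}

#' Bipartite sigma-70 promoter search
#'
#' Slides the -35 box (default `TTGACA`) and -10 box (default `TATAAT`) over
#' the genome with a spacer of `spacer_range` nucleotides strictly between
#' the boxes and a *shared* mismatch budget across both boxes. All
#' `(pos35, spacer)` placements within budget are enumerated, then collapsed
#' to one hit per -10 box position (minimal total mismatches; ties broken by
#' the smallest spacer), because one -10 box reachable through several
#' compatible spacers is one promoter.
#'
#' @param genome Genome or string.
#' @param box35,box10 Fixed-length IUPAC consensus boxes.
#' @param spacer_range Integer vector `c(min, max)` spacer length.
#' @param max_total_mismatch Shared budget (default 2).
#' @param strand `"forward"` (default; promoters are sought on the
#'   coding strand of a unidirectional genome) or `"both"`.
#' @return Data frame with columns `pos35`, `pos10`, `spacer`, `mm35`,
#'   `mm10`, `mm_total`, `strand`, `box35`, `box10`, sorted by `pos35`;
#'   reverse-strand hits (if requested) are in forward coordinates of each
#'   box's leftmost base, with `pos35 > pos10`.
#' @export
find_promoters <- function(genome, box35 = "TTGACA", box10 = "TATAAT",
                           spacer_range = c(15L, 18L), max_total_mismatch = 2L,
                           strand = c("forward", "both"),
                           permissive_ambiguity = FALSE) {
  strand <- match.arg(strand)
  s <- .as_seq(genome)
  out <- .promoters_one_strand(s, box35, box10, spacer_range,
                               max_total_mismatch, permissive_ambiguity)
  out$strand <- rep("+", nrow(out))
  if (strand == "both") {
    rc <- .promoters_one_strand(reverse_complement(s), box35, box10,
                                spacer_range, max_total_mismatch,
                                permissive_ambiguity)
    if (nrow(rc) > 0L) {
      n <- nchar(s)
      flip35 <- n - (rc$pos35 + nchar(box35) - 1L) + 1L
      flip10 <- n - (rc$pos10 + nchar(box10) - 1L) + 1L
      rc$pos35 <- flip35
      rc$pos10 <- flip10
      rc$strand <- "-"
      out <- rbind(out, rc)
    }
  }
  out <- out[order(out$pos35, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "genome_id") <- .genome_id(genome)
  out
}

.promoters_one_strand <- function(s, box35, box10, spacer_range, budget,
                                  permissive_ambiguity) {
  codes <- .seq_codes(s, permissive_ambiguity)
  m35 <- compile_iupac(box35)
  m10 <- compile_iupac(box10)
  mm35 <- .window_mismatches(codes, m35)
  mm10 <- .window_mismatches(codes, m10)
  cand <- list()
  for (spacer in seq(spacer_range[1L], spacer_range[2L])) {
    off <- m35$length + spacer     # pos10 = pos35 + |box35| + spacer
    n35 <- length(mm35) - off
    if (n35 < 1L) next
    p35 <- seq_len(n35)
    tot <- mm35[p35] + mm10[p35 + off]
    keep <- which(tot <= budget)
    if (length(keep) > 0L)
      cand[[length(cand) + 1L]] <- data.frame(
        pos35 = keep, pos10 = keep + off, spacer = spacer,
        mm35 = mm35[keep], mm10 = mm10[keep + off],
        mm_total = tot[keep], stringsAsFactors = FALSE)
  }
  if (length(cand) == 0L)
    return(data.frame(pos35 = integer(), pos10 = integer(), spacer = integer(),
                      mm35 = integer(), mm10 = integer(), mm_total = integer(),
                      box35 = character(), box10 = character(),
                      stringsAsFactors = FALSE))
  all <- do.call(rbind, cand)
  # one hit per -10 box: minimal mm_total, tie -> smallest spacer
  all <- all[order(all$pos10, all$mm_total, all$spacer), , drop = FALSE]
  all <- all[!duplicated(all$pos10), , drop = FALSE]
  all$box35 <- toupper(box35)
  all$box10 <- toupper(box10)
  rownames(all) <- NULL
  all
}
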