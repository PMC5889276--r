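# ORF/CDS calling under bacterial translation table 11, CDS translation,
# genome-packing statistics, and the curated-annotation import path.
#
# Conventions forced by the target application: the stop codon is counted
# inside the CDS interval and nt length, so aa_length == nt_length/3 - 1.

# Translation table 11 (bacterial/archaeal/plastid). Codon -> single-letter
# amino acid; '*' marks stops. Same codon box as the standard code; the
# difference is the alternative initiators, handled at translation time.
.codon_table11 <- local({
  b <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1L]]
  codons <- paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L), rep(b, 16L))
  stats::setNames(aas, codons)
})

STOP_CODONS <- names(.codon_table11)[.codon_table11 == "*"]

# Translate an in-frame nucleotide string; no stop handling policy here.
.codons_of <- function(ntseq) {
  substring(ntseq, seq(1L, nchar(ntseq) - 2L, by = 3L),
            seq(3L, nchar(ntseq), by = 3L))
}

#' Translate a CDS interval under translation table 11
#'
#' The interval must be in frame (length divisible by 3) and end in a stop
#' codon, which is dropped from the returned protein. The initiator codon is
#' translated as M when it is one of the configured start codons (ATG, GTG,
#' TTG by default), per the bacterial code.
#'
#' @param genome Genome or string.
#' @param start,end 1-based inclusive CDS bounds (stop codon included).
#' @param strand `"+"` or `"-"`.
#' @param start_codons Codons granted the initiator-Met rule.
#' @return Amino-acid string without the stop symbol.
#' @export
translate_cds <- function(genome, start, end, strand = "+",
                          start_codons = c("ATG", "GTG", "TTG")) {
  nt <- subseq1(genome, start, end, strand)
  n <- nchar(nt)
  if (n %% 3L != 0L)
    stop(sprintf("CDS %d-%d (%s): length %d not divisible by 3", start, end, strand, n))
  codons <- .codons_of(nt)
  aa <- unname(.codon_table11[codons])
  if (anyNA(aa))
    stop(sprintf("CDS %d-%d: ambiguous or invalid codon '%s' at codon %d",
                 start, end, codons[which(is.na(aa))[1L]], which(is.na(aa))[1L]))
  k <- length(aa)
  if (aa[k] != "*")
    stop(sprintf("CDS %d-%d (%s): final codon %s is not a stop", start, end,
                 strand, codons[k]))
  internal <- which(aa[-k] == "*")
  if (length(internal) > 0L)
    stop(sprintf("CDS %d-%d (%s): internal stop at codon %d", start, end,
                 strand, internal[1L]))
  if (codons[1L] %in% start_codons) aa[1L] <- "M"
  paste(aa[-k], collapse = "")
}

# Build one CDS feature row (computing translation, mass, pI).
.make_cds_row <- function(genome, start, end, strand, label,
                          start_codons = c("ATG", "GTG", "TTG")) {
  protein <- translate_cds(genome, start, end, strand, start_codons)
  data.frame(label = label, start = start, end = end, strand = strand,
             nt_length = end - start + 1L, aa_length = nchar(protein),
             protein = protein, mass_kda = average_mass(protein),
             pi = isoelectric_point(protein), stringsAsFactors = FALSE)
}

.empty_cds <- function() {
  data.frame(label = character(), start = integer(), end = integer(),
             strand = character(), nt_length = integer(), aa_length = integer(),
             protein = character(), mass_kda = numeric(), pi = numeric(),
             stringsAsFactors = FALSE)
}

#' Call ORFs/CDSs with a minimum-product-mass filter
#'
#' In each frame of each requested strand, each stop codon closes at most
#' one candidate CDS: the longest open reading from the most upstream start
#' codon after the previous in-frame stop, through the closing stop
#' (included in the interval). Candidates whose translated product is
#' lighter than `min_mass_kda` (average mass) are removed.
#'
#' @param genome Genome or `phage_genome`.
#' @param min_mass_kda Minimum product mass in kDa (default 4.0).
#' @param start_codons Allowed start codons.
#' @param strands `"both"` (default) or `"forward"`.
#' @param all_starts If `TRUE`, report one candidate per (start, stop) pair
#'   instead of only the longest reading per stop.
#' @return CDS data frame (columns `label`, `start`, `end`, `strand`,
#'   `nt_length`, `aa_length`, `protein`, `mass_kda`, `pi`), sorted by start.
#' @export
find_orfs <- function(genome, min_mass_kda = 4.0,
                      start_codons = c("ATG", "GTG", "TTG"),
                      strands = c("both", "forward"), all_starts = FALSE) {
  strands <- match.arg(strands)
  out <- .enumerate_orfs(genome, min_mass_kda, start_codons, strands, all_starts)
  if (nrow(out) > 0L) {
    out$pi <- vapply(out$protein, isoelectric_point, numeric(1L),
                     USE.NAMES = FALSE)
    stem <- gsub("[^A-Za-z0-9]", "", .genome_id(genome))
    out$label <- sprintf("%s_%02d", stem, seq_len(nrow(out)))
    out <- out[, c("label", "start", "end", "strand", "nt_length",
                   "aa_length", "protein", "mass_kda", "pi")]
  }
  attr(out, "genome_id") <- .genome_id(genome)
  out
}

# Interval enumeration + translation + mass filter, without the pI
# computation (kept separate because callers like the synthetic-data
# clearing loop only need intervals and masses).
.enumerate_orfs <- function(genome, min_mass_kda, start_codons, strands,
                            all_starts = FALSE) {
  s <- .as_seq(genome)
  n <- nchar(s)
  strand_set <- if (strands == "both") c("+", "-") else "+"
  rcs <- if ("-" %in% strand_set) reverse_complement(s) else NULL
  rows <- list()
  for (strand in strand_set) {
    ss <- if (strand == "+") s else rcs
    for (frame in 0:2) {
      ncod <- (n - frame) %/% 3L
      if (ncod < 2L) next
      pos <- frame + seq(1L, by = 3L, length.out = ncod)
      codons <- substring(ss, pos, pos + 2L)
      is_stop <- codons %in% STOP_CODONS
      is_start <- codons %in% start_codons
      stop_idx <- which(is_stop)
      prev <- 0L
      for (j in stop_idx) {
        if (j > prev + 1L) {
          range <- (prev + 1L):(j - 1L)
          starts <- range[is_start[range]]
          if (length(starts) > 0L) {
            use <- if (all_starts) starts else starts[1L]
            for (a in use) {
              ls <- pos[a]
              le <- pos[j] + 2L
              if (strand == "+") {
                fs <- ls; fe <- le
              } else {
                fs <- n - le + 1L; fe <- n - ls + 1L
              }
              rows[[length(rows) + 1L]] <- c(fs, fe, ls, le,
                                             if (strand == "+") 1L else -1L)
            }
          }
        }
        prev <- j
      }
    }
  }
  if (length(rows) == 0L) return(.empty_cds())
  m <- do.call(rbind, rows)
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  kept <- list()
  for (i in seq_len(nrow(m))) {
    strand <- if (m[i, 5L] > 0L) "+" else "-"
    nt <- substr(if (strand == "+") s else rcs, m[i, 3L], m[i, 4L])
    codons <- .codons_of(nt)
    aa <- unname(.codon_table11[codons])
    if (codons[1L] %in% start_codons) aa[1L] <- "M"
    protein <- paste(aa[-length(aa)], collapse = "")
    mass <- average_mass(protein)
    if (mass >= min_mass_kda)
      kept[[length(kept) + 1L]] <- data.frame(
        label = "", start = m[i, 1L], end = m[i, 2L], strand = strand,
        nt_length = m[i, 2L] - m[i, 1L] + 1L, aa_length = nchar(protein),
        protein = protein, mass_kda = mass, pi = NA_real_,
        stringsAsFactors = FALSE)
  }
  if (length(kept) == 0L) return(.empty_cds())
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  out
}

#' Genome-packing statistics for a CDS set
#'
#' Gaps are computed per consecutive start-sorted pair as
#' `start(downstream) - end(upstream) - 1`; a negative gap is an overlap.
#'
#' @param features CDS data frame with `label`, `start`, `end`, `strand`.
#' @return List of class `packing_profile`: `strand_counts`, `gaps` (data
#'   frame `upstream_label`, `downstream_label`, `gap_nt`), `n_overlaps`,
#'   `max_gap` (one row of `gaps`; ties broken by smaller upstream start).
#' @export
packing_profile <- function(features) {
  stopifnot(nrow(features) >= 1L)
  f <- features[order(features$start, features$end), , drop = FALSE]
  strand_counts <- c(`+` = sum(f$strand == "+"), `-` = sum(f$strand == "-"))
  if (nrow(f) > 1L) {
    up <- seq_len(nrow(f) - 1L)
    gaps <- data.frame(upstream_label = f$label[up],
                       downstream_label = f$label[up + 1L],
                       gap_nt = f$start[up + 1L] - f$end[up] - 1L,
                       stringsAsFactors = FALSE)
  } else {
    gaps <- data.frame(upstream_label = character(),
                       downstream_label = character(), gap_nt = integer(),
                       stringsAsFactors = FALSE)
  }
  max_gap <- if (nrow(gaps) > 0L) gaps[which.max(gaps$gap_nt), , drop = FALSE] else NULL
  structure(list(strand_counts = strand_counts, gaps = gaps,
                 n_overlaps = sum(gaps$gap_nt < 0L), max_gap = max_gap),
            class = "packing_profile")
}

#' @export
print.packing_profile <- function(x, ...) {
  cat(sprintf("<packing_profile> %d features (+%d/-%d), %d overlaps\n",
              sum(x$strand_counts), x$strand_counts[["+"]],
              x$strand_counts[["-"]], x$n_overlaps))
  if (!is.null(x$max_gap))
    cat(sprintf("  largest gap: %d nt between %s and %s\n", x$max_gap$gap_nt,
                x$max_gap$upstream_label, x$max_gap$downstream_label))
  invisible(x)
}

#' Read a curated CDS table (TSV)
#'
#' Importer for curated annotations: requires columns `label`, `start`,
#' `end`, `strand`; extra reference columns (`nt_length`, `aa_length`,
#' `mass_kda`, `pi`) are kept when present.
#'
#' @param path TSV path.
#' @return Data frame sorted by start.
#' @export
read_cds_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "start", "end", "strand")
  if (!all(need %in% names(df)))
    stop("CDS table needs columns: ", paste(need, collapse = ", "))
  df[order(df$start), , drop = FALSE]
}

#' Build CDS features from imported coordinates
#'
#' The reference path for validating a genome against a curated annotation:
#' coordinates in, full features (translation, mass, pI) out. Rows whose
#' interval cannot be translated (out of frame, internal stop, no terminal
#' stop) are kept with `NA` products and the failure reason in `note`.
#'
#' @param genome Genome.
#' @param table Data frame from [read_cds_table()].
#' @export
cds_from_table <- function(genome, table) {
  rows <- vector("list", nrow(table))
  for (i in seq_len(nrow(table))) {
    r <- table[i, ]
    rows[[i]] <- tryCatch({
      x <- .make_cds_row(genome, r$start, r$end, r$strand, r$label)
      x$note <- ""
      x
    }, error = function(e) {
      data.frame(label = r$label, start = r$start, end = r$end,
                 strand = r$strand, nt_length = r$end - r$start + 1L,
                 aa_length = NA_integer_, protein = NA_character_,
                 mass_kda = NA_real_, pi = NA_real_,
                 note = conditionMessage(e), stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  attr(out, "genome_id") <- .genome_id(genome)
  out
}

#' Concordance report between a curated CDS table and recomputed values
#'
#' Structural checks use the table alone: strand census, the arithmetic
#' `aa_length == nt_length/3 - 1` per row, and agreement between the printed
#' `nt_length` and the printed interval (disagreements are flagged, not
#' failed — curated tables are known to carry the occasional typo). When a
#' genome is supplied, products are recomputed from the sequence and
#' per-row mass and pI deltas against the reference columns are added.
#'
#' @param table Curated table with reference columns (see
#'   [read_cds_table()]).
#' @param genome Optional genome for recomputation.
#' @return List of class `cds_concordance` with `per_row` (data frame) and
#'   summary fields `n_cds`, `strand_counts`, `n_aa_consistent`,
#'   `interval_flags` (labels where printed length != interval span).
#' @export
table_concordance <- function(table, genome = NULL) {
  per <- data.frame(label = table$label, strand = table$strand,
                    stringsAsFactors = FALSE)
  span <- table$end - table$start + 1L
  has_nt <- "nt_length" %in% names(table)
  nt <- if (has_nt) table$nt_length else span
  per$nt_length <- nt
  per$interval_span <- span
  per$interval_consistent <- nt == span
  if ("aa_length" %in% names(table)) {
    per$aa_length <- table$aa_length
    per$aa_consistent <- table$aa_length == nt %/% 3L - 1L
  }
  if (!is.null(genome)) {
    feats <- cds_from_table(genome, table)
    per$mass_recomputed <- feats$mass_kda
    per$pi_recomputed <- feats$pi
    if ("mass_kda" %in% names(table))
      per$mass_delta <- feats$mass_kda - table$mass_kda
    if ("pi" %in% names(table))
      per$pi_delta <- feats$pi - table$pi
    per$note <- feats$note
  }
  structure(list(
    per_row = per,
    n_cds = nrow(table),
    strand_counts = c(`+` = sum(table$strand == "+"),
                      `-` = sum(table$strand == "-")),
    n_aa_consistent = if ("aa_consistent" %in% names(per))
      sum(per$aa_consistent) else NA_integer_,
    interval_flags = per$label[!per$interval_consistent]
  ), class = "cds_concordance")
}

#' @export
print.cds_concordance <- function(x, ...) {
  cat(sprintf("<cds_concordance> %d CDSs (+%d/-%d); aa arithmetic ok: %s/%d\n",
              x$n_cds, x$strand_counts[["+"]], x$strand_counts[["-"]],
              ifelse(is.na(x$n_aa_consistent), "NA", x$n_aa_consistent), x$n_cds))
  if (length(x$interval_flags) > 0L)
    cat("  printed length != interval span for:",
        paste(x$interval_flags, collapse = ", "), "\n")
  invisible(x)
}
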