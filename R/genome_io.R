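# Genome input/output and the coordinate conventions used package-wide.
#
# Every interval in this package is 1-based and inclusive at both ends, on
# the forward (deposited) strand. Conversions to other conventions happen
# only at serialization boundaries.

# 15-letter IUPAC nucleotide alphabet (N included).
IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

# Bit masks: A=1, C=2, G=4, T=8; a degenerate letter is the OR of its bases.
IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Construct a genome record
#'
#' A `phage_genome` is the package's carrier for one nucleotide sequence:
#' an identifier, an uppercased sequence over the IUPAC alphabet, its length
#' and its topology. Lowercase input is uppercased silently; `U` is mapped to
#' `T` with a warning. Characters outside the 15-letter IUPAC alphabet are an
#' error that names the first offending offset.
#'
#' @param seq Nucleotide string.
#' @param id Sequence identifier.
#' @param topology `"linear"` (default) or `"circular"`.
#' @return An object of class `phage_genome` with fields `id`, `seq`,
#'   `length`, `topology` and `n_ambiguous` (count of non-ACGT letters).
#' @export
genome_record <- function(seq, id = "genome", topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("U", seq, fixed = TRUE)) {
    warning("sequence contains U; mapping U -> T (RNA input assumed)")
    seq <- gsub("U", "T", seq, fixed = TRUE)
  }
  .validate_alphabet(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  structure(
    list(id = id, seq = seq, length = nchar(seq), topology = topology,
         n_ambiguous = sum(!chars %in% c("A", "C", "G", "T"))),
    class = "phage_genome"
  )
}

#' @export
print.phage_genome <- function(x, ...) {
  cat(sprintf("<phage_genome> %s: %d bp, %s", x$id, x$length, x$topology))
  if (x$n_ambiguous > 0L) cat(sprintf(" (%d ambiguous)", x$n_ambiguous))
  cat("\n")
  invisible(x)
}

.validate_alphabet <- function(seq) {
  bad <- regexpr(paste0("[^", paste(IUPAC_LETTERS, collapse = ""), "]"), seq)
  if (bad > 0L) {
    stop(sprintf("illegal character '%s' at offset %d (not an IUPAC nucleotide code)",
                 substr(seq, bad, bad), bad))
  }
  invisible(TRUE)
}

# Accept either a phage_genome or a bare string everywhere downstream.
.as_seq <- function(genome) {
  if (inherits(genome, "phage_genome")) return(genome$seq)
  if (is.character(genome) && length(genome) == 1L) return(toupper(genome))
  stop("expected a phage_genome or a single nucleotide string")
}

.genome_id <- function(genome) {
  if (inherits(genome, "phage_genome")) genome$id else "genome"
}

#' Read genome sequences from FASTA or bare sequence text
#'
#' Reads standard (possibly multi-record) FASTA. A headerless "bare" dialect
#' is also accepted — plain sequence text with arbitrary line breaks,
#' whitespace and line numbers, as distributed in supplementary TXT files —
#' in which case a single record is synthesized with the file stem as its id.
#'
#' @param path Path to the file.
#' @param topology Topology recorded on the returned genomes.
#' @return A list of [genome_record()] objects.
#' @export
read_fasta <- function(path, topology = "linear") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^;", lines)]       # old-style FASTA comments
  headers <- grep("^>", lines)
  clean <- function(x) gsub("[\\s0-9]", "", paste(x, collapse = ""), perl = TRUE)
  records <- list()
  if (length(headers) == 0L) {
    seq <- clean(lines)
    if (!nzchar(seq)) stop(sprintf("no sequence in %s", path))
    id <- sub("\\.[^.]*$", "", basename(path))
    records[[1L]] <- genome_record(seq, id = id, topology = topology)
  } else {
    if (headers[1L] != 1L && nzchar(clean(lines[seq_len(headers[1L] - 1L)])))
      stop(sprintf("sequence before first FASTA header in %s", path))
    bounds <- c(headers, length(lines) + 1L)
    for (i in seq_along(headers)) {
      id <- sub("^>\\s*", "", lines[headers[i]])
      id <- strsplit(id, "\\s+")[[1L]][1L]
      body <- lines[seq(headers[i] + 1L, length.out = bounds[i + 1L] - headers[i] - 1L)]
      seq <- clean(body)
      if (!nzchar(seq)) stop(sprintf("no sequence under header '%s' in %s", id, path))
      records[[i]] <- genome_record(seq, id = id, topology = topology)
    }
  }
  records
}

#' Write genome records as FASTA
#'
#' @param genomes A `phage_genome` or list of them.
#' @param path Output path.
#' @param width Line width.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "phage_genome")) genomes <- list(genomes)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genomes) {
    writeLines(paste0(">", g$id), con)
    starts <- seq(1L, g$length, by = width)
    writeLines(substring(g$seq, starts, pmin(starts + width - 1L, g$length)), con)
  }
  invisible(path)
}

#' IUPAC-aware reverse complement
#'
#' Complements every IUPAC letter (Y<->R, S<->S, W<->W, K<->M, B<->V, D<->H,
#' N<->N) and reverses the string. An involution: `reverse_complement(
#' reverse_complement(s)) == s` for every IUPAC string.
#'
#' @param seq Nucleotide string over the IUPAC alphabet.
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(.as_seq(seq))
  .validate_alphabet(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Extract a subsequence (1-based, inclusive)
#'
#' @param genome Genome or string.
#' @param start,end 1-based inclusive bounds.
#' @param strand `"+"` returns the forward subsequence, `"-"` its reverse
#'   complement.
#' @export
subseq1 <- function(genome, start, end, strand = "+") {
  s <- .as_seq(genome)
  if (start < 1L || end > nchar(s) || start > end)
    stop(sprintf("interval %d-%d out of range for %d bp sequence", start, end, nchar(s)))
  x <- substr(s, start, end)
  if (strand == "-") reverse_complement(x) else x
}

# --- GFF3 -------------------------------------------------------------------

# Normalize heterogeneous feature tables (CDS calls, promoter hits,
# terminator candidates, motif hits) into GFF3 rows. Ordering is start, then
# type priority CDS < promoter < terminator < motif, so output is stable.
.gff_type_rank <- c(CDS = 1L, promoter = 2L, terminator = 3L, motif = 4L)

.as_gff_rows <- function(features) {
  if (is.data.frame(features)) features <- list(features)
  rows <- list()
  for (df in features) {
    if (is.null(df) || nrow(df) == 0L) next
    if (all(c("pos35", "pos10") %in% names(df))) {
      rows[[length(rows) + 1L]] <- data.frame(
        type = "promoter", start = df$pos35, end = df$pos10 + nchar_or(df$box10, 6L) - 1L,
        strand = df$strand, score = df$mm_total,
        note = sprintf("mm35=%d;mm10=%d;spacer=%d", df$mm35, df$mm10, df$spacer),
        stringsAsFactors = FALSE)
    } else if ("dg_stem" %in% names(df)) {
      rows[[length(rows) + 1L]] <- data.frame(
        type = "terminator", start = df$start, end = df$end,
        strand = df$strand, score = df$dg_stem,
        note = sprintf("stem=%d;loop=%d;u_score=%.3f", df$stem_len, df$loop_len, df$u_score),
        stringsAsFactors = FALSE)
    } else if ("pattern_name" %in% names(df)) {
      rows[[length(rows) + 1L]] <- data.frame(
        type = "motif", start = df$position,
        end = df$position + nchar(df$pattern) - 1L,
        strand = df$strand, score = df$mismatches,
        note = sprintf("pattern=%s", df$pattern_name), stringsAsFactors = FALSE)
    } else {
      note <- if ("label" %in% names(df)) sprintf("label=%s", df$label) else ""
      rows[[length(rows) + 1L]] <- data.frame(
        type = "CDS", start = df$start, end = df$end,
        strand = df$strand, score = NA_real_, note = note, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(type = character(), start = integer(), end = integer(),
                      strand = character(), score = numeric(), note = character()))
  out <- do.call(rbind, rows)
  out[order(out$start, .gff_type_rank[out$type]), , drop = FALSE]
}

nchar_or <- function(x, default) if (is.null(x)) default else nchar(x)

#' Write features as GFF3
#'
#' Emits a `##gff-version 3` file with 1-based inclusive coordinates and
#' stable zero-padded feature IDs derived from the genome id. Features are
#' ordered by start, ties broken CDS before promoter before terminator.
#'
#' @param genome The `phage_genome` the features belong to.
#' @param features A feature data frame or a list of them (CDS tables,
#'   promoter hits, terminator candidates, motif hits are all recognized).
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @export
write_gff3 <- function(genome, features, path, source = "phagechar") {
  stopifnot(inherits(genome, "phage_genome"))
  rows <- .as_gff_rows(features)
  if (nrow(rows) > 0L) {
    bad <- which(rows$start < 1L | rows$end > genome$length | rows$start > rows$end)
    if (length(bad) > 0L)
      stop(sprintf("feature %s %d-%d out of range [1, %d]",
                   rows$type[bad[1L]], rows$start[bad[1L]], rows$end[bad[1L]],
                   genome$length))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", genome$id, genome$length), con)
  if (nrow(rows) > 0L) {
    stem <- gsub("[^A-Za-z0-9]", "", genome$id)
    ids <- sprintf("%s_%02d", stem, seq_len(nrow(rows)))
    attrs <- sprintf("ID=%s", ids)
    extra <- nzchar(rows$note)
    attrs[extra] <- paste0(attrs[extra], ";", rows$note[extra])
    score <- ifelse(is.na(rows$score), ".", formatC(rows$score, format = "g"))
    writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t.\t%s",
                       genome$id, source, rows$type, rows$start, rows$end,
                       score, rows$strand, attrs), con)
  }
  invisible(path)
}

#' Minimal GenBank flat-file reader
#'
#' Reads the ORIGIN sequence block and plain (optionally `complement(a..b)`)
#' CDS feature intervals from a GenBank flat file. Joins and other composite
#' locations are not supported.
#'
#' @param path Path to a GenBank flat file.
#' @return A list with `genome` (a [genome_record()]) and `cds`
#'   (a data frame with columns `start`, `end`, `strand`).
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus) > 0L) strsplit(trimws(locus[1L]), "\\s+")[[1L]][2L] else
    sub("\\.[^.]*$", "", basename(path))
  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0L) stop("no ORIGIN block")
  endrec <- grep("^//", lines)
  endrec <- endrec[endrec > ori[1L]][1L]
  if (is.na(endrec)) endrec <- length(lines) + 1L
  seq <- gsub("[\\s0-9/]", "", paste(lines[(ori[1L] + 1L):(endrec - 1L)], collapse = ""),
              perl = TRUE)
  cds_lines <- grep("^\\s{4,}CDS\\s", lines, value = TRUE)
  loc <- trimws(sub("^\\s*CDS\\s+", "", cds_lines))
  strand <- ifelse(grepl("^complement", loc), "-", "+")
  loc <- gsub("complement\\(|\\)|<|>", "", loc)
  parts <- strsplit(loc, "\\.\\.")
  ok <- lengths(parts) == 2L
  cds <- data.frame(start = as.integer(vapply(parts[ok], `[`, "", 1L)),
                    end = as.integer(vapply(parts[ok], `[`, "", 2L)),
                    strand = strand[ok], stringsAsFactors = FALSE)
  list(genome = genome_record(seq, id = id), cds = cds[order(cds$start), , drop = FALSE])
}
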