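# Seeded synthetic phage-genome generator with a planted-feature ledger.
#
# The generator emulates the structure this package is built to analyse: a
# 20-60 kb linear dsDNA genome at a target GC fraction, tightly packed with
# unidirectional (occasionally overlapping) CDSs, with bipartite promoters
# planted at known mismatch counts, stem-loop + U-tract terminators, and
# degenerate restriction sites. Background is i.i.d.; every planted feature
# is recorded in a ground-truth ledger and is literally present at its
# ledger coordinates. Background is post-processed so that no accidental
# ORF above the mass threshold survives, which makes exact-interval CDS
# recovery testable.

#' Specification for a synthetic phage genome
#'
#' Defaults state the emulated world once: a 40-kb linear genome at GC
#' 0.545 packed with 40 forward-strand CDSs (a fifth of adjacent pairs
#' overlapping by 4 nt through the classic ATGA start/stop overlap), five
#' planted promoters at total mismatches {0,1,1,2,2}, ten terminators with
#' a 10-bp GC stem / 4-nt loop / 8-nt U-tract, and a handful of degenerate
#' restriction sites. CDS density is kept below the packing of a real phage
#' genome so that the planted span stays under ~70% of the genome, the
#' generator's satisfiability bound.
#'
#' @param length Genome length in nt.
#' @param target_gc Background GC fraction.
#' @param n_cds Number of planted CDSs.
#' @param cds_length_range CDS length range in nt (stop included); rounded
#'   to multiples of 3, minimum 150 (a 49-aa product, comfortably above the
#'   4-kDa default mass floor for any composition).
#' @param allow_overlap Permit planted 4-nt CDS overlaps.
#' @param overlap_fraction Fraction of adjacent CDS pairs overlapping.
#' @param strand_mode `"unidirectional"` (all `+`) or `"mixed"`.
#' @param n_promoters Number of planted promoters.
#' @param promoter_mismatches Integer vector (length `n_promoters`) of total
#'   mismatches (0-2) to realize; default `{0,1,1,2,2}` recycled.
#' @param promoter_spacers Spacer lengths (15-18); default sampled.
#' @param n_terminators Number of planted terminators.
#' @param terminator_stem,terminator_loop,terminator_tail Planted geometry.
#' @param sites Named integer vector: IUPAC pattern -> copies to plant.
#' @param gap_range Background gap between consecutive blocks, in nt.
#' @param min_mass_kda Mass threshold used when clearing accidental ORFs
#'   (should match the caller's ORF-calling threshold).
#' @param start_codons Start codons assumed by the clearing step.
#' @param seed Integer seed; fully determines the output.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(length = 40000L, target_gc = 0.545, n_cds = 40L,
                           cds_length_range = c(150L, 900L),
                           allow_overlap = TRUE, overlap_fraction = 0.2,
                           strand_mode = c("unidirectional", "mixed"),
                           n_promoters = 5L, promoter_mismatches = NULL,
                           promoter_spacers = NULL, n_terminators = 10L,
                           terminator_stem = 10L, terminator_loop = 4L,
                           terminator_tail = 8L,
                           sites = c(CGATCG = 5L, GGTACC = 2L),
                           gap_range = c(2L, 40L), min_mass_kda = 4.0,
                           start_codons = c("ATG", "GTG", "TTG"),
                           seed = 1L) {
  strand_mode <- match.arg(strand_mode)
  if (is.null(promoter_mismatches) && n_promoters > 0L)
    promoter_mismatches <- rep_len(c(0L, 1L, 1L, 2L, 2L), n_promoters)
  if (n_promoters > 0L) {
    stopifnot(length(promoter_mismatches) == n_promoters,
              all(promoter_mismatches >= 0L & promoter_mismatches <= 2L))
  }
  if (!is.null(promoter_spacers))
    stopifnot(all(promoter_spacers >= 15L & promoter_spacers <= 18L))
  structure(list(
    length = as.integer(length), target_gc = target_gc,
    n_cds = as.integer(n_cds),
    cds_length_range = pmax(as.integer(cds_length_range), 150L),
    allow_overlap = allow_overlap, overlap_fraction = overlap_fraction,
    strand_mode = strand_mode, n_promoters = as.integer(n_promoters),
    promoter_mismatches = as.integer(promoter_mismatches),
    promoter_spacers = promoter_spacers,
    n_terminators = as.integer(n_terminators),
    terminator_stem = as.integer(terminator_stem),
    terminator_loop = as.integer(terminator_loop),
    terminator_tail = as.integer(terminator_tail),
    sites = sites, gap_range = as.integer(gap_range),
    min_mass_kda = min_mass_kda, start_codons = start_codons,
    seed = as.integer(seed)), class = "synthetic_spec")
}

BASES <- c("A", "C", "G", "T")

.bg_probs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

.random_bases <- function(n, gc) {
  if (n <= 0L) return(character(0))
  sample(BASES, n, replace = TRUE, prob = .bg_probs(gc))
}

# Stop cassette: four sense-frame codons (Leu Ala Ser Tyr) that contain a
# stop codon in every alien reading frame (both forward shifts and all
# three reverse-strand offsets). Inserted every CASSETTE_PERIOD codons in
# planted CDS interiors, it bounds any alien open reading at ~17 codons,
# far below the 4-kDa product-mass floor — which is what makes
# exact-interval CDS recovery on synthetic genomes attainable at all.
STOP_CASSETTE <- c("CTA", "GCT", "AGC", "TAC")
CASSETTE_PERIOD <- 15L
CASSETTE_GC <- 0.5

# A random non-stop codon at the background composition; optional fixed
# first/third base (used for the overlap construction).
.random_codon <- function(gc, first = NULL, third = NULL) {
  repeat {
    b <- .random_bases(3L, gc)
    if (!is.null(first)) b[1L] <- first
    if (!is.null(third)) b[3L] <- third
    codon <- paste(b, collapse = "")
    if (!codon %in% STOP_CODONS) return(codon)
  }
}

# Realize an IUPAC pattern as a concrete sequence.
.realize_iupac <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  paste(vapply(chars, function(ch) {
    mask <- IUPAC_MASK[[ch]]
    opts <- BASES[bitwAnd(mask, c(1L, 2L, 4L, 8L)) != 0L]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1L)), collapse = "")
}

# Mutate `k` distinct positions of a concrete box to non-matching bases.
.mutate_box <- function(box, k) {
  chars <- strsplit(box, "", fixed = TRUE)[[1L]]
  if (k > 0L) {
    pos <- sample(length(chars), k)
    for (p in pos) chars[p] <- sample(setdiff(BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# --- block builders ---------------------------------------------------------
# A block is list(seq, type, meta). Coordinates inside meta are relative to
# the block start and resolved after placement.

.build_cds_chain <- function(lens, overlaps, gc, start_codons) {
  # lens: nt lengths (stop included) of the CDSs in one overlap chain;
  # overlaps[i] is TRUE when CDS i+1 overlaps CDS i by 4 nt (ATGA).
  #
  # Interior codons are drawn at a GC adjusted for the periodic stop
  # cassettes so the whole CDS still averages the target GC.
  cass_frac <- length(STOP_CASSETTE) / CASSETTE_PERIOD
  gc_cds <- min(max((gc - cass_frac * CASSETTE_GC) / (1 - cass_frac), 0.05), 0.95)
  pieces <- character(0)
  rel <- integer(0)       # relative start of each CDS (1-based within block)
  meta_cds <- list()
  cursor <- 0L
  for (i in seq_along(lens)) {
    ncod <- lens[i] %/% 3L
    over_up <- i < length(lens) && overlaps[i]      # tail feeds an overlap
    over_dn <- i > 1L && overlaps[i - 1L]           # head shares ATGA
    codons <- character(ncod)
    codons[1L] <- "ATG"                             # overlap needs ATG anyway
    free <- rep(TRUE, ncod)
    free[1L] <- FALSE
    for (k in seq(2L, ncod - 1L)) codons[k] <- .random_codon(gc_cds)
    if (over_dn) codons[2L] <- .random_codon(gc_cds, first = "A")
    if (over_up) {
      if (ncod < 8L) stop("CDS too short for overlap construction")
      codons[ncod - 2L] <- .random_codon(gc_cds, third = "T")
      codons[ncod - 1L] <- "AAA"
      codons[ncod] <- "TGA"
      free[c(ncod - 2L, ncod - 1L, ncod)] <- FALSE
    } else {
      codons[ncod] <- sample(STOP_CODONS, 1L)
      free[ncod] <- FALSE
    }
    # plant stop cassettes so no alien-frame ORF can nest inside the CDS
    k <- 4L
    while (k + length(STOP_CASSETTE) - 1L <= ncod - 3L) {
      idx <- k:(k + length(STOP_CASSETTE) - 1L)
      if (all(free[idx])) {
        codons[idx] <- STOP_CASSETTE
        free[idx] <- FALSE
      }
      k <- k + CASSETTE_PERIOD
    }
    body <- paste(codons, collapse = "")
    if (i == 1L) {
      pieces <- c(pieces, "TAA", body)   # in-frame cap upstream of the start
      cursor <- cursor + 3L
      rel <- c(rel, cursor + 1L)
      cursor <- cursor + lens[i]
    } else if (over_dn) {
      rel <- c(rel, cursor - 3L)         # ATG overlaps previous TGA by 4 nt
      pieces <- c(pieces, substring(body, 5L))
      cursor <- cursor + lens[i] - 4L
    } else {
      stop("non-overlapping CDS inside a chain")
    }
    meta_cds[[i]] <- list(len = lens[i], over_dn = over_dn, over_up = over_up,
                          free = free)
  }
  list(seq = paste(pieces, collapse = ""), type = "cds_chain",
       meta = list(rel_starts = rel, cds = meta_cds))
}

.build_promoter <- function(gc, mm_total, spacer) {
  mm35 <- sample(0:mm_total, 1L)
  mm10 <- mm_total - mm35
  b35 <- .mutate_box("TTGACA", mm35)
  b10 <- .mutate_box("TATAAT", mm10)
  sp <- paste(.random_bases(spacer, gc), collapse = "")
  list(seq = paste0(b35, sp, b10), type = "promoter",
       meta = list(mm35 = mm35, mm10 = mm10, mm_total = mm_total,
                   spacer = spacer))
}

.build_terminator <- function(gc, stem, loop, tail) {
  arm <- paste(sample(c("G", "C"), stem, replace = TRUE), collapse = "")
  repeat {   # loop whose outer bases do not pair (keeps geometry as planted)
    lp <- .random_bases(loop, gc)
    if (.pair_type(lp[1L], lp[loop], TRUE) == 0L) break
  }
  list(seq = paste0(arm, paste(lp, collapse = ""), reverse_complement(arm),
                    strrep("T", tail)),
       type = "terminator",
       meta = list(stem = stem, loop = loop, tail = tail))
}

.build_site <- function(pattern) {
  list(seq = .realize_iupac(pattern), type = "site",
       meta = list(pattern = toupper(pattern)))
}

# --- generator --------------------------------------------------------------

#' Generate a synthetic phage genome with a ground-truth ledger
#'
#' See [synthetic_spec()] for the stated world. Deterministic per seed:
#' the same spec yields a byte-identical genome and ledger.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `genome` (a [genome_record()], id
#'   `synth<seed>`) and `truth` (class `ground_truth`: data frames
#'   `cds`, `promoters`, `terminators`, `sites`).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  for (attempt in seq_len(10L)) {
    res <- try(.generate_once(spec), silent = TRUE)
    if (!inherits(res, "try-error")) return(res)
  }
  stop("generator failed after 10 attempts: ", attr(res, "condition")$message)
}

.generate_once <- function(spec) {
  gc <- spec$target_gc
  # --- build blocks ---
  cds_lens <- integer(0)
  if (spec$n_cds > 0L) {
    lens <- sample(seq(spec$cds_length_range[1L], spec$cds_length_range[2L]),
                   spec$n_cds, replace = TRUE)
    cds_lens <- (lens %/% 3L) * 3L
  }
  mixed <- spec$strand_mode == "mixed"
  overlaps <- rep(FALSE, max(spec$n_cds - 1L, 0L))
  if (spec$allow_overlap && !mixed && spec$n_cds > 1L)
    overlaps <- stats::runif(spec$n_cds - 1L) < spec$overlap_fraction
  # split CDS indices into overlap chains
  chains <- list()
  if (spec$n_cds > 0L) {
    cur <- 1L
    for (i in seq_len(spec$n_cds)) {
      if (i == spec$n_cds || !overlaps[i]) {
        chains[[length(chains) + 1L]] <- cur:i
        cur <- i + 1L
      }
    }
  }
  cds_blocks <- lapply(chains, function(idx) {
    b <- .build_cds_chain(cds_lens[idx], overlaps[idx[-length(idx)]], gc,
                          spec$start_codons)
    b$meta$strand <- "+"
    if (mixed && stats::runif(1L) < 0.5) {
      # mirror the whole block onto the minus strand
      lb <- nchar(b$seq)
      lens_k <- vapply(b$meta$cds, function(m) m$len, integer(1L))
      b$seq <- reverse_complement(b$seq)
      b$meta$rel_starts <- lb - (b$meta$rel_starts + lens_k - 1L) + 1L
      b$meta$strand <- "-"
    }
    b
  })
  other_blocks <- list()
  if (spec$n_promoters > 0L) {
    spacers <- spec$promoter_spacers
    if (is.null(spacers)) spacers <- sample(15:18, spec$n_promoters, replace = TRUE)
    for (i in seq_len(spec$n_promoters))
      other_blocks[[length(other_blocks) + 1L]] <-
        .build_promoter(gc, spec$promoter_mismatches[i], spacers[i])
  }
  if (spec$n_terminators > 0L)
    for (i in seq_len(spec$n_terminators))
      other_blocks[[length(other_blocks) + 1L]] <-
        .build_terminator(gc, spec$terminator_stem, spec$terminator_loop,
                          spec$terminator_tail)
  if (length(spec$sites) > 0L)
    for (p in names(spec$sites))
      for (k in seq_len(spec$sites[[p]]))
        other_blocks[[length(other_blocks) + 1L]] <- .build_site(p)

  # interleave: CDS chains keep their order; other blocks get random slots
  n_slots <- length(cds_blocks) + 1L
  slot_of <- if (length(other_blocks) > 0L)
    sample(n_slots, length(other_blocks), replace = TRUE) else integer(0)
  blocks <- list()
  for (s in seq_len(n_slots)) {
    for (j in which(slot_of == s)) blocks[[length(blocks) + 1L]] <- other_blocks[[j]]
    if (s <= length(cds_blocks)) blocks[[length(blocks) + 1L]] <- cds_blocks[[s]]
  }
  span <- sum(vapply(blocks, function(b) nchar(b$seq), integer(1L)))
  if (span > 0.7 * spec$length)
    stop(sprintf("unsatisfiable spec: planted span %d exceeds 70%% of length %d",
                 span, spec$length))
  gaps <- sample(seq(spec$gap_range[1L], spec$gap_range[2L]),
                 length(blocks), replace = TRUE)
  if (span + sum(gaps) > spec$length)
    stop("unsatisfiable spec: planted blocks plus minimal gaps exceed length")

  # --- assemble ---
  pieces <- character(0)
  cursor <- 0L
  placed <- list()
  for (i in seq_along(blocks)) {
    g <- gaps[i]
    pieces <- c(pieces, paste(.random_bases(g, gc), collapse = ""))
    cursor <- cursor + g
    b <- blocks[[i]]
    b$start <- cursor + 1L
    b$end <- cursor + nchar(b$seq)
    pieces <- c(pieces, b$seq)
    cursor <- b$end
    placed[[length(placed) + 1L]] <- b
  }
  pieces <- c(pieces, paste(.random_bases(spec$length - cursor, gc), collapse = ""))
  seqstr <- paste(pieces, collapse = "")

  # --- ledgers (coordinates now absolute) ---
  cds_rows <- list(); cds_meta <- list()
  prom_rows <- list(); term_rows <- list(); site_rows <- list()
  for (b in placed) {
    if (b$type == "cds_chain") {
      for (k in seq_along(b$meta$rel_starts)) {
        st <- b$start + b$meta$rel_starts[k] - 1L
        m <- b$meta$cds[[k]]
        strand_k <- b$meta$strand
        if (strand_k == "-") m$free[] <- FALSE  # redraw path is +-strand only
        cds_rows[[length(cds_rows) + 1L]] <- data.frame(
          label = "", start = st, end = st + m$len - 1L, strand = strand_k,
          nt_length = m$len, stringsAsFactors = FALSE)
        cds_meta[[length(cds_meta) + 1L]] <- c(m, list(start = st))
      }
    } else if (b$type == "promoter") {
      prom_rows[[length(prom_rows) + 1L]] <- data.frame(
        pos35 = b$start, pos10 = b$start + 6L + b$meta$spacer,
        spacer = b$meta$spacer, mm35 = b$meta$mm35, mm10 = b$meta$mm10,
        mm_total = b$meta$mm_total, strand = "+", stringsAsFactors = FALSE)
    } else if (b$type == "terminator") {
      hp_end <- b$end - b$meta$tail
      term_rows[[length(term_rows) + 1L]] <- data.frame(
        start = b$start, end = b$end, hairpin_start = b$start,
        hairpin_end = hp_end, stem_len = b$meta$stem, loop_len = b$meta$loop,
        strand = "+", stringsAsFactors = FALSE)
    } else if (b$type == "site") {
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        pattern_name = b$meta$pattern, pattern = b$meta$pattern,
        position = b$start, strand = "+", stringsAsFactors = FALSE)
    }
  }
  bind <- function(x, proto) if (length(x) > 0L) do.call(rbind, x) else proto
  truth <- list(
    genome_id = sprintf("synth%d", spec$seed),
    cds = bind(cds_rows, data.frame(label = character(), start = integer(),
                                    end = integer(), strand = character(),
                                    nt_length = integer())),
    promoters = bind(prom_rows, data.frame(pos35 = integer(), pos10 = integer(),
                                           spacer = integer(), mm35 = integer(),
                                           mm10 = integer(), mm_total = integer(),
                                           strand = character())),
    terminators = bind(term_rows, .empty_terminators()[
      c("start", "end", "hairpin_start", "hairpin_end", "stem_len",
        "loop_len", "strand")]),
    sites = bind(site_rows, data.frame(pattern_name = character(),
                                       pattern = character(),
                                       position = integer(),
                                       strand = character())),
    seed = spec$seed, spec = spec)
  if (nrow(truth$cds) > 0L)
    truth$cds$label <- sprintf("%s_cds%02d", truth$genome_id,
                               seq_len(nrow(truth$cds)))

  # protected intervals: every planted block span
  protected <- do.call(rbind, lapply(placed, function(b) c(b$start, b$end)))

  # --- clear accidental ORFs above the mass threshold ---
  seqstr <- .clear_accidental_orfs(seqstr, truth, cds_meta, protected,
                                   spec, gc)

  # --- rebalance background GC ---
  # Clearing writes AT-rich stop codons into background; flip background
  # bases toward the target and re-clear until both constraints hold.
  bg_mask <- rep(TRUE, nchar(seqstr))
  if (!is.null(protected) && nrow(protected) > 0L)
    for (i in seq_len(nrow(protected)))
      bg_mask[protected[i, 1L]:protected[i, 2L]] <- FALSE
  for (round in seq_len(6L)) {
    chars <- strsplit(seqstr, "", fixed = TRUE)[[1L]]
    delta <- spec$target_gc - mean(chars %in% c("G", "C"))
    if (abs(delta) <= 0.003) break
    k <- ceiling(abs(delta) * length(chars))
    pool <- if (delta > 0) which(bg_mask & chars %in% c("A", "T"))
            else which(bg_mask & chars %in% c("G", "C"))
    if (length(pool) == 0L) break
    flip <- sample(pool, min(k, length(pool)))
    chars[flip] <- sample(if (delta > 0) c("G", "C") else c("A", "T"),
                          length(flip), replace = TRUE)
    seqstr <- paste(chars, collapse = "")
    seqstr <- .clear_accidental_orfs(seqstr, truth, cds_meta, protected,
                                     spec, gc)
  }

  # --- verify planted promoters still score as planted ---
  if (nrow(truth$promoters) > 0L) {
    hits <- find_promoters(seqstr, max_total_mismatch = 2L)
    for (i in seq_len(nrow(truth$promoters))) {
      h <- hits[hits$pos10 == truth$promoters$pos10[i], , drop = FALSE]
      if (nrow(h) != 1L || h$mm_total != truth$promoters$mm_total[i])
        stop("planted promoter obscured by background; retrying")
    }
  }

  genome <- genome_record(seqstr, id = truth$genome_id)
  # finalize CDS products from the final sequence
  if (nrow(truth$cds) > 0L) {
    prot <- character(nrow(truth$cds))
    for (i in seq_len(nrow(truth$cds)))
      prot[i] <- translate_cds(genome, truth$cds$start[i], truth$cds$end[i],
                               truth$cds$strand[i], spec$start_codons)
    truth$cds$protein <- prot
    truth$cds$mass_kda <- vapply(prot, average_mass, numeric(1L), USE.NAMES = FALSE)
    truth$cds$pi <- vapply(prot, isoelectric_point, numeric(1L), USE.NAMES = FALSE)
  }
  # literal-presence audit of non-CDS features
  .verify_planted(genome, truth)
  class(truth) <- "ground_truth"
  list(genome = genome, truth = truth)
}

# Insert stops into background codons of unexpected ORFs (or redraw free
# codons of a planted CDS when an accidental ORF nests inside one) until the
# ORF caller finds exactly the planted set.
.clear_accidental_orfs <- function(seqstr, truth, cds_meta, protected, spec, gc) {
  in_protected <- function(a, b) {
    if (is.null(protected) || nrow(protected) == 0L) return(FALSE)
    any(a <= protected[, 2L] & b >= protected[, 1L])
  }
  tkey <- paste(truth$cds$start, truth$cds$end, truth$cds$strand)
  for (iter in seq_len(60L)) {
    found <- .enumerate_orfs(seqstr, spec$min_mass_kda, spec$start_codons,
                             "both")
    key <- paste(found$start, found$end, found$strand)
    unexpected <- found[!key %in% tkey, , drop = FALSE]
    if (nrow(unexpected) == 0L) {
      missing <- !tkey %in% key
      if (any(missing)) stop("planted CDS lost during clearing")
      return(seqstr)
    }
    # batch pass: one stop written into the first background codon of every
    # unexpected ORF (writes may interact across frames; the loop re-checks)
    for (i in seq_len(nrow(unexpected))) {
      o <- unexpected[i, ]
      codon_starts <- seq(o$start, o$end - 2L, by = 3L)
      bg <- codon_starts[!vapply(codon_starts, function(p)
        in_protected(p, p + 2L), logical(1L))]
      if (length(bg) > 0L) {
        # random position: deterministic midpoints can lock neighbouring
        # frames into a two-cycle where each write re-opens the other ORF
        p <- bg[sample.int(length(bg), 1L)]
        stopseq <- if (o$strand == "+") "TAA" else "TTA"
        substr(seqstr, p, p + 2L) <- stopseq
      } else {
        # nested inside planted blocks (should be precluded by the stop
        # cassettes): redraw the free codons of an overlapped CDS
        host <- which(truth$cds$start <= o$end & truth$cds$end >= o$start)
        if (length(host) == 0L)
          stop("accidental ORF cannot be cleared (no background codon)")
        m <- cds_meta[[host[1L]]]
        for (k in which(m$free)) {
          cd <- if (k == 2L && m$over_dn) .random_codon(gc, first = "A")
                else .random_codon(gc)
          p <- m$start + 3L * (k - 1L)
          substr(seqstr, p, p + 2L) <- cd
        }
        break  # re-enumerate before touching anything else
      }
    }
  }
  stop("accidental-ORF clearing did not converge")
}

# Literal-presence audit: every planted non-CDS feature must be verifiable
# by direct string inspection of the emitted genome.
.verify_planted <- function(genome, truth) {
  s <- genome$seq
  if (nrow(truth$promoters) > 0L) {
    for (i in seq_len(nrow(truth$promoters))) {
      p <- truth$promoters[i, ]
      mm <- iupac_mismatches("TTGACA", substr(s, p$pos35, p$pos35 + 5L)) +
            iupac_mismatches("TATAAT", substr(s, p$pos10, p$pos10 + 5L))
      if (mm != p$mm_total) stop("promoter ledger mismatch")
    }
  }
  if (nrow(truth$terminators) > 0L) {
    for (i in seq_len(nrow(truth$terminators))) {
      t <- truth$terminators[i, ]
      arm1 <- substr(s, t$hairpin_start, t$hairpin_start + t$stem_len - 1L)
      arm2 <- substr(s, t$hairpin_end - t$stem_len + 1L, t$hairpin_end)
      if (reverse_complement(arm1) != arm2) stop("terminator ledger mismatch")
    }
  }
  if (nrow(truth$sites) > 0L) {
    for (i in seq_len(nrow(truth$sites))) {
      st <- truth$sites[i, ]
      win <- substr(s, st$position, st$position + nchar(st$pattern) - 1L)
      if (iupac_mismatches(st$pattern, win) != 0L) stop("site ledger mismatch")
    }
  }
  invisible(TRUE)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s: %d CDSs, %d promoters, %d terminators, %d sites (seed %d)\n",
              x$genome_id, nrow(x$cds), nrow(x$promoters),
              nrow(x$terminators), nrow(x$sites), x$seed))
  invisible(x)
}

#' Write a ground-truth ledger to disk
#'
#' One TSV per feature class plus a JSON copy of the spec.
#'
#' @param truth A `ground_truth`.
#' @param dir Output directory (created if needed).
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cls in c("cds", "promoters", "terminators", "sites")) {
    df <- truth[[cls]]
    if (cls == "cds" && "protein" %in% names(df)) df$protein <- NULL
    utils::write.table(df, file.path(dir, paste0(cls, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(truth$spec[setdiff(names(truth$spec), "sites")],
                       file.path(dir, "spec.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Per-feature-class recovery report against a ground-truth ledger
#'
#' Matching rules: CDSs by exact interval and strand; promoters by -10 box
#' position and strand (with the count of hits whose mismatch total equals
#' the planted one reported as `n_exact_mm`); restriction-site hits by
#' pattern and position; terminators by >= 50% overlap between the reported
#' and planted hairpin intervals. Precision for motif-like classes is
#' verified by direct string inspection when the genome is supplied, so
#' accidental background hits are counted as correct detections rather than
#' false positives.
#'
#' @param outputs Named list with any of `cds`, `promoters`, `terminators`,
#'   `sites` (data frames as produced by the corresponding finders).
#' @param truth A `ground_truth`.
#' @param genome Optional genome for string-inspection precision.
#' @return Data frame: `class`, `n_truth`, `n_found`, `tp`, `sensitivity`,
#'   `precision`, `n_exact_mm` (promoters only, else `NA`).
#' @export
recovery_report <- function(outputs, truth, genome = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  for (nm in names(outputs)) {
    gid <- attr(outputs[[nm]], "genome_id")
    if (!is.null(gid) && gid != "genome" && gid != truth$genome_id)
      stop(sprintf("outputs$%s come from genome '%s', ledger is for '%s'",
                   nm, gid, truth$genome_id))
  }
  rows <- list()
  rep_row <- function(class, n_truth, n_found, tp, precision, n_exact_mm = NA_integer_) {
    data.frame(class = class, n_truth = n_truth, n_found = n_found, tp = tp,
               sensitivity = if (n_truth > 0L) tp / n_truth else NA_real_,
               precision = precision, n_exact_mm = n_exact_mm,
               stringsAsFactors = FALSE)
  }
  if (!is.null(outputs$cds)) {
    f <- outputs$cds; t <- truth$cds
    fkey <- paste(f$start, f$end, f$strand)
    tkey <- paste(t$start, t$end, t$strand)
    tp <- sum(tkey %in% fkey)
    rows[[length(rows) + 1L]] <- rep_row("cds", nrow(t), nrow(f), tp,
      if (nrow(f) > 0L) sum(fkey %in% tkey) / nrow(f) else NA_real_)
  }
  if (!is.null(outputs$promoters)) {
    f <- outputs$promoters; t <- truth$promoters
    fkey <- paste(f$pos10, f$strand)
    tkey <- paste(t$pos10, t$strand)
    tp <- sum(tkey %in% fkey)
    exact <- 0L
    for (i in seq_len(nrow(t))) {
      h <- f[f$pos10 == t$pos10[i] & f$strand == t$strand[i], , drop = FALSE]
      if (nrow(h) > 0L && h$mm_total[1L] == t$mm_total[i]) exact <- exact + 1L
    }
    prec <- NA_real_
    if (!is.null(genome) && nrow(f) > 0L) {
      s <- .as_seq(genome)
      ok <- vapply(seq_len(nrow(f)), function(i) {
        mm <- iupac_mismatches(f$box35[i], substr(s, f$pos35[i],
                                                  f$pos35[i] + nchar(f$box35[i]) - 1L)) +
              iupac_mismatches(f$box10[i], substr(s, f$pos10[i],
                                                  f$pos10[i] + nchar(f$box10[i]) - 1L))
        mm == f$mm_total[i]
      }, logical(1L))
      prec <- mean(ok)
    }
    rows[[length(rows) + 1L]] <- rep_row("promoters", nrow(t), nrow(f), tp,
                                         prec, exact)
  }
  if (!is.null(outputs$sites)) {
    f <- outputs$sites; t <- truth$sites
    fkey <- paste(f$pattern_name, f$position)
    tkey <- paste(t$pattern_name, t$position)
    tp <- sum(tkey %in% fkey)
    prec <- NA_real_
    if (!is.null(genome) && nrow(f) > 0L) {
      s <- .as_seq(genome)
      ok <- vapply(seq_len(nrow(f)), function(i) {
        pat <- if (f$strand[i] == "+") f$pattern[i] else
          reverse_complement(f$pattern[i])
        win <- substr(s, f$position[i], f$position[i] + nchar(pat) - 1L)
        iupac_mismatches(pat, win) <= f$mismatches[i]
      }, logical(1L))
      prec <- mean(ok)
    }
    rows[[length(rows) + 1L]] <- rep_row("sites", nrow(t), nrow(f), tp, prec)
  }
  if (!is.null(outputs$terminators)) {
    f <- outputs$terminators; t <- truth$terminators
    ovl50 <- function(a1, a2, b1, b2) {
      ov <- pmin(a2, b2) - pmax(a1, b1) + 1L
      ov >= 0.5 * (b2 - b1 + 1L)
    }
    tp <- 0L
    for (i in seq_len(nrow(t)))
      if (nrow(f) > 0L && any(ovl50(f$hairpin_start, f$hairpin_end,
                                    t$hairpin_start[i], t$hairpin_end[i])))
        tp <- tp + 1L
    fp <- 0L
    if (nrow(f) > 0L) {
      matched <- vapply(seq_len(nrow(f)), function(i)
        nrow(t) > 0L && any(ovl50(rep(f$hairpin_start[i], nrow(t)),
                                  rep(f$hairpin_end[i], nrow(t)),
                                  t$hairpin_start, t$hairpin_end)),
        logical(1L))
      fp <- sum(!matched)
    }
    rows[[length(rows) + 1L]] <- rep_row("terminators", nrow(t), nrow(f), tp,
      if (nrow(f) > 0L) (nrow(f) - fp) / nrow(f) else NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
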