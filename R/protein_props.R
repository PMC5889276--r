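# Protein physical properties: average molecular mass and theoretical
# isoelectric point from residue composition.

# Average (not monoisotopic) residue masses in Da; the choice matches how
# annotation tables report predicted polypeptide weights.
AVERAGE_RESIDUE_MASS <- c(
  G = 57.0519,  A = 71.0788,  S = 87.0782,  P = 97.1167,  V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
WATER_MASS <- 18.01524

#' Average molecular mass of a protein
#'
#' Sum of average residue masses plus one water, in kDa. Full precision is
#' returned; tabular reports round to 0.1 kDa.
#'
#' @param protein Amino-acid string over the 20 canonical letters.
#' @return Mass in kDa.
#' @export
average_mass <- function(protein) {
  if (!is.character(protein) || length(protein) != 1L || !nzchar(protein))
    stop("protein must be a nonempty amino-acid string")
  chars <- strsplit(toupper(protein), "", fixed = TRUE)[[1L]]
  m <- AVERAGE_RESIDUE_MASS[chars]
  if (anyNA(m)) {
    i <- which(is.na(m))[1L]
    stop(sprintf("non-canonical amino acid '%s' at position %d", chars[i], i))
  }
  (sum(m) + WATER_MASS) / 1000
}

#' pKa sets for isoelectric-point calculation
#'
#' The default `"Bjellqvist"` set is the ExPASy convention: side-chain pKa
#' for C, D, E, H, K, R, Y; residue-specific N-terminal pKa; C-terminal pKa
#' with D/E adjustments. An `"EMBOSS"` alternative is provided for
#' sensitivity checks. Individual values can be overridden.
#'
#' @param name `"Bjellqvist"` (default) or `"EMBOSS"`.
#' @param side,nterm,cterm Optional named numeric vectors overriding entries
#'   of the chosen set.
#' @return List of class `pka_set` with fields `name`, `side`,
#'   `nterm_default`, `nterm_by_residue`, `cterm_default`,
#'   `cterm_by_residue`.
#' @export
pka_set <- function(name = c("Bjellqvist", "EMBOSS"),
                    side = NULL, nterm = NULL, cterm = NULL) {
  name <- match.arg(name)
  if (name == "Bjellqvist") {
    out <- list(
      name = name,
      side = c(C = 9.00, D = 4.05, E = 4.45, H = 5.98, K = 10.00,
               R = 12.00, Y = 10.00),
      nterm_default = 7.50,
      nterm_by_residue = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36,
                           T = 6.82, V = 7.44, E = 7.70, G = 7.50),
      cterm_default = 3.55,
      cterm_by_residue = c(D = 4.55, E = 4.75)
    )
  } else {
    out <- list(
      name = name,
      side = c(C = 8.50, D = 3.90, E = 4.10, H = 6.50, K = 10.80,
               R = 12.50, Y = 10.10),
      nterm_default = 8.60, nterm_by_residue = numeric(0),
      cterm_default = 3.60, cterm_by_residue = numeric(0)
    )
  }
  if (!is.null(side)) out$side[names(side)] <- side
  if (!is.null(nterm)) {   # a flat override replaces the per-residue table
    out$nterm_default <- nterm
    out$nterm_by_residue <- numeric(0)
  }
  if (!is.null(cterm)) {
    out$cterm_default <- cterm
    out$cterm_by_residue <- numeric(0)
  }
  bad <- c(out$side, out$nterm_default, out$cterm_default)
  if (any(bad <= 0 | bad >= 14)) stop("pKa values must lie in (0, 14)")
  structure(out, class = "pka_set")
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch composition model: positive groups (N-terminus, H,
#' K, R) contribute `1/(1 + 10^(pH - pKa))`; negative groups (C-terminus,
#' D, E, C, Y) contribute `-1/(1 + 10^(pKa - pH))`. Strictly decreasing in
#' pH, so the isoelectric point is a unique root.
#'
#' @param protein Amino-acid string.
#' @param pH pH value (vectorized).
#' @param pka A [pka_set()].
#' @return Net charge (same length as `pH`).
#' @export
net_charge <- function(protein, pH, pka = pka_set()) {
  chars <- strsplit(toupper(protein), "", fixed = TRUE)[[1L]]
  counts <- table(factor(chars, levels = names(AVERAGE_RESIDUE_MASS)))
  pos_pka <- c(.term_pka(chars[1L], pka, "n"),
               rep(pka$side[["H"]], counts[["H"]]),
               rep(pka$side[["K"]], counts[["K"]]),
               rep(pka$side[["R"]], counts[["R"]]))
  neg_pka <- c(.term_pka(chars[length(chars)], pka, "c"),
               rep(pka$side[["D"]], counts[["D"]]),
               rep(pka$side[["E"]], counts[["E"]]),
               rep(pka$side[["C"]], counts[["C"]]),
               rep(pka$side[["Y"]], counts[["Y"]]))
  vapply(pH, function(p) {
    sum(1 / (1 + 10^(p - pos_pka))) - sum(1 / (1 + 10^(neg_pka - p)))
  }, numeric(1L))
}

.term_pka <- function(res, pka, which) {
  if (which == "n") {
    if (res %in% names(pka$nterm_by_residue)) pka$nterm_by_residue[[res]]
    else pka$nterm_default
  } else {
    if (res %in% names(pka$cterm_by_residue)) pka$cterm_by_residue[[res]]
    else pka$cterm_default
  }
}

#' Theoretical isoelectric point
#'
#' The pH at which [net_charge()] is zero, found by bisection on [0, 14].
#' Composition-only: residue order does not matter (beyond the identity of
#' the two terminal residues, which select terminal pKa values).
#'
#' @param protein Nonempty amino-acid string.
#' @param pka A [pka_set()].
#' @param tol Bisection tolerance on pH (default 0.01).
#' @return pI as a pH value.
#' @export
isoelectric_point <- function(protein, pka = pka_set(), tol = 0.01) {
  if (!nzchar(protein)) stop("protein must be nonempty")
  lo <- 0; hi <- 14
  # net_charge is strictly decreasing: positive at pH 0, negative at pH 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(protein, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Machine-readable CDS property table
#'
#' Formats a CDS feature set the way curated annotation tables print it:
#' label, nt length, location, strand, aa length, mass in kDa (1 decimal),
#' pI (2 decimals), ordered by start.
#'
#' @param features CDS data frame (from [find_orfs()] or
#'   [cds_from_table()]).
#' @return Data frame with character-formatted `mass_kda` and `pi` columns.
#' @export
cds_table <- function(features) {
  if (nrow(features) == 0L)
    return(data.frame(label = character(), nt_length = integer(),
                      location = character(), strand = character(),
                      aa_length = integer(), mass_kda = character(),
                      pi = character(), stringsAsFactors = FALSE))
  f <- features[order(features$start), , drop = FALSE]
  data.frame(
    label = f$label, nt_length = f$nt_length,
    location = sprintf("%d-%d", f$start, f$end), strand = f$strand,
    aa_length = f$aa_length,
    mass_kda = sprintf("%.1f", f$mass_kda),
    pi = sprintf("%.2f", f$pi),
    stringsAsFactors = FALSE)
}
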