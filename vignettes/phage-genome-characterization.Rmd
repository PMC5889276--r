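---
title: "Methods: phage genome characterization with phagechar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phage genome characterization with phagechar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models behind
each analysis stage, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where the problem left room. Nothing here states an empirical result
that the test suite or the acceptance script does not itself compute.

## Setting

The package targets the desk half of a phage genome project: a single
assembled linear dsDNA genome of a few tens of kilobases — the motivating
case is a thermophilic *Geobacillus* siphophage whose 47.7-kb genome is
tightly packed with same-strand genes — to be annotated for coding
content, regulatory signals and composition without any wet-lab input.
All coordinates are 1-based and inclusive at both ends, matching how
curated annotation tables print intervals; conversion to other conventions
happens only at serialization boundaries, because mixed conventions are
where off-by-one bugs live.

## ORF/CDS calling

In each of the six reading frames, stop codons partition the frame into
stop-free stretches. Each stop closes at most one candidate CDS: from the
most upstream allowed start codon (default ATG/GTG/TTG, the usual set for
*Bacillus*-group phage annotation) after the previous in-frame stop,
through the closing stop. The stop codon is counted inside the interval
and the nucleotide length, so `aa_length = nt_length/3 - 1`; this
convention is forced by curated tables in which a 567-nt CDS yields a
188-aa protein. Translation uses bacterial table 11, with any configured
initiator translated as Met.

The only filter is a product-mass floor, default **4 kDa** (average
masses), the conventional "polypeptides of 4 kDa or larger" census
threshold. There is no coding-potential scoring: on real genomes the
caller over-reports relative to a curated annotation (alien-frame ORFs are
reported whenever they clear the mass floor), which is why the package
also ships an importer path (`read_cds_table()` / `cds_from_table()` /
`table_concordance()`) — coordinates in, recomputed products out — as the
reference path for validating a genome against a curated table.

A brute-force enumerator over every (frame, start, stop) triple serves as
the test oracle; raising the mass floor is tested to only ever remove
calls.

## Protein properties

Average (not monoisotopic) residue masses plus one water, reported in kDa;
tabular output rounds to 0.1 kDa, matching annotation-table precision.

Theoretical pI solves `Q(pH) = 0` where Q is the Henderson–Hasselbalch
net charge: positive groups (N-terminus, His, Lys, Arg) contribute
`1/(1+10^(pH-pKa))`, negative groups (C-terminus, Asp, Glu, Cys, Tyr)
contribute `-1/(1+10^(pKa-pH))`. Q is strictly decreasing in pH, so the
root is unique; bisection on [0, 14] converges to the default tolerance of
0.01 pH units in ~11 steps. The default pKa set is **Bjellqvist** as
implemented by ExPASy, including residue-specific N-terminal pKa values
and the Asp/Glu C-terminal adjustments; an EMBOSS set is included for
sensitivity checks, and any value can be overridden (a flat terminal
override deliberately clears the residue-specific table, so toy symmetric
sets behave as expected). The test oracle is an independently coded
10^5-point grid scan of Q.

## Degenerate motif scanning

IUPAC letters compile to 4-bit base masks; a pattern position matches a
genome position when the masks intersect, making Hamming distance under
degeneracy well defined. Scanning is O(pattern × genome) with vectorized
per-offset comparison — no seeding heuristics, so the scanner is exact and
directly comparable to an all-windows oracle.

Two conventions worth stating:

* **Ambiguity in the genome matches nothing** by default (conservative
  counting; even pattern N fails against genome N), with a permissive
  flag.
* **Site counting**: for an IUPAC-palindromic recognition sequence
  (pattern equals its IUPAC-aware reverse complement, e.g. GATC, CGATCG,
  CYCGRG) the forward-strand match count already enumerates all sites;
  otherwise the count is the union of forward positions of matches on
  either strand. This is what makes "0 sites" claims for non-palindromic
  enzymes (e.g. GsaI CCCAGC) well defined.

## Bipartite promoter search

The σ70 consensus is two hexamers, −35 `TTGACA` and −10 `TATAAT`,
separated by a spacer of 15–18 nt measured strictly between the boxes.
The mismatch budget (default **2**) is *shared* across both boxes — the
phrase "allowing a 2-bp mismatch" in the motivating study reads as a
whole-consensus budget, not per box. All (pos35, spacer) placements within
budget are enumerated, then collapsed to one hit per −10 position keeping
the minimal total mismatch count (tie: smallest spacer), because one −10
box reachable through several compatible spacers is one promoter, and the
−10 is what fixes the transcription start.

Scanning defaults to the forward strand only: in a genome whose genes all
point one way, promoters serve that direction; a both-strand flag exists
and reports reverse hits in forward coordinates. Widening the budget or
the spacer range is tested to never remove a hit.

## Rho-independent terminator detection

The paper-scale analysis this replaces used a third-party server (ARNold);
the package detects terminators natively and declares its own thresholds.

**Hairpin enumeration.** For every loop placement (loop 3–10 nt) the stem
extends outward pair by pair — Watson–Crick, or G·T as a weak wobble pair
— allowing at most one non-complementary pair, up to 30 pairs. Both stem
ends must be real pairs: outer mismatches are trimmed, and a mismatch
adjacent to the loop disqualifies the register (it is just a bigger loop).
A hairpin is reported only if maximal (the loop cannot shrink by another
pair within the allowed range), which keeps one record per register.

**Energy model.** The stem score is the standard duplex decomposition:
initiation (+4.09 kcal/mol) plus published RNA nearest-neighbor stack
terms for consecutive Watson–Crick pairs (applied to the transcribed
strand, DNA letters standing for RNA), a +0.45 terminal penalty per A·U or
G·U closing pair, a flat −1.3 for any stack touching a wobble pair, and
+1.7 for an internal 1×1 mismatch (which also interrupts stacking). No
loop entropy term is included — geometry is filtered separately — so the
initiation term effectively stands in for the loop penalty, and the
default threshold **ΔG ≤ −8 kcal/mol** approximates the conventional
full-hairpin criterion. An early version without initiation let random
5-bp GC stems pass wholesale; the term was added on model-fidelity
grounds.

**U-tract.** `u_score` is the T fraction of the fixed 8-nt window 3′ of
the hairpin (the classic intrinsic-terminator heuristic); candidates need
**u_score ≥ 0.5**. A hairpin whose window would run past the genome end is
rejected as "truncated tail".

**Register search.** A maximal inverted repeat routinely over-extends its
3′ arm into its own U-tract (U pairs A, and G as a wobble), leaving no
tail to score. Each hairpin is therefore re-scored at every outer-trimmed
register down to the minimum stem, and the most stable register passing
both filters is kept. Overlapping survivors collapse to the lowest-ΔG one.

Because the thresholds are declared package defaults rather than a
reproduction of ARNold, the terminator count on any real genome is
reported as informational, and validation is property-based: planted
terminators in synthetic genomes must be recovered (≥50% hairpin overlap),
and every reported candidate must be independently re-verifiable from the
raw sequence. Accidental background candidates that genuinely satisfy the
thresholds are counted as correct detections by the oracle, not as false
positives — in i.i.d. background at GC 0.545 such hairpins occur at a few
per 10 kb, which is a property of the stated thresholds, not of the
implementation.

## Composition profiles

Global GC excludes ambiguity letters from numerator and denominator
(warning above 0.1% ambiguous). The window profile (defaults **window
500, step 100** — the source analysis used a web calculator's unstated
defaults, so these are declared package constants) reports per-window GC
and skew `(G−C)/(G+C)` on the forward strand, centers at the floored
window midpoint; zero-GC windows carry skew 0 with an explicit flag rather
than NaN. Extreme-region calling collapses maximal runs of windows at or
beyond a threshold (defaults 0.62 / 0.28) to the center of the run's most
extreme window. Positional comparison to published extreme-GC coordinates
is inspection-only, since the original window size is unknown.

## The synthetic-genome generator

The generator states one world and sticks to it: a linear genome
(default 40 kb) at **GC 0.545**, packed with forward-strand CDSs separated
by 2–40 nt gaps, a fifth of adjacent pairs overlapping by 4 nt through the
classic `ATGA` stop/start overlap, five planted promoters at total
mismatches {0,1,1,2,2}, ten terminators with a 10-bp GC stem, 4-nt loop
and 8-nt U-tract, and a handful of concrete realizations of degenerate
restriction sites. CDS density is kept below a real packed phage genome's
(~40% vs >90% coding) to respect the generator's satisfiability bound
(planted span ≤ 70% of length). Everything is driven by one seed;
identical seeds give byte-identical genomes and ledgers.

Two deliberate deviations from a pure i.i.d. background make exact
recovery testable at all:

* **Stop cassettes.** A CDS interior drawn uniformly at random *will*
  contain nested open readings above 4 kDa in alien frames once it is a
  few hundred nt long, so exact-interval recovery would be unattainable.
  Interiors therefore carry the 4-codon cassette `CTA GCT AGC TAC` every
  15 codons — sense-frame Leu-Ala-Ser-Tyr, but a stop codon in *every*
  alien frame (both forward shifts and all three reverse offsets) — which
  bounds any alien reading at ~17 codons, below the 4-kDa floor for any
  composition. Remaining interior codons are drawn at a GC adjusted so the
  CDS still averages the target GC.
* **Background clearing and GC rebalancing.** Accidental ORFs above the
  mass floor that remain (spanning background, or crossing block edges)
  are destroyed by writing stop codons into background codons of the
  offending frame, at randomized positions (deterministic midpoints can
  lock two neighbouring frames into a two-cycle). Because stops are
  AT-rich this depresses background GC, so background bases are then
  flipped toward the target and the clearing re-checked, alternating until
  both constraints hold (GC within 0.003 of target before the 70%-density
  cap, and no unexpected ORF).

Each planted CDS is preceded by an in-frame `TAA` cap with the planted ATG
immediately after it, which pins the caller's "most upstream start" to the
planted start. The 4-nt overlap construction fixes the upstream CDS's last
codons (`..T | AAA | TGA`) so the downstream `ATG` overlaps the stop as
`ATGA` and still sees an in-frame stop just upstream. Planted promoters
are re-verified after assembly: if background accidentally offers the same
−10 box a better −35, the whole genome is regenerated (the ledger's
mismatch counts must be what a scanner recovers). Planted terminator loops
are drawn so their outer bases do not pair, keeping the planted geometry
the maximal register.

What the generator does **not** emulate: codon usage, Markov structure,
GC skew trends, repeats, tRNAs, or modified bases. A green recovery test
therefore establishes that the scanners implement their definitions
exactly on sequences with realistic composition and packing — not that
the thresholds are well calibrated for any particular real genome.

## Reference-data checks and their limits

The package bundles the curated 81-CDS annotation table of the
*Geobacillus* phage TP-84 (GenBank KY565347.1) transcribed into TSV, and
asserts its structural invariants: 81 rows, all forward-strand, and
`aa = nt/3 − 1` in every row. Two transcription-time findings are flagged
rather than asserted: one row (TP84_43) prints a length of 309 nt against
a 310-nt interval, and the prose "largest gap 265 bp" conflicts with the
printed coordinates, which give 365 nt between TP84_55 and TP84_56 — the
package reports the coordinate-derived value.

The genome sequence itself is not redistributable here, so the
genome-level acceptance checks (length 47,703 bp; GC 54.5%; GATC 743,
CGATCG 59, GGATCC/CYCGRG/CCCAGC 0; five promoter hits; per-row mass within
0.1 kDa and pI within 0.05 for ≥75/81 rows) are implemented as tests that
run against a user-supplied FASTA at `tp84_genome_path()` and *fail with
an explanatory message* when it is absent. They are deliberately not
skipped: an environment that cannot obtain the genome should see exactly
which published numbers were not re-verified.

## Numerical and interface choices

* Ties everywhere break toward the smaller coordinate (GFF3 ordering also
  ranks CDS before promoter before terminator at equal starts).
* pI bisection tolerance 0.01 pH; report precision 0.01. Mass reported at
  0.1 kDa, full precision internally.
* Pipeline TSV/JSON outputs use fixed decimal formats per column so reruns
  are byte-identical and diffable; `summary.json` embeds an MD5 of the
  configuration and the package version.
* Configuration files are JSON (`read_config()`), not YAML: the target
  runtime has no YAML parser available offline, and JSON round-trips
  through `jsonlite` loss-free. TSV pattern registries are supported.
* Headerless "bare" sequence text (supplementary-file style, with line
  numbers and whitespace) is accepted by `read_fasta()`, with the file
  stem as the record id. `U` is mapped to `T` with a warning; lowercase is
  uppercased silently; anything outside the 15-letter IUPAC alphabet is an
  error naming the first bad offset.
* Topology is recorded (`linear` default) but scanning is linear-only;
  circular wrap-around scanning is out of scope.

## Known limitations

* The ORF caller has no coding-potential model; on real genomes it
  over-calls relative to curated annotations, by design.
* The terminator energy model is stem-only with constant wobble and
  mismatch terms; it ranks hairpins sensibly but is not a folding engine,
  and its absolute ΔG values should not be compared with full
  thermodynamic predictions.
* The promoter model is consensus-plus-mismatch, not a PWM; it cannot
  rank two hits with equal mismatch counts.
* GenBank reading is limited to the ORIGIN block and simple
  `a..b` / `complement(a..b)` CDS locations.
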