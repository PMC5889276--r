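# phagechar

Desk-side characterization of small (20–60 kb) double-stranded DNA
bacteriophage genomes, of the kind sequenced from thermophilic
*Geobacillus* hosts: given one genome FASTA, the package calls and
translates CDSs, tabulates protein properties, screens restriction sites,
searches for host-type promoters, detects intrinsic terminators, and
profiles base composition — and it ships a seeded synthetic-genome
generator with a planted-feature ledger so that every stage is testable
offline, without downloading anything.

## What it computes

* **ORF/CDS calling** under bacterial translation table 11 (alternative
  initiators GTG/TTG read as Met). In each reading frame, each stop codon
  closes at most one CDS: the longest open reading from the most upstream
  start codon after the previous in-frame stop, stop codon included in the
  interval (so `aa_length = nt_length/3 − 1`). Products lighter than a mass
  floor (default 4 kDa, average masses) are dropped.
* **Protein properties**: average molecular weight (residue masses + one
  water) and theoretical pI — the unique root of the Henderson–Hasselbalch
  net charge Q(pH), found by bisection under the Bjellqvist/ExPASy pKa set
  (swappable).
* **Restriction screening** with IUPAC-degenerate recognition sequences
  (e.g. Gst1588I `CYCGRG`): distinct genomic site positions, with
  IUPAC-palindromic sites counted once from the forward strand and
  non-palindromic sites as the union over both strands.
* **σ70-type bipartite promoter search**: −35 box (`TTGACA`) and −10 box
  (`TATAAT`) separated by a 15–18 nt spacer, with a *shared* mismatch
  budget (default 2) across both boxes, deduplicated to one hit per −10
  box.
* **Rho-independent terminator detection**, natively: maximal
  inverted-repeat hairpins (stem 4–30 bp, loop 3–10 nt, ≤1 mismatch, G·U
  wobble allowed), scored with a nearest-neighbor stem free energy
  (initiation + published RNA stack terms + terminal A·U and internal
  mismatch penalties) and a U-tract score (T fraction of the 8 nt
  downstream); kept if ΔG ≤ −8 kcal/mol and U-score ≥ 0.5.
* **Composition profiles**: global GC, sliding-window GC and GC skew
  `(G−C)/(G+C)` (window 500, step 100), and collapsed extreme-GC region
  calls (≥62% / ≤28%).
* **Packing statistics**: strand census, intergenic gaps
  (`start(next) − end(prev) − 1`; negative = overlap), overlap count,
  largest gap.

All coordinates everywhere are 1-based and inclusive at both ends.

## Worked example

```r
library(phagechar)

sim <- generate_genome(synthetic_spec(length = 20000, n_cds = 18,
                                      n_promoters = 5, n_terminators = 4,
                                      sites = c(CGATCG = 3L), seed = 42))
sim$genome
#> <phage_genome> synth42: 20000 bp, linear

cds <- find_orfs(sim$genome)
head(cds_table(cds), 4)
#>        label nt_length  location strand aa_length mass_kda    pi
#> 1 synth42_01       708    35-742      +       235     25.5  9.40
#> 2 synth42_02       468  776-1243      +       155     16.7 10.44
#> 3 synth42_03       300 1240-1539      +        99     11.0  9.40
#> 4 synth42_04       222 1625-1846      +        73      8.1  9.10

packing_profile(cds)
#> <packing_profile> 18 features (+18/-0), 3 overlaps
#>   largest gap: 186 nt between synth42_11 and synth42_12

round(100 * global_gc(sim$genome), 1)   # percent GC
#> [1] 54.4
count_recognition_sites(sim$genome, "GATC")
#> [1] 61

head(find_promoters(sim$genome)[, c("pos35", "pos10", "spacer", "mm_total")], 3)
#>   pos35 pos10 spacer mm_total
#> 1  1553  1577     18        2
#> 2  1885  1908     17        0
#> 3  2326  2350     18        1

head(find_terminators(sim$genome)[, c("hairpin_start", "hairpin_end",
                                      "stem_len", "dg_stem", "u_score")], 3)
#>   hairpin_start hairpin_end stem_len dg_stem u_score
#> 1          1589        1610        6  -11.47     0.5
#> 2          2715        2738       10  -23.61     1.0
#> 3          3601        3624       10  -23.93     1.0

recovery_report(list(cds = cds), sim$truth, sim$genome)
#>   class n_truth n_found tp sensitivity precision n_exact_mm
#> 1   cds      18      18 18           1         1         NA
```

Every planted CDS was recovered at its exact interval; the CDS table mirrors
curated annotation tables (mass to 0.1 kDa, pI to 0.01). A full report
directory (GFF3, TSV tables, `summary.json`) comes from
`run_pipeline(genome, out_dir)`; a command-line front end with
`annotate`/`scan`/`terminators`/`composition`/`protein-table`/`simulate`/
`validate` subcommands is installed under `exec/phagechar`.

## Limitations

The detector thresholds for terminators are declared package defaults, not
a reproduction of ARNold (Erpin + RNAmotif), which the original TP-84 study
used; the TP-84 terminator count is therefore informational. Likewise the
published extreme-GC window coordinates depend on an unstated window size
and are reported for inspection, not asserted. See the methods vignette
(`vignettes/phage-genome-characterization.Rmd`) for the full model account.
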