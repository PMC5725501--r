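# boxascan

Comparative-genomics screening for **BoxA antitermination elements** in
bacterial genomes.

BoxA is a short RNA element bound by the NusB/NusE proteins in nascent
transcripts. It is classically found upstream of rRNA operons, but perfect
matches to the γ-proteobacterial consensus

```
5'-G Y T C T T T A A N A-3'     (Y = C/T, N = any base; 8 concrete 11-mers)
```

also occur just upstream of protein-coding genes — most prominently *suhB* —
where they mediate Nus-factor regulation. `boxascan` implements the screen
for such elements and its companion analyses:

* **Motif scan** — all occurrences of an IUPAC degenerate pattern on both
  strands of a genome, by per-position set membership (a genomic `N` never
  counts as a match: a perfect consensus match cannot be asserted over an
  unknown base).
* **Upstream screen** — keep motif hits lying in the 50-nt window
  immediately upstream of an annotated gene start, on the gene's strand.
  A hit–gene pair is retained when the whole motif fits in the window
  (`containment` mode, gap ≤ 50 − 11 = 39 nt) or, under the looser `gap`
  mode, when the gap itself is ≤ 50 nt. Counting is per distinct motif
  locus, not per hit–gene pair.
* **Genus-level aggregation** — gene functions downstream of hits are
  credited to a genus at most once, regardless of how many species, strains
  or loci support them. This controls the heavy over-representation of some
  genera among sequenced genomes.
* **Conservation track** — per-column percent match of an upstream-region
  multiple alignment to a reference row:
  `pct = 100 × (n_match + 1) / n_rows`, the "+1" accounting for the
  reference sequence itself (with 19 non-reference species this is exactly
  the +1-then-divide-by-20 percentage).
* **Rut-like composition** — Rho-utilization (Rut) sites are
  pyrimidine-rich and G-poor; the module counts bases over printed 1-based
  intervals and slides a thresholded window (defaults: 21 nt, ≥ 16
  pyrimidines, ≤ 1 G) to flag candidate segments.
* **Synthetic genomes** — a generator that plants consensus matches at
  controlled gaps and one-mismatch decoys into annotated genomes, with a
  truth table, so the whole pipeline is testable offline.

## Worked example

```r
library(boxascan)

sim <- simulate_genomes(sim_config(
  seed = 20, genera_plan = c(Escherichia = 2, Salmonella = 2, Vibrio = 1)))
hits <- screen_genomes(sim$genomes, sim$annotations)
head(hits[, c("genome_id", "motif_start0", "strand", "matched_seq",
              "gene_id", "gap_nt", "function_label")], 4)
#>   genome_id motif_start0 strand matched_seq  gene_id gap_nt function_label
#> 1      G001          629      - GTTCTTTAACA G001_g01     14           suhB
#> 2      G001        12271      - GTTCTTTAAGA G001_g05      9           prsA
#> 3      G001        36986      - GCTCTTTAACA G001_g15      2           rpsJ
#> 4      G002         9253      - GCTCTTTAAGA G002_g04     12           suhB
```

Each row is one consensus match sitting `gap_nt` nucleotides upstream of a
gene's start codon on the gene's strand. Distinct-locus tallies per genome
and the genus-level summary:

```r
per_genome_counts(hits, sim$metadata)
#>   genome_id n_motif_loci
#> 1      G001            3
#> 2      G002            4
#> 3      G003            6
#> 4      G004            1
#> 5      G005            1

aggregate_by_genus(hits, sim$metadata)[, c("function_label", "n_genera")]
#>    function_label n_genera
#> 1            suhb        3
#> 2 pare-like toxin        2
#> 3            prsa        2
#> 4            rpsj        2
#> 5            ribh        1

genus_coverage(hits, sim$metadata, "suhB")
#> $n_genera_with_hit
#> [1] 3
#> $n_genera_total
#> [1] 3
```

`suhB` is hit in all 3 genera: a function found once per genus counts once,
however many genomes of that genus carry it. Conservation of a simulated
20-row upstream alignment (each non-reference row substituting 20% of
columns) against its reference:

```r
ref <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
aln <- simulate_alignment(ref, n_rows = 20, p_sub = 0.2, seed = 20)
track <- column_match_percent(aln)
head(track, 3)
#>   ref_pos column ref_base n_match pct
#> 1       1      1        T      13  70
#> 2       2      2        A      13  70
#> 3       3      3        G      16  85
mean(track$pct)
#> [1] 79.75   # expectation 100 * (1 + 19 * 0.8) / 20 = 81
```

And the Rut-style composition report for a pyrimidine-rich 21-mer:

```r
base_composition("CTTCTCTTTAACATCTTCGTC")
#> <composition_report> positions 1-21 (21 nt): 17 pyrimidines (C=7, T=10),
#>   1 G, 3 A, 0 other
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/boxascan.R` (subcommands `scan`, `screen`, `aggregate`,
`conserve`, `composition`, `simulate`).

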