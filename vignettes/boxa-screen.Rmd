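---
title: "Screening genomes for BoxA antitermination elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening genomes for BoxA antitermination elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boxascan)
```

## The screen

BoxA is an 11-nt RNA element bound by the Nus factor complex (NusB/NusE with
NusA, NusG and SuhB) in nascent transcripts. In γ-proteobacteria its
consensus is the degenerate pattern `GYTCTTTAANA` (`Y` = C/T, `N` = any
base), which expands to 8 unambiguous 11-mers. The screen asks a simple
question of every genome: where does a *perfect* match to this consensus sit
immediately upstream of an annotated protein-coding gene start? Such
elements, transcribed into the 5′ leader of the downstream gene, are
candidates for Nus-factor-mediated regulation of that gene — the arrangement
known for *suhB*, where the BoxA additionally overlaps a Rho-utilization
(Rut) site and mediates Rho-dependent termination and translational
repression.

The pipeline has five analysis stages, each an independent module:

1. `scan_genome()` — every occurrence of the pattern on both strands;
2. `screen_genome()` — hits retained within the upstream window of a gene;
3. `aggregate_by_genus()` / `genus_coverage()` — genus-level function
   presence;
4. `column_match_percent()` — conservation of upstream regions against a
   reference;
5. `base_composition()` / `rut_candidate_windows()` — pyrimidine/G
   composition for Rut localization.

`simulate_genomes()` supplies planted-truth inputs so that all of it runs,
and is tested, without any external download.

## Matching semantics

Matching is per-position set membership: position *j* of a window matches if
the genomic base is in the allowed set of pattern code *j*. Two consequences
are deliberate:

* **Genomic `N` matches nothing**, including pattern `N`. The screen's
  criterion is a perfect match to the consensus, and a perfect match cannot
  be asserted over an unknown base. (Degenerate-pattern matchers that let
  pattern `N` match subject `N` would silently admit such windows.)
* **Both strands are scanned**, and a hit is reported on the strand where
  the motif reads 5′→3′, with coordinates always on the forward genomic
  axis: a minus-strand hit's `matched_seq` is the reverse complement of the
  genomic slice. Overlapping hits are all reported.

Internally the scanner is a vectorized membership test per pattern position;
the test suite checks it against two independent routes — a brute-force
enumeration of all 11-mers against the 8 consensus expansions, and
`Biostrings::matchPattern(fixed = FALSE)` on `N`-free sequence — and against
a strand-symmetry property (scanning the reverse complement mirrors every
hit).

All internal coordinates are 0-based half-open; 1-based inclusive
coordinates appear only in GFF3 I/O and printed reports. "Gene start" always
means the first base of the annotated start codon: `start0` for a `+` gene,
`end0 − 1` for a `−` gene. No transcription start sites are assumed.

## The upstream window

The distance rule has two defensible readings, and both are implemented:

* `containment` (default): the whole motif lies within the `distance_nt`
  window immediately upstream of the start codon, i.e.
  `gap_nt ≤ distance_nt − 11` (≤ 39 for the default 50-nt window);
* `gap`: only the gap between the motif's 3′ end and the start codon is
  bounded, `gap_nt ≤ distance_nt`.

`gap_nt` counts the bases strictly between the motif and the start codon, so
a motif abutting the start codon has gap 0. Every qualifying (motif, gene)
pair is one output row — a motif upstream of two overlapping gene models
yields two rows — while `per_genome_counts()` counts *distinct motif loci*
(replicon, start, strand), which is the unit in which instances per genome
are reported. Defaults the screen takes as given:

* `same_strand_only = TRUE`: a BoxA functions in the nascent transcript of
  the downstream gene, so opposite-strand matches are not biologically
  equivalent; the option exists for exploration.
* `allow_overlap_upstream_gene = TRUE`: a motif overlapping the 3′ end of
  the preceding gene is still eligible, because the filter is purely
  distance-based; intergenic-only placement can be enforced by disabling it.

`extend_to_operon()` optionally propagates a hit on an operon lead gene to
the downstream members of the same operon (flagged rows), capturing cases
where the regulated function sits downstream in the operon rather than
immediately behind the BoxA. Flagged rows never enter per-genome counts and
are excluded from genus aggregation by default.

## Genus-level aggregation

Sequenced genomes are very unevenly distributed across genera, so counting
species (or genomes) would weight heavily sequenced genera arbitrarily.
A gene function is therefore credited to a genus at most once: `n_genera`
counts genera in which ≥ 1 species has ≥ 1 upstream hit on a gene with that
label. Function identity is the supplied label after case-folding and
whitespace normalization — no ontology reasoning; labels come from whatever
annotation attribute or external table (e.g. COG assignments) the user
supplies, because annotation granularity is a property of the input, not of
the method. Genes without a label group under `unannotated`. The key
invariant, tested directly, is idempotence: duplicating any genome's rows
(or adding a cloned genome of an existing genus) changes no `n_genera`.

## Conservation scoring

For an alignment of *n* upstream regions including a designated reference
row, each column where the reference is not gapped scores

```
pct = 100 × (n_match + 1) / n
```

where `n_match` counts non-reference rows equal to the reference character.
The `+1` counts the reference itself, so the track is bounded in
`[100/n, 100]`; with 19 non-reference species this is exactly "+1, divide
by 20, convert to a percentage". Gap handling must be decided by the
implementation: a gap in a non-reference row counts as a mismatch (absence
of the base is not a match), and columns where the *reference* is gapped are
omitted from the track — it is drawn along the reference's own coordinates —
but reported in a side attribute. Comparison is case-insensitive. The
aligner itself is an external input (`read_alignment()` reads aligned
FASTA); an optional centered moving average (`windowed_mean()`, truncated at
the edges) is provided for plotting and is off by default in all reports.

## Rut-like composition

Rut sites are pyrimidine-rich and G-poor, but no formal score for them is
established. The module therefore reports plain counts
(`base_composition()`, over 1-based inclusive intervals to match printed
coordinates such as "positions 2–22") and a thresholded sliding window
(`rut_candidate_windows()`) whose defaults — window 21 nt, ≥ 16 pyrimidines,
≤ 1 G — are calibrated to the one worked example available: a 21-nt
5′-UTR segment containing 17 pyrimidines and a single G. Results always echo
the thresholds, so a report can never silently present the cutoff as a
property of the data. Maximal runs of passing windows are merged for
reporting. The module does not attempt to predict actual Rho termination
sites, and it ignores RNA secondary structure.

## The synthetic-genome generator

`simulate_genomes()` emulates the screened population at desk scale. Its
defaults are one fixed study condition: 20 genera × 5 genomes (100 genomes),
one 50-kb replicon per genome at GC 0.5, 20 non-overlapping single-CDS genes
(300–900 nt, random strands, real start/stop codons written into the
sequence), 1–7 planted consensus matches per genome — each a uniformly
chosen expansion written on the target gene's strand at a gap drawn from
0–39 nt, so every planted motif lies wholly inside the default window — and
3 decoys per genome, each an expansion mutated at one consensus position to
a base outside that position's allowed set. Genomes live in per-genome RNG
substreams of one master seed, so adding genomes to a plan never perturbs
earlier ones, and the emitted FASTA/GFF3/TSV files are byte-identical across
runs.

Two properties make the generator honest as a test bed. Decoys are
guaranteed non-matching at their planted locus by construction (the mutated
position violates its code). Background sequence, however, can contain
*spontaneous* consensus matches — at GC 0.5 the expected density is
16/4^11 per base over both strands, about 0.2 per 50-kb genome — so planted
truth is evaluated as containment (every planted motif recovered; no decoy
locus reported) rather than as exact equality with the screen output, and a
generator sanity check verifies the background match count against binomial
bounds.

What the generator does **not** emulate: codon usage and amino-acid content,
operonic gene spacing (its operon table is a synthetic mapping to exercise
the operon extension, not a spatial arrangement), phylogenetic correlation
between genomes of a genus, multi-replicon genomes, and annotation errors.
Passing the recovery tests therefore demonstrates the correctness of the
scanning/filtering logic, not robustness to the annotation noise and
compositional structure of real genomes. Similarly, `simulate_alignment()`
mutates columns independently (substitution probability `p_sub`, gap
probability `p_gap` per non-reference row), giving a closed-form expected
mean conservation of `100 × (1 + (n−1)(1−p_sub))/n` to test against — 81 for
`n = 20, p_sub = 0.2` — but no indel blocks or covarying columns.

## Numerical and edge-case choices

* Ties and ordering: all tables are emitted in a fixed sort order
  (replicon, start, strand, gene), so identical inputs give byte-identical
  outputs.
* Degenerate inputs: an empty hit list yields a header-only table and
  zero counts for every genome in the metadata; a window longer than the
  sequence yields an empty composition scan with a warning; ragged
  alignments, unknown replicons, out-of-bounds features and non-ACGTN
  residues are errors that name the offending record.
* Test problem sizes were chosen to exercise each property at comfortable
  margins: 200 random kilobases for scanner/oracle equivalence, the
  100-genome default population for planted recovery, a 10-kb reference for
  the conservation Monte-Carlo check (3 standard errors ≈ 0.26 percentage
  points around the expectation of 81).

## Limitations

The headline tallies of any real screen (counts of putative elements,
genomes, genera and functions) are properties of a specific genome inventory
and its annotation versions; they are not reproducible from this package
alone and are deliberately out of its test scope. The screen uses annotated
translational starts, so mispredicted starts shift or lose hits; elements
more than `distance_nt` upstream (known to occur) are invisible by design;
non-coding RNA targets are not considered; and genera whose BoxA consensus
deviates from `GYTCTTTAANA` require a different pattern argument.
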